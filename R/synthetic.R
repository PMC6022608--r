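# Seeded synthetic data: gold standards with controllable genome/contig
# size structure, a degradation model that corrupts the perfect binning in
# the four ways real binners fail (merged bins, split bins, misassigned
# sequences, unassigned sequences), and the small hand-checkable worked
# fixture used throughout the documentation and tests.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gold standard
#'
#' Draws a community of `n_genomes` genomes, each split into a uniformly
#' drawn number of contigs with uniformly drawn lengths, so genome sizes
#' vary across the community. Ids are stable zero-padded strings
#' (`G001`, `G001_c0001`, ...). The same seed always yields the same
#' object.
#'
#' @param n_genomes Number of genomes, >= 1.
#' @param contigs_per_genome Integer range (length-2 vector) of contigs
#'   per genome; default 5–20.
#' @param length_range_bp Integer range of contig lengths in bp; default
#'   1,000–100,000.
#' @param seed Integer seed.
#' @return A [gold_standard()] object.
#' @export
generate_gold_standard <- function(n_genomes,
                                   contigs_per_genome = c(5L, 20L),
                                   length_range_bp = c(1000L, 100000L),
                                   seed = 1L) {
  if (n_genomes < 1L) stop("n_genomes must be >= 1", call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && all(r >= 1) && r[1] <= r[2]
  if (!rng_ok(contigs_per_genome) || !rng_ok(length_range_bp)) {
    stop("contigs_per_genome and length_range_bp must be valid positive ranges",
         call. = FALSE)
  }
  sample_range <- function(lo, hi, n) {
    lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  }
  with_local_seed(seed, {
    gpad <- max(3L, nchar(as.character(n_genomes)))
    assignment <- character(); lengths <- numeric()
    for (i in seq_len(n_genomes)) {
      gid <- sprintf(paste0("G%0", gpad, "d"), i)
      k <- sample_range(contigs_per_genome[1], contigs_per_genome[2], 1L)
      len <- sample_range(length_range_bp[1], length_range_bp[2], k)
      cid <- sprintf(paste0(gid, "_c%04d"), seq_len(k))
      assignment[cid] <- gid
      lengths[cid] <- len
    }
    gold_standard(assignment, lengths)
  })
}

#' Degradation settings for a synthetic binning
#'
#' Describes how far a binning departs from the perfect one-bin-per-genome
#' solution. Degradations are applied in the fixed order merge, split,
#' misassign, unassign, under a single seeded random stream, so a spec
#' plus seed fully determines the output.
#'
#' @param unassign_rate Per-sequence probability of being left out of the
#'   binning (Bernoulli, so realized fractions fluctuate binomially).
#' @param misassign_rate Per-sequence probability of being moved to a
#'   uniformly chosen wrong bin.
#' @param merge_pairs Number of random bin pairs fused into one bin
#'   (underbinning: several genomes in one bin).
#' @param split_count Number of random bins split in two (overbinning:
#'   one genome across many bins).
#' @param seed Integer seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(unassign_rate = 0, misassign_rate = 0,
                             merge_pairs = 0L, split_count = 0L, seed = 1L) {
  rates <- c(unassign_rate, misassign_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (merge_pairs < 0L || split_count < 0L) {
    stop("merge_pairs and split_count must be non-negative", call. = FALSE)
  }
  structure(list(unassign_rate = unassign_rate, misassign_rate = misassign_rate,
                 merge_pairs = as.integer(merge_pairs),
                 split_count = as.integer(split_count),
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Produce a controllably degraded binning from a gold standard
#'
#' Starts from the perfect binning (one bin per genome, every sequence
#' assigned, bin ids `bin_<genome>`), then applies the degradations of the
#' spec in the fixed order merge, split, misassign, unassign. The realized
#' edit counts are attached as the `edits` attribute.
#'
#' @param gold A [gold_standard()] object.
#' @param spec A [degradation_spec()].
#' @param label Display label for the resulting binning.
#' @return A [binning()] object with attribute `edits` (a list with
#'   `merged`, `split`, `misassigned`, `unassigned` counts).
#' @export
perturb_binning <- function(gold, spec, label = "synthetic") {
  stopifnot(inherits(gold, "gold_standard"), inherits(spec, "degradation_spec"))
  with_local_seed(spec$seed, {
    assignment <- stats::setNames(paste0("bin_", gold$assignment),
                                  names(gold$assignment))
    edits <- list(merged = 0L, split = 0L, misassigned = 0L, unassigned = 0L)

    for (i in seq_len(spec$merge_pairs)) {
      bins <- sort(unique(unname(assignment)), method = "radix")
      if (length(bins) < 2L) break
      pair <- sort(sample(bins, 2L))
      fused <- paste(pair, collapse = "+")
      assignment[assignment %in% pair] <- fused
      edits$merged <- edits$merged + 1L
    }

    for (i in seq_len(spec$split_count)) {
      bins <- sort(unique(unname(assignment)), method = "radix")
      sizes <- table(assignment)
      splittable <- bins[sizes[bins] >= 2L]
      if (length(splittable) == 0L) break
      target <- sample(splittable, 1L)
      members <- sort(names(assignment)[assignment == target], method = "radix")
      moved <- sample(members, floor(length(members) / 2))
      assignment[moved] <- paste0(target, "_s", i)
      edits$split <- edits$split + 1L
    }

    if (spec$misassign_rate > 0) {
      bins <- sort(unique(unname(assignment)), method = "radix")
      if (length(bins) >= 2L) {
        hit <- stats::runif(length(assignment)) < spec$misassign_rate
        for (id in names(assignment)[hit]) {
          others <- setdiff(bins, assignment[[id]])
          assignment[[id]] <- sample(others, 1L)
        }
        edits$misassigned <- sum(hit)
      }
    }

    if (spec$unassign_rate > 0) {
      drop <- stats::runif(length(assignment)) < spec$unassign_rate
      edits$unassigned <- sum(drop)
      assignment <- assignment[!drop]
    }
    if (length(assignment) == 0L) {
      stop("degradation left no sequence assigned", call. = FALSE)
    }
    b <- binning(assignment, label = label)
    attr(b, "edits") <- edits
    b
  })
}

#' The worked five-contig example
#'
#' A tiny benchmark whose every metric can be derived by hand: genomes
#' A = \{a1: 60 bp, a2: 40 bp\}, B = \{b1: 50 bp, b2: 50 bp\},
#' C = \{c1: 30 bp\}; the evaluated binning puts a1, a2 and b1 in bin X,
#' b2 in bin Y, and leaves c1 unassigned. Bin X therefore holds all of
#' genome A (purity 2/3, completeness 1) plus half of genome B; bin Y is
#' pure but covers only half of genome B; genome C is entirely unassigned.
#'
#' @param dir If non-NULL, the two objects are also written there as
#'   Bioboxes files `gold_standard.tsv` (with a `_LENGTH` column) and
#'   `binning.tsv`.
#' @return A list with elements `gold` and `binning` (and `paths` when
#'   `dir` was given).
#' @export
fixture_f1 <- function(dir = NULL) {
  gold <- gold_standard(
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C"),
    c(a1 = 60, a2 = 40, b1 = 50, b2 = 50, c1 = 30)
  )
  bin <- binning(c(a1 = "X", a2 = "X", b1 = "X", b2 = "Y"), label = "F1")
  out <- list(gold = gold, binning = bin)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gold_path <- file.path(dir, "gold_standard.tsv")
    ids <- names(gold$assignment)
    writeLines(c(
      "@Version:0.9.0",
      "@SampleID:F1_gold",
      "@@SEQUENCEID\tBINID\t_LENGTH",
      paste0(ids, "\t", unname(gold$assignment), "\t",
             format(gold$seq_lengths[ids], trim = TRUE, scientific = FALSE))
    ), gold_path, useBytes = TRUE)
    bin_path <- file.path(dir, "binning.tsv")
    write_bioboxes_binning(bin, bin_path, sample_id = "F1")
    out$paths <- c(gold = gold_path, binning = bin_path)
  }
  out
}
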