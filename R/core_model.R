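# Contingency structure between predicted bins and gold-standard genomes,
# and the bin-to-genome mapping under either of the two supported criteria.
# The unit of assignment is the whole sequence; overlaps are tallied in
# exact integer base pairs and in sequence counts in one pass.

#' Build the bin-by-genome contingency table
#'
#' Cross-tabulates a predicted binning against the gold standard. The cell
#' (x, y) holds the overlap between bin x and genome y, in base pairs and
#' in sequence counts. Sequences in the binning that are absent from the
#' gold standard are excluded from evaluation (with a counted warning);
#' gold-standard base pairs in no bin form the unassigned tally U.
#'
#' @param gold A [gold_standard()] object.
#' @param binning A [binning()] object.
#' @return An object of class `bin_contingency` with the bp and
#'   sequence-count cell matrices (bins in rows, genomes in columns; both
#'   in byte-sorted id order), marginal totals, the unassigned tally, and
#'   bookkeeping counts.
#' @export
build_contingency <- function(gold, binning) {
  stopifnot(inherits(gold, "gold_standard"), inherits(binning, "binning"))
  common <- intersect(names(binning$assignment), names(gold$assignment))
  n_dropped <- length(binning$assignment) - length(common)
  if (length(common) == 0L) {
    stop("no evaluable sequences: binning and gold standard share no sequence ids",
         call. = FALSE)
  }
  if (n_dropped > 0L) {
    warning(sprintf("%d sequence(s) in binning '%s' absent from the gold standard were excluded",
                    n_dropped, binning$label), call. = FALSE)
  }
  bin_of <- binning$assignment[common]
  genome_of <- gold$assignment[common]
  len_of <- gold$seq_lengths[common]

  bins <- sort(unique(unname(bin_of)), method = "radix")
  lost_bins <- setdiff(unique(unname(binning$assignment)), bins)
  if (length(lost_bins)) {
    warning(sprintf("%d bin(s) with no evaluable sequence removed", length(lost_bins)),
            call. = FALSE)
  }
  genomes <- names(gold$genome_sizes)
  fb <- factor(bin_of, levels = bins)
  fg <- factor(genome_of, levels = genomes)
  cells_bp <- tapply_matrix(len_of, fb, fg)
  cells_seq <- tapply_matrix(rep(1, length(common)), fb, fg)

  bin_totals_bp <- rowSums(cells_bp)
  genome_totals_assigned_bp <- colSums(cells_bp)
  total_assigned_bp <- sum(bin_totals_bp)
  total_bp <- sum(gold$genome_sizes)
  unassigned_per_genome_bp <- gold$genome_sizes - genome_totals_assigned_bp

  structure(list(
    cells_bp = cells_bp,
    cells_seq = cells_seq,
    bin_totals_bp = bin_totals_bp,
    genome_totals_assigned_bp = genome_totals_assigned_bp,
    total_assigned_bp = total_assigned_bp,
    unassigned_bp = total_bp - total_assigned_bp,
    unassigned_per_genome_bp = unassigned_per_genome_bp,
    genome_sizes = gold$genome_sizes,
    total_bp = total_bp,
    total_assigned_seq = length(common),
    total_seq = length(gold$assignment),
    n_dropped = n_dropped
  ), class = "bin_contingency")
}

tapply_matrix <- function(values, frow, fcol) {
  m <- tapply(values, list(frow, fcol), sum, default = 0)
  m[is.na(m)] <- 0
  matrix(as.numeric(m), nrow = nlevels(frow), ncol = nlevels(fcol),
         dimnames = list(levels(frow), levels(fcol)))
}

#' @export
print.bin_contingency <- function(x, ...) {
  cat(sprintf("Contingency: %d bins x %d genomes; %s of %s bp assigned (U = %s)\n",
              nrow(x$cells_bp), ncol(x$cells_bp),
              format(x$total_assigned_bp, big.mark = ","),
              format(x$total_bp, big.mark = ","),
              format(x$unassigned_bp, big.mark = ",")))
  invisible(x)
}

# Extract one row as a named vector (plain indexing drops names when the
# matrix has a single column).
row_scores <- function(m, b) stats::setNames(m[b, ], colnames(m))

# Deterministic argmax over one bin's overlap scores: ties are broken
# towards the larger genome, then the byte-order smaller genome id.
argmax_genome <- function(scores, genome_sizes) {
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    sz <- genome_sizes[best]
    best <- best[sz == max(sz)]
    if (length(best) > 1L) {
      ids <- names(scores)[best]
      best <- best[order(ids, method = "radix")[1L]]
    }
  }
  names(scores)[best[1L]]
}

finish_mapping <- function(ct, mapped, criterion) {
  bins <- rownames(ct$cells_bp)
  tp <- ct$cells_bp[cbind(bins, mapped)]
  names(tp) <- bins
  fp <- ct$bin_totals_bp - tp
  fn <- ct$genome_sizes[mapped] - tp
  names(fn) <- bins
  structure(list(
    mapped_genome = stats::setNames(mapped, bins),
    tp_bp = tp, fp_bp = fp, fn_bp = fn,
    unmapped_genomes = setdiff(colnames(ct$cells_bp), mapped),
    criterion = criterion
  ), class = "bin_genome_mapping")
}

#' Map bins to genomes by majority overlap
#'
#' Each predicted bin is mapped to the genome contributing the most base
#' pairs to it. Ties are broken towards the larger genome, then the
#' byte-order smaller genome id. True positives of a bin are the base
#' pairs shared with its mapped genome; false positives are the rest of
#' the bin; false negatives are the rest of the mapped genome. Genomes in
#' the image of no bin form the unmapped set.
#'
#' @param ct A `bin_contingency` from [build_contingency()].
#' @return An object of class `bin_genome_mapping`.
#' @export
map_bins_majority <- function(ct) {
  stopifnot(inherits(ct, "bin_contingency"))
  mapped <- vapply(rownames(ct$cells_bp), function(b) {
    argmax_genome(row_scores(ct$cells_bp, b), ct$genome_sizes)
  }, character(1L))
  finish_mapping(ct, mapped, "majority_overlap")
}

#' Map bins to genomes by contained genome fraction
#'
#' Each predicted bin is mapped to the genome whose largest fraction of
#' base pairs was assigned to the bin (overlap divided by genome size).
#' When more than one genome is completely contained in the bin — or the
#' top fraction is otherwise tied — the larger genome is mapped, then the
#' byte-order smaller id. TP/FP/FN and the unmapped genome set are derived
#' as in [map_bins_majority()], under this mapping.
#'
#' @param ct A `bin_contingency` from [build_contingency()].
#' @param gold Optional [gold_standard()]; genome sizes default to those
#'   recorded in `ct`.
#' @return An object of class `bin_genome_mapping`.
#' @export
map_bins_fraction <- function(ct, gold = NULL) {
  stopifnot(inherits(ct, "bin_contingency"))
  sizes <- if (is.null(gold)) ct$genome_sizes else gold$genome_sizes[colnames(ct$cells_bp)]
  mapped <- vapply(rownames(ct$cells_bp), function(b) {
    argmax_genome(row_scores(ct$cells_bp, b) / sizes, ct$genome_sizes)
  }, character(1L))
  finish_mapping(ct, mapped, "genome_fraction")
}

#' @export
print.bin_genome_mapping <- function(x, ...) {
  cat(sprintf("Bin-to-genome mapping (%s): %d bins, %d unmapped genome(s)\n",
              x$criterion, length(x$mapped_genome), length(x$unmapped_genomes)))
  invisible(x)
}
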