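# Readers and writers for the Bioboxes binning format and sequence-length
# indexing from FASTA/FASTQ. All parsed inputs are normalised into the two
# in-memory containers the rest of the package consumes: a `gold_standard`
# (true sequence -> genome partition with lengths) and a `binning`
# (predicted sequence -> bin partition).

#' Construct a gold standard object
#'
#' A gold standard is the known true partition of sequences (contigs or
#' reads) into the genomes of the community members, together with the
#' length in base pairs of every sequence. Per-genome sizes are derived as
#' the sum of the lengths of the sequences assigned to each genome.
#'
#' @param assignment Named character vector mapping sequence id (names) to
#'   genome id (values).
#' @param seq_lengths Named numeric vector of sequence lengths in bp; must
#'   cover every assigned sequence id.
#' @return An object of class `gold_standard` with elements `assignment`,
#'   `seq_lengths` and `genome_sizes`.
#' @export
gold_standard <- function(assignment, seq_lengths) {
  assignment <- unlist_map(assignment)
  seq_lengths <- unlist_map(seq_lengths, numeric = TRUE)
  if (length(assignment) == 0L) {
    stop("empty gold standard: no sequence-to-genome assignments", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicate sequence ids in gold standard assignment", call. = FALSE)
  }
  missing <- setdiff(names(assignment), names(seq_lengths))
  if (length(missing)) {
    stop("sequences lacking a length: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L),
         call. = FALSE)
  }
  if (any(seq_lengths < 1)) {
    stop("sequence lengths must be >= 1 bp", call. = FALSE)
  }
  seq_lengths <- seq_lengths[names(seq_lengths) %in% names(assignment)]
  ord <- order(names(assignment), method = "radix")
  assignment <- assignment[ord]
  seq_lengths <- seq_lengths[names(assignment)]
  sizes <- tapply(seq_lengths, assignment, sum)
  genome_sizes <- as.numeric(sizes)
  names(genome_sizes) <- names(sizes)
  genome_sizes <- genome_sizes[order(names(genome_sizes), method = "radix")]
  structure(
    list(assignment = assignment, seq_lengths = seq_lengths,
         genome_sizes = genome_sizes),
    class = "gold_standard"
  )
}

#' Construct a binning object
#'
#' A binning is a predicted partition of sequences into genome bins, as
#' produced by a genome binning program. Each sequence belongs to at most
#' one bin; bins carry no taxonomic label.
#'
#' @param assignment Named character vector mapping sequence id to bin id.
#' @param label Display label for the binner (used in reports and rankings).
#' @return An object of class `binning`.
#' @export
binning <- function(assignment, label = "binning") {
  assignment <- unlist_map(assignment)
  if (length(assignment) == 0L) stop("empty binning", call. = FALSE)
  if (anyDuplicated(names(assignment))) {
    stop("duplicate sequence ids in binning", call. = FALSE)
  }
  if (any(!nzchar(assignment))) stop("empty bin ids are not allowed", call. = FALSE)
  ord <- order(names(assignment), method = "radix")
  structure(list(label = as.character(label), assignment = assignment[ord]),
            class = "binning")
}

unlist_map <- function(x, numeric = FALSE) {
  if (is.list(x)) x <- unlist(x)
  if (numeric) x <- stats::setNames(as.numeric(x), names(x))
  else x <- stats::setNames(as.character(x), names(x))
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("assignment maps must be named vectors", call. = FALSE)
  }
  x
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard: %d sequences, %d genomes, %s bp\n",
              length(x$assignment), length(x$genome_sizes),
              format(sum(x$genome_sizes), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
print.binning <- function(x, ...) {
  cat(sprintf("Binning '%s': %d sequences in %d bins\n", x$label,
              length(x$assignment), length(unique(x$assignment))))
  invisible(x)
}

# Open a file as a text connection, decompressing transparently when the
# gzip magic bytes (1f 8b) are present. Detection is by content, never by
# file extension.
open_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

read_text_lines <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Tolerant Bioboxes parser shared by the binning and gold-standard readers.
# Accepts `@Key:Value` headers and `#` comments in any order before the
# mandatory `@@` column line; fields are single-tab separated with
# surrounding whitespace stripped; header keys are case-insensitive.
parse_bioboxes <- function(path) {
  lines <- read_text_lines(path)
  headers <- character()
  columns <- NULL
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) next
    if (startsWith(line, "@@")) {
      if (!is.null(columns)) {
        stop(sprintf("%s: second '@@' column header at line %d", path, i),
             call. = FALSE)
      }
      columns <- toupper(trimws(strsplit(sub("^@@", "", line), "\t", fixed = TRUE)[[1]]))
      next
    }
    if (startsWith(line, "@")) {
      kv <- sub("^@", "", line)
      pos <- regexpr(":", kv, fixed = TRUE)
      if (pos > 0) {
        key <- toupper(trimws(substr(kv, 1L, pos - 1L)))
        headers[key] <- trimws(substr(kv, pos + 1L, nchar(kv)))
      }
      next
    }
    if (is.null(columns)) {
      stop(sprintf("%s: data row before '@@' column header at line %d", path, i),
           call. = FALSE)
    }
    fields <- trimws(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (length(fields) < length(columns)) {
      stop(sprintf("%s: row at line %d has %d fields, expected %d",
                   path, i, length(fields), length(columns)), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fields[seq_along(columns)]
  }
  if (is.null(columns)) {
    stop(sprintf("%s: missing '@@' column header line", path), call. = FALSE)
  }
  required <- c("SEQUENCEID", "BINID")
  if (!all(required %in% columns)) {
    stop(sprintf("%s: '@@' header must contain SEQUENCEID and BINID (found: %s)",
                 path, paste(columns, collapse = ", ")), call. = FALSE)
  }
  data <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix(character(), 0L, length(columns)), stringsAsFactors = FALSE)
  }
  names(data) <- columns
  list(headers = headers, columns = columns, data = data)
}

resolve_duplicates <- function(seq_id, bin_id, path, keep_first) {
  dup <- duplicated(seq_id)
  if (!any(dup)) return(list(seq_id = seq_id, bin_id = bin_id, n_dropped = 0L))
  first_bin <- bin_id[match(seq_id, seq_id)]
  conflicting <- unique(seq_id[dup & bin_id != first_bin])
  if (length(conflicting) && !keep_first) {
    stop(sprintf("%s: sequence(s) assigned to more than one bin: %s%s",
                 path, paste(utils::head(conflicting, 10L), collapse = ", "),
                 if (length(conflicting) > 10L) " ..." else ""),
         call. = FALSE)
  }
  if (length(conflicting)) {
    warning(sprintf("%s: kept first of conflicting assignments for %d sequence(s)",
                    path, length(conflicting)), call. = FALSE)
  }
  list(seq_id = seq_id[!dup], bin_id = bin_id[!dup], n_dropped = sum(dup))
}

#' Read a predicted binning in Bioboxes binning format
#'
#' Parses a tab-separated Bioboxes binning file: optional `@Key:Value`
#' header lines and `#` comments, then an `@@SEQUENCEID<TAB>BINID...`
#' column line, then one row per sequence. Column order is taken from the
#' `@@` line, so files with permuted columns parse identically. Extra
#' columns (e.g. TAXID, _LENGTH) are preserved as the `metadata` attribute.
#'
#' @param path Path to the file; gzip-compressed input is detected by its
#'   magic bytes and decompressed transparently.
#' @param label Display label; defaults to the file's `@SampleID` header if
#'   present, else the basename without extension.
#' @param keep_first If `TRUE`, a sequence listed with conflicting bins
#'   keeps its first assignment with a warning instead of raising an error.
#' @return A [binning()] object.
#' @export
read_bioboxes_binning <- function(path, label = NULL, keep_first = FALSE) {
  parsed <- parse_bioboxes(path)
  if (is.null(label)) {
    label <- if (!is.na(parsed$headers["SAMPLEID"])) {
      parsed$headers[["SAMPLEID"]]
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  d <- parsed$data
  res <- resolve_duplicates(d$SEQUENCEID, d$BINID, path, keep_first)
  keep <- !duplicated(d$SEQUENCEID)
  b <- binning(stats::setNames(res$bin_id, res$seq_id), label = label)
  extra <- setdiff(parsed$columns, c("SEQUENCEID", "BINID"))
  if (length(extra)) {
    meta <- d[keep, c("SEQUENCEID", extra), drop = FALSE]
    rownames(meta) <- NULL
    attr(b, "metadata") <- meta
  }
  attr(b, "headers") <- parsed$headers
  b
}

#' Write a binning in Bioboxes binning format
#'
#' Emits `@Version`, `@SampleID`, the `@@SEQUENCEID<TAB>BINID` column line
#' and one tab-separated row per sequence, sorted by sequence id in byte
#' order so output is deterministic and write/read/write is idempotent.
#'
#' @param x A [binning()] object.
#' @param path Output file path.
#' @param sample_id Value for the `@SampleID` header; defaults to the
#'   binning's label.
#' @param version Value for the `@Version` header.
#' @return `path`, invisibly.
#' @export
write_bioboxes_binning <- function(x, path, sample_id = x$label,
                                   version = "0.9.0") {
  stopifnot(inherits(x, "binning"))
  if (length(x$assignment) == 0L) stop("refusing to write an empty binning", call. = FALSE)
  ids <- sort(names(x$assignment), method = "radix")
  lines <- c(
    paste0("@Version:", version),
    paste0("@SampleID:", sample_id),
    "@@SEQUENCEID\tBINID",
    paste0(ids, "\t", unname(x$assignment[ids]))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

first_token <- function(x) sub("[ \t].*$", "", x)

detect_seq_format <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    if (nzchar(trimws(line))) break
  }
  ch <- substr(trimws(line), 1L, 1L)
  if (ch == ">") "fasta" else if (ch == "@") "fastq" else NA_character_
}

#' Index sequence lengths from FASTA/FASTQ files
#'
#' Builds a map from sequence id to length in base pairs. The format of
#' each file is auto-detected from its first record character (`>` FASTA,
#' `@` FASTQ); gzip compression is detected from magic bytes. The sequence
#' id is the header token up to the first whitespace; length is the residue
#' count ignoring line breaks.
#'
#' @param paths Character vector of FASTA/FASTQ file paths.
#' @return Named numeric vector of lengths in bp.
#' @export
index_sequence_lengths <- function(paths) {
  out <- numeric()
  for (path in paths) {
    fmt <- detect_seq_format(path)
    if (is.na(fmt)) {
      stop(sprintf("%s: not recognisably FASTA or FASTQ", path), call. = FALSE)
    }
    if (fmt == "fasta") {
      lens <- Biostrings::fasta.seqlengths(path)
    } else {
      seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
      lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
    }
    names(lens) <- first_token(names(lens))
    if (any(lens == 0)) {
      warning(sprintf("%s: %d empty sequence record(s) excluded", path, sum(lens == 0)),
              call. = FALSE)
      lens <- lens[lens > 0]
    }
    clash <- intersect(names(lens), names(out))
    if (length(clash)) {
      stop(sprintf("duplicate sequence id(s) across files: %s",
                   paste(utils::head(clash, 10L), collapse = ", ")), call. = FALSE)
    }
    out <- c(out, lens)
  }
  out
}

#' Read a gold standard in Bioboxes binning format
#'
#' The BINID column of the file holds the true genome id of each sequence.
#' Sequence lengths come from the `lengths` argument (typically built with
#' [index_sequence_lengths()]), from an in-file `_LENGTH` column, or both;
#' when both are present they must agree for every sequence.
#'
#' @param path Path to the Bioboxes file.
#' @param lengths Optional named numeric vector of sequence lengths in bp.
#' @return A [gold_standard()] object.
#' @export
read_gold_standard <- function(path, lengths = NULL) {
  parsed <- parse_bioboxes(path)
  d <- parsed$data
  res <- resolve_duplicates(d$SEQUENCEID, d$BINID, path, keep_first = FALSE)
  seq_id <- res$seq_id
  genome_id <- res$bin_id
  file_lengths <- NULL
  if ("_LENGTH" %in% parsed$columns) {
    lens <- suppressWarnings(as.numeric(d$`_LENGTH`[!duplicated(d$SEQUENCEID)]))
    if (anyNA(lens)) {
      stop(sprintf("%s: non-numeric _LENGTH value(s)", path), call. = FALSE)
    }
    file_lengths <- stats::setNames(lens, seq_id)
  }
  if (is.null(lengths) && is.null(file_lengths)) {
    stop(sprintf(paste0("%s: no sequence length source; supply FASTA/FASTQ-derived ",
                        "lengths or include a _LENGTH column"), path), call. = FALSE)
  }
  if (!is.null(lengths) && !is.null(file_lengths)) {
    both <- intersect(names(lengths), names(file_lengths))
    bad <- both[lengths[both] != file_lengths[both]]
    if (length(bad)) {
      stop(sprintf("%s: _LENGTH column disagrees with supplied lengths for: %s",
                   path, paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
    }
  }
  all_lengths <- if (is.null(lengths)) file_lengths else {
    c(lengths, file_lengths[setdiff(names(file_lengths), names(lengths))])
  }
  gold_standard(stats::setNames(genome_id, seq_id), all_lengths)
}

#' Convert a directory of per-bin FASTA files to a binning
#'
#' Some binners emit one FASTA file per predicted bin. Each file becomes a
#' bin whose id is the file basename without extension; the member sequence
#' ids are the FASTA header tokens. Sequence lengths are NOT taken from
#' these files — the gold standard governs lengths.
#'
#' @param dir Directory containing `.fa`/`.fasta`/`.fna` files (optionally
#'   gzip-compressed).
#' @param label Display label; defaults to the directory basename.
#' @return A [binning()] object.
#' @export
convert_fasta_bins_dir <- function(dir, label = basename(normalizePath(dir))) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0L) {
    stop(sprintf("%s: no FASTA files found", dir), call. = FALSE)
  }
  seq_id <- character(); bin_id <- character()
  for (f in files) {
    ids <- first_token(names(Biostrings::fasta.seqlengths(f)))
    if (length(ids) == 0L) {
      warning(sprintf("%s: empty FASTA file, bin omitted", f), call. = FALSE)
      next
    }
    bin <- sub("\\.gz$", "", basename(f), ignore.case = TRUE)
    bin <- tools::file_path_sans_ext(bin)
    clash <- intersect(ids, seq_id)
    if (length(clash)) {
      stop(sprintf("sequence id(s) present in more than one bin file: %s",
                   paste(utils::head(clash, 10L), collapse = ", ")), call. = FALSE)
    }
    seq_id <- c(seq_id, ids)
    bin_id <- c(bin_id, rep(bin, length(ids)))
  }
  if (length(seq_id) == 0L) stop(sprintf("%s: all FASTA files empty", dir), call. = FALSE)
  binning(stats::setNames(bin_id, seq_id), label = label)
}

#' Remove genomes from a gold standard
#'
#' Filters out genomes that should not enter the evaluation, such as
#' plasmids, viruses or other circular elements present in a benchmark
#' community. Each element of `exclude` is matched against genome ids
#' first as an exact id and otherwise as a regular expression. Removed
#' sequences are treated downstream as nonexistent, not as unassigned.
#'
#' @param gold A [gold_standard()] object.
#' @param exclude Character vector of genome ids or id regular expressions.
#' @return A filtered [gold_standard()] object.
#' @export
apply_exclusion_filter <- function(gold, exclude) {
  stopifnot(inherits(gold, "gold_standard"))
  if (length(exclude) == 0L) return(gold)
  genomes <- names(gold$genome_sizes)
  drop <- character()
  for (pat in exclude) {
    hit <- if (pat %in% genomes) pat else genomes[grepl(pat, genomes)]
    if (length(hit) == 0L) {
      warning(sprintf("exclusion pattern '%s' matched no genome", pat), call. = FALSE)
    }
    drop <- union(drop, hit)
  }
  if (length(drop) == length(genomes)) {
    stop("exclusion removed every genome: empty gold standard", call. = FALSE)
  }
  keep <- !(gold$assignment %in% drop)
  gold_standard(gold$assignment[keep], gold$seq_lengths[keep])
}
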