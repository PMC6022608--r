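# The metric layer: per-bin purity/contamination/completeness, the
# macro-averaged and truncated averages, base-pair-weighted purity and
# completeness, sample-wide accuracy, the adjusted Rand index of the
# assigned portion, genome recovery counts and binning rankings.
#
# All ratios are formed in double precision from exact integer bp tallies;
# choose-2 sums for the ARI are computed exactly before the final division.

#' Per-bin quality metrics
#'
#' For every predicted bin x with mapped genome g(x): purity
#' p = TP / (TP + FP) (precision — the fraction of the bin's base pairs
#' that belong to the mapped genome), completeness r = TP / (TP + FN)
#' (recall — the fraction of the mapped genome captured by the bin) and
#' contamination c = 1 - p. Genomes mapped by no bin produce no record
#' here; they enter only the average completeness denominator.
#'
#' @param ct A `bin_contingency`.
#' @param mapping A `bin_genome_mapping` built from `ct`.
#' @return A data.frame with columns `bin_id`, `mapped_genome`, `size_bp`,
#'   `purity`, `completeness`, `contamination`.
#' @export
per_bin_metrics <- function(ct, mapping) {
  stopifnot(inherits(ct, "bin_contingency"), inherits(mapping, "bin_genome_mapping"))
  bins <- names(mapping$mapped_genome)
  tp <- mapping$tp_bp
  size <- tp + mapping$fp_bp
  purity <- tp / size
  completeness <- tp / (tp + mapping$fn_bp)
  data.frame(
    bin_id = bins,
    mapped_genome = unname(mapping$mapped_genome),
    size_bp = unname(size),
    purity = unname(purity),
    completeness = unname(completeness),
    contamination = unname(1 - purity),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Macro-averaged and truncated average purity
#'
#' The average purity is the unweighted mean of per-bin purities; small
#' bins count as much as large ones. The truncated average at percentile
#' `alpha` first removes the smallest bins that together make up
#' (100 - alpha)% of the assigned base pairs: bins are sorted by size
#' descending and a bin is retained while the data preceding it is below
#' the alpha threshold, so the bin overlapping the threshold is kept, as
#' is any removed bin of the same size as the last retained one.
#'
#' @param bins Per-bin metrics data.frame from [per_bin_metrics()] (needs
#'   columns `size_bp` and `purity`).
#' @param alpha Percentile in (0, 100]; 100 disables truncation.
#' @return A list with `avg_purity`, `avg_contamination`,
#'   `truncated_avg_purity`, `n_bins`, `n_bins_truncated`, `std_error`
#'   (standard error of the mean purity over the truncated set; 0 for a
#'   single bin) and the logical `defined` (FALSE when there are no bins,
#'   in which case averages are reported as 0).
#' @export
average_purity <- function(bins, alpha = 99) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 100) {
    stop("alpha must be a single percentile in (0, 100]", call. = FALSE)
  }
  n_p <- nrow(bins)
  if (n_p == 0L) {
    return(list(avg_purity = 0, avg_contamination = 1, truncated_avg_purity = 0,
                n_bins = 0L, n_bins_truncated = 0L, std_error = 0, defined = FALSE))
  }
  p_bar <- mean(bins$purity)
  ord <- order(-bins$size_bp, bins$bin_id, method = "radix")
  size <- bins$size_bp[ord]
  purity <- bins$purity[ord]
  cum_before <- cumsum(size) - size
  keep <- cum_before < alpha / 100 * sum(size)
  keep <- keep | size == min(size[keep])
  p_alpha <- mean(purity[keep])
  se <- if (sum(keep) > 1L) stats::sd(purity[keep]) / sqrt(sum(keep)) else 0
  list(avg_purity = p_bar, avg_contamination = 1 - p_bar,
       truncated_avg_purity = p_alpha, n_bins = n_p,
       n_bins_truncated = sum(keep), std_error = se, defined = TRUE)
}

#' Average completeness per genome
#'
#' Averaged over all genomes rather than all bins: every genome mapped by
#' no bin contributes a completeness of zero, so the denominator is the
#' number of bins plus the number of unmapped genomes.
#'
#' @param bins Per-bin metrics data.frame (may have zero rows).
#' @param mapping A `bin_genome_mapping` supplying the unmapped genome set.
#' @return A list with `avg_completeness`, `n_genomes` (the denominator),
#'   and `std_error` (standard error of the mean over bin completenesses
#'   plus the implicit zeros; 0 for a single element).
#' @export
average_completeness <- function(bins, mapping) {
  stopifnot(inherits(mapping, "bin_genome_mapping"))
  n_r <- nrow(bins) + length(mapping$unmapped_genomes)
  if (n_r == 0L) return(list(avg_completeness = 0, n_genomes = 0L, std_error = 0))
  values <- c(bins$completeness, rep(0, length(mapping$unmapped_genomes)))
  se <- if (n_r > 1L) stats::sd(values) / sqrt(n_r) else 0
  list(avg_completeness = sum(bins$completeness) / n_r, n_genomes = n_r,
       std_error = se)
}

row_maxima <- function(m) if (nrow(m) == 0L) numeric() else apply(m, 1L, max)
col_maxima <- function(m) if (nrow(m) == 0L) rep(0, ncol(m)) else apply(m, 2L, max)

#' Base-pair-weighted average purity and completeness
#'
#' Size-weighted counterparts of the macro averages, so large bins
#' dominate. Purity per bp sums, over bins, the largest overlap of the bin
#' with any genome (the majority-overlap criterion, regardless of the
#' per-bin mapping in use) divided by the total assigned base pairs.
#' Completeness per bp sums, over genomes, the largest overlap of the
#' genome with any bin, divided by the total genome base pairs; genomes
#' intersecting no bin contribute zero.
#'
#' @param ct A `bin_contingency`.
#' @return A list with `avg_purity_bp` and `avg_completeness_bp`.
#' @export
per_bp_purity_completeness <- function(ct) {
  stopifnot(inherits(ct, "bin_contingency"))
  p_bp <- if (ct$total_assigned_bp > 0) sum(row_maxima(ct$cells_bp)) / ct$total_assigned_bp else 0
  r_bp <- sum(col_maxima(ct$cells_bp)) / ct$total_bp
  list(avg_purity_bp = p_bp, avg_completeness_bp = r_bp)
}

#' Sample-wide binning accuracy
#'
#' The fraction of all gold-standard base pairs in scope — including the
#' unassigned tally U — that sit in the bin mapped to their genome under
#' the majority-overlap criterion. Equals the bp-weighted purity when
#' every base pair is assigned, and is strictly smaller otherwise.
#'
#' @param ct A `bin_contingency`.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(ct) {
  stopifnot(inherits(ct, "bin_contingency"))
  sum(row_maxima(ct$cells_bp)) / (ct$unassigned_bp + ct$total_assigned_bp)
}

choose2_sum <- function(v) sum(v * (v - 1)) / 2

# Identical-partition test on the assigned portion: the contingency is a
# (permuted) diagonal — each bin meets exactly one genome and vice versa.
identical_partitions <- function(cells) {
  all(rowSums(cells > 0) == 1) && all(colSums(cells > 0) <= 1)
}

#' Adjusted Rand index of the assigned portion
#'
#' Chance-corrected agreement between the predicted bin partition and the
#' gold-standard genome partition, computed only over the assigned items:
#' base pairs left in no bin are excluded, because including them makes
#' the index meaningless for binners that deliberately leave data
#' unassigned. Interpret it together with [percentage_assigned()]. The
#' `currency` selects whether items are base pairs or whole sequences.
#' Choose-2 sums are computed exactly before the single final division.
#'
#' When fewer than two items are assigned or the index is undefined
#' (denominator zero), the value is 1 if the two partitions of the
#' assigned portion are identical and 0 otherwise.
#'
#' @param ct A `bin_contingency`.
#' @param currency `"bp"` (default) or `"seq"`.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(ct, currency = c("bp", "seq")) {
  stopifnot(inherits(ct, "bin_contingency"))
  currency <- match.arg(currency)
  cells <- if (currency == "bp") ct$cells_bp else ct$cells_seq
  m <- sum(cells)
  nm <- m * (m - 1) / 2
  s_cells <- choose2_sum(cells)
  s_rows <- choose2_sum(rowSums(cells))
  s_cols <- choose2_sum(colSums(cells))
  if (nm == 0) {
    return(if (identical_partitions(cells)) 1 else 0)
  }
  expected <- (s_rows / nm) * s_cols
  num <- s_cells - expected
  den <- (s_rows + s_cols) / 2 - expected
  if (den == 0) {
    return(if (num == 0 && identical_partitions(cells)) 1 else 0)
  }
  num / den
}

#' Fraction of the sample that was assigned to bins
#'
#' @param ct A `bin_contingency`.
#' @param currency `"bp"` (default): assigned base pairs over all
#'   gold-standard base pairs in scope; `"seq"`: assigned sequences over
#'   all gold-standard sequences.
#' @return Fraction in [0, 1].
#' @export
percentage_assigned <- function(ct, currency = c("bp", "seq")) {
  stopifnot(inherits(ct, "bin_contingency"))
  currency <- match.arg(currency)
  if (currency == "bp") ct$total_assigned_bp / ct$total_bp
  else ct$total_assigned_seq / ct$total_seq
}

#' Genome recovery counts at quality thresholds
#'
#' Counts, for every pair of thresholds, the genomes recovered by at least
#' one bin with contamination strictly below the contamination bound and
#' completeness strictly above the completeness bound. A genome is counted
#' at most once per threshold pair even if several of its bins qualify.
#' Defaults follow common practice: contamination below 5% and 10%,
#' completeness above 50%, 70% and 90%.
#'
#' @param bins Per-bin metrics data.frame from [per_bin_metrics()].
#' @param contamination_bounds Numeric vector of bounds in (0, 1).
#' @param completeness_bounds Numeric vector of bounds in (0, 1).
#' @return An integer matrix, contamination bounds in rows (named `<x%`),
#'   completeness bounds in columns (named `>y%`).
#' @export
genome_recovery_counts <- function(bins,
                                   contamination_bounds = c(0.05, 0.10),
                                   completeness_bounds = c(0.5, 0.7, 0.9)) {
  if (any(contamination_bounds <= 0 | contamination_bounds >= 1) ||
      any(completeness_bounds <= 0 | completeness_bounds >= 1)) {
    stop("recovery bounds must lie strictly inside (0, 1)", call. = FALSE)
  }
  out <- matrix(0L, length(contamination_bounds), length(completeness_bounds),
                dimnames = list(
                  paste0("<", format(contamination_bounds * 100, trim = TRUE), "%"),
                  paste0(">", format(completeness_bounds * 100, trim = TRUE), "%")))
  for (i in seq_along(contamination_bounds)) {
    for (j in seq_along(completeness_bounds)) {
      ok <- bins$contamination < contamination_bounds[i] &
        bins$completeness > completeness_bounds[j]
      out[i, j] <- length(unique(bins$mapped_genome[ok]))
    }
  }
  out
}

#' Rank binnings by a summary criterion
#'
#' Orders assessment summaries descending by truncated average purity,
#' average completeness, or their sum; ties are broken by label in byte
#' order, so the ranking is deterministic.
#'
#' @param summaries A list of `bin_assessment` objects from [evaluate_all()].
#' @param criterion One of `"purity"`, `"completeness"`,
#'   `"purity_plus_completeness"`.
#' @return A data.frame with columns `rank`, `label`, `value`.
#' @export
rank_binnings <- function(summaries,
                          criterion = c("purity", "completeness",
                                        "purity_plus_completeness")) {
  criterion <- match.arg(criterion)
  if (length(summaries) == 0L) stop("no summaries to rank", call. = FALSE)
  labels <- vapply(summaries, function(s) s$label, character(1L))
  value <- vapply(summaries, function(s) {
    switch(criterion,
           purity = s$truncated_avg_purity,
           completeness = s$avg_completeness,
           purity_plus_completeness = s$truncated_avg_purity + s$avg_completeness)
  }, numeric(1L))
  ord <- order(-value, labels, method = "radix")
  data.frame(rank = seq_along(ord), label = labels[ord], value = value[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate one binning against a gold standard
#'
#' Orchestrates the whole assessment: builds the contingency table, maps
#' bins to genomes under the chosen criterion, and computes every summary
#' metric. Deterministic: identical inputs give identical summaries.
#'
#' The bp-weighted purity, bp-weighted completeness and accuracy always
#' use the majority-overlap maxima, independent of the per-bin mapping
#' criterion selected.
#'
#' @param gold A [gold_standard()] object.
#' @param binning A [binning()] object.
#' @param alpha Truncation percentile for the average purity, in (0, 100];
#'   default 99 (the smallest bins making up 1% of assigned data removed).
#' @param mapping_criterion `"majority_overlap"` (default) or
#'   `"genome_fraction"`.
#' @param contamination_bounds,completeness_bounds Recovery thresholds,
#'   see [genome_recovery_counts()].
#' @return An object of class `bin_assessment`: all scalar metrics, the
#'   recovery count matrix, the per-bin metrics data.frame (`bin_metrics`)
#'   and the underlying contingency table and mapping.
#' @export
evaluate_all <- function(gold, binning, alpha = 99,
                         mapping_criterion = c("majority_overlap", "genome_fraction"),
                         contamination_bounds = c(0.05, 0.10),
                         completeness_bounds = c(0.5, 0.7, 0.9)) {
  mapping_criterion <- match.arg(mapping_criterion)
  ct <- build_contingency(gold, binning)
  mapping <- if (mapping_criterion == "majority_overlap") {
    map_bins_majority(ct)
  } else {
    map_bins_fraction(ct, gold)
  }
  bins <- per_bin_metrics(ct, mapping)
  pur <- average_purity(bins, alpha = alpha)
  com <- average_completeness(bins, mapping)
  bp <- per_bp_purity_completeness(ct)
  structure(list(
    label = binning$label,
    mapping_criterion = mapping_criterion,
    alpha = alpha,
    avg_purity = pur$avg_purity,
    avg_contamination = pur$avg_contamination,
    truncated_avg_purity = pur$truncated_avg_purity,
    std_error_purity = pur$std_error,
    n_bins = pur$n_bins,
    n_bins_truncated = pur$n_bins_truncated,
    avg_completeness = com$avg_completeness,
    std_error_completeness = com$std_error,
    n_genomes = com$n_genomes,
    avg_purity_bp = bp$avg_purity_bp,
    avg_completeness_bp = bp$avg_completeness_bp,
    accuracy = accuracy(ct),
    ari_bp = adjusted_rand_index(ct, "bp"),
    ari_seq = adjusted_rand_index(ct, "seq"),
    pct_assigned_bp = percentage_assigned(ct, "bp"),
    pct_assigned_seq = percentage_assigned(ct, "seq"),
    recovery_counts = genome_recovery_counts(bins, contamination_bounds,
                                             completeness_bounds),
    bin_metrics = bins,
    contingency = ct,
    mapping = mapping
  ), class = "bin_assessment")
}

#' @export
print.bin_assessment <- function(x, digits = 4, ...) {
  cat(sprintf("Assessment of '%s' (%s mapping, alpha = %g)\n",
              x$label, x$mapping_criterion, x$alpha))
  vals <- c(
    "avg purity (p)" = x$avg_purity,
    "truncated avg purity" = x$truncated_avg_purity,
    "avg completeness (r)" = x$avg_completeness,
    "avg purity per bp" = x$avg_purity_bp,
    "avg completeness per bp" = x$avg_completeness_bp,
    "accuracy" = x$accuracy,
    "ARI (bp)" = x$ari_bp,
    "ARI (seq)" = x$ari_seq,
    "% assigned (bp)" = x$pct_assigned_bp
  )
  for (nm in names(vals)) cat(sprintf("  %-24s %s\n", nm, format(round(vals[[nm]], digits))))
  cat(sprintf("  %d bins, %d genomes in scope\n", x$n_bins, x$n_genomes))
  invisible(x)
}
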