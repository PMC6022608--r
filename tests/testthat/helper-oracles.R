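# Shared oracles and generators for the suite.

# Brute-force adjusted Rand index by explicit pair enumeration over the
# assigned items. Each sequence is expanded into `weights` identical items
# (bp currency: its length; seq currency: 1), every item pair is classified
# directly, and the index is formed from the pair counts. Independent of
# the contingency-table implementation under test. Returns NA when the
# index is undefined (fewer than two items or zero denominator).
brute_force_ari <- function(bin_of, genome_of, weights) {
  idx <- rep(seq_along(bin_of), times = weights)
  b <- bin_of[idx]
  g <- genome_of[idx]
  n <- length(b)
  if (n < 2L) return(NA_real_)
  same_bin <- outer(b, b, "==")
  same_genome <- outer(g, g, "==")
  ut <- upper.tri(same_bin)
  tp <- sum(same_bin & same_genome & ut)
  pairs_same_bin <- sum(same_bin & ut)
  pairs_same_genome <- sum(same_genome & ut)
  n_pairs <- n * (n - 1) / 2
  expected <- pairs_same_bin * pairs_same_genome / n_pairs
  den <- (pairs_same_bin + pairs_same_genome) / 2 - expected
  if (den == 0) return(NA_real_)
  (tp - expected) / den
}

# Small random benchmark instance: a gold standard of <= max_genomes
# genomes over <= max_seq sequences with short lengths, and a binning that
# assigns a random subset of the sequences to <= max_bins bins.
random_instance <- function(seed, max_seq = 30L, max_genomes = 5L,
                            max_bins = 5L, len_range = c(1L, 10L)) {
  set.seed(seed)
  n <- sample(4:max_seq, 1L)
  ng <- sample(1:max_genomes, 1L)
  nb <- sample(1:max_bins, 1L)
  ids <- sprintf("s%03d", seq_len(n))
  genome_of <- stats::setNames(sample(sprintf("g%d", 1:ng), n, replace = TRUE), ids)
  lens <- stats::setNames(sample(len_range[1]:len_range[2], n, replace = TRUE), ids)
  gold <- gold_standard(genome_of, lens)
  assigned <- stats::runif(n) < 0.8
  if (!any(assigned)) assigned[1L] <- TRUE
  bin_of <- stats::setNames(sample(sprintf("b%d", 1:nb), sum(assigned), replace = TRUE),
                            ids[assigned])
  list(gold = gold, binning = binning(bin_of, label = sprintf("rand%d", seed)))
}

# Random binning over arbitrary ids, for format round-trip checks.
random_binning <- function(seed, n = 20L) {
  set.seed(seed)
  ids <- sprintf("ctg_%d_%04d", seed, sample.int(9999L, n))
  bins <- sprintf("bin%02d", sample.int(8L, n, replace = TRUE))
  binning(stats::setNames(bins, ids), label = sprintf("rt%d", seed))
}

expect_file_bytes_equal <- function(a, b) {
  expect_identical(readBin(a, "raw", file.info(a)$size),
                   readBin(b, "raw", file.info(b)$size))
}
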