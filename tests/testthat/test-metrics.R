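# Per-bin metrics, averages, truncation, bp-weighted metrics, accuracy,
# ARI, recovery counts and rankings.

f1_summary <- function(...) {
  f <- fixture_f1()
  evaluate_all(f$gold, f$binning, ...)
}

test_that("per-bin purity and completeness match the hand derivation", {
  f <- fixture_f1()
  ct <- build_contingency(f$gold, f$binning)
  bins <- per_bin_metrics(ct, map_bins_majority(ct))
  x <- bins[bins$bin_id == "X", ]
  y <- bins[bins$bin_id == "Y", ]
  expect_equal(x$purity, 2 / 3)
  expect_equal(x$completeness, 1)
  expect_equal(x$contamination, 1 / 3)
  expect_equal(y$purity, 1)
  expect_equal(y$completeness, 1 / 2)
  expect_equal(bins$purity + bins$contamination, rep(1, 2))
})

test_that("macro averages and their complements match the worked example", {
  s <- f1_summary(alpha = 100)
  expect_equal(s$avg_purity, 5 / 6)
  expect_equal(s$avg_contamination, 1 / 6)
  expect_equal(s$truncated_avg_purity, 5 / 6)
  expect_equal(s$avg_completeness, 0.5)  # (1 + 0.5 + 0 for unmapped C) / 3
  expect_equal(s$n_genomes, 3L)
})

test_that("truncation removes the smallest bins up to the percentile", {
  bins <- data.frame(bin_id = c("big", "mid", "tiny"),
                     size_bp = c(97, 2, 1),
                     purity = c(1.0, 0.5, 0.0))
  res99 <- average_purity(bins, alpha = 99)
  expect_equal(res99$avg_purity, 0.5)
  expect_equal(res99$truncated_avg_purity, 0.75)
  expect_equal(res99$n_bins_truncated, 2L)
  res100 <- average_purity(bins, alpha = 100)
  expect_equal(res100$truncated_avg_purity, res100$avg_purity)

  # the bin overlapping the threshold is retained, as are equal-sized bins
  ties <- data.frame(bin_id = c("a", "b", "c", "d"),
                     size_bp = c(94, 2, 2, 2),
                     purity = c(1, 0, 0, 0))
  res <- average_purity(ties, alpha = 99)
  expect_equal(res$n_bins_truncated, 4L)

  expect_error(average_purity(bins, alpha = 0), "alpha")
  expect_error(average_purity(bins, alpha = 101), "alpha")
})

test_that("alpha-100 truncation is the identity on random instances", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    ct <- build_contingency(inst$gold, inst$binning)
    bins <- per_bin_metrics(ct, map_bins_majority(ct))
    res <- average_purity(bins, alpha = 100)
    expect_identical(res$truncated_avg_purity, res$avg_purity)
    expect_identical(res$n_bins_truncated, res$n_bins)
  }
})

test_that("single-bin and empty-binning conventions hold", {
  one <- data.frame(bin_id = "b", size_bp = 10, purity = 0.8)
  res <- average_purity(one, alpha = 99)
  expect_equal(res$truncated_avg_purity, 0.8)
  expect_equal(res$std_error, 0)

  none <- data.frame(bin_id = character(), size_bp = numeric(),
                     purity = numeric(), completeness = numeric())
  resp <- average_purity(none)
  expect_false(resp$defined)
  expect_equal(resp$avg_purity, 0)
  fake_mapping <- structure(list(unmapped_genomes = c("g1", "g2", "g3")),
                            class = "bin_genome_mapping")
  resc <- average_completeness(none, fake_mapping)
  expect_equal(resc$avg_completeness, 0)
  expect_equal(resc$n_genomes, 3L)
})

test_that("bp-weighted metrics and accuracy match the worked example", {
  f <- fixture_f1()
  ct <- build_contingency(f$gold, f$binning)
  bp <- per_bp_purity_completeness(ct)
  expect_equal(bp$avg_purity_bp, 0.75)          # (100 + 50) / 200
  expect_equal(bp$avg_completeness_bp, 150 / 230)
  expect_equal(accuracy(ct), 150 / 230)         # 150 / (30 + 200)
  expect_equal(percentage_assigned(ct, "bp"), 200 / 230)
  expect_equal(percentage_assigned(ct, "seq"), 4 / 5)
})

test_that("everything merged into one bin halves bp purity but not bp completeness", {
  gold <- gold_standard(c(u1 = "g1", v1 = "g2"), c(u1 = 100, v1 = 100))
  b <- binning(c(u1 = "all", v1 = "all"), label = "merged")
  ct <- build_contingency(gold, b)
  bp <- per_bp_purity_completeness(ct)
  expect_equal(bp$avg_purity_bp, 0.5)
  expect_equal(bp$avg_completeness_bp, 1.0)
})

test_that("ARI on the worked example matches the exact binomial-sum arithmetic", {
  f <- fixture_f1()
  ct <- build_contingency(f$gold, f$binning)
  expected_bp <- (7400 - 12400 * 9900 / 19900) /
    (0.5 * (12400 + 9900) - 12400 * 9900 / 19900)
  expect_equal(adjusted_rand_index(ct, "bp"), expected_bp, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(ct, "seq"), 0)
})

test_that("ARI is exactly 1 for perfect binnings and handles degenerate cases", {
  gold <- generate_gold_standard(4, c(2L, 3L), c(10L, 50L), seed = 3)
  perfect <- perturb_binning(gold, degradation_spec(seed = 3))
  ct <- build_contingency(gold, perfect)
  expect_identical(adjusted_rand_index(ct, "bp"), 1)
  expect_identical(adjusted_rand_index(ct, "seq"), 1)

  # one bin over one genome: undefined denominator, identical partitions
  g1 <- gold_standard(c(s1 = "g", s2 = "g"), c(s1 = 5, s2 = 5))
  b1 <- binning(c(s1 = "b", s2 = "b"), label = "one")
  ct1 <- build_contingency(g1, b1)
  expect_identical(adjusted_rand_index(ct1, "seq"), 1)

  # a single assigned sequence: fewer than two seq items
  g2 <- gold_standard(c(s1 = "g", s2 = "h"), c(s1 = 5, s2 = 5))
  b2 <- binning(c(s1 = "b"), label = "single")
  ct2 <- build_contingency(g2, b2)
  expect_identical(adjusted_rand_index(ct2, "seq"), 1)
})

test_that("the closed-form ARI agrees with brute-force pair counting", {
  skipped <- 0L
  for (seed in 1:60) {
    inst <- random_instance(seed)
    ct <- build_contingency(inst$gold, inst$binning)
    common <- names(inst$binning$assignment)
    common <- common[common %in% names(inst$gold$assignment)]
    bin_of <- unname(inst$binning$assignment[common])
    genome_of <- unname(inst$gold$assignment[common])
    lens <- unname(inst$gold$seq_lengths[common])
    for (currency in c("bp", "seq")) {
      w <- if (currency == "bp") lens else rep(1L, length(common))
      oracle <- brute_force_ari(bin_of, genome_of, w)
      if (is.na(oracle)) { skipped <- skipped + 1L; next }
      expect_equal(adjusted_rand_index(ct, currency), oracle, tolerance = 1e-9)
    }
  }
  expect_lt(skipped, 30L)
})

test_that("recovery counting uses strict bounds and counts genomes once", {
  s <- f1_summary()
  # bin X fails contamination < 0.10; bin Y sits exactly at completeness 0.5
  expect_true(all(s$recovery_counts == 0L))

  gold <- generate_gold_standard(3, c(2L, 3L), c(10L, 50L), seed = 11)
  perfect <- perturb_binning(gold, degradation_spec(seed = 11))
  sp <- evaluate_all(gold, perfect)
  expect_true(all(sp$recovery_counts == 3L))

  # two qualifying bins on the same genome count it once
  g <- gold_standard(c(x1 = "g", x2 = "g", y1 = "h"),
                     c(x1 = 60, x2 = 60, y1 = 100))
  b <- binning(c(x1 = "b1", x2 = "b2", y1 = "b3"), label = "dupbins")
  ct <- build_contingency(g, b)
  bins <- per_bin_metrics(ct, map_bins_majority(ct))
  rc <- genome_recovery_counts(bins, 0.05, 0.4)
  expect_equal(unname(rc[1, 1]), 2L)

  expect_error(genome_recovery_counts(bins, 0, 0.5), "bounds")
  expect_error(genome_recovery_counts(bins, 0.05, 1), "bounds")
})

test_that("rankings order by the criterion with label tie-breaks", {
  mk <- function(label, p, r) {
    structure(list(label = label, truncated_avg_purity = p, avg_completeness = r),
              class = "bin_assessment")
  }
  # dyadic fractions so the three sums tie exactly at 1.25
  s <- list(mk("zeta", 0.5, 0.75), mk("alpha", 0.75, 0.5), mk("mid", 0.625, 0.625))
  expect_equal(rank_binnings(s, "purity")$label, c("alpha", "mid", "zeta"))
  expect_equal(rank_binnings(s, "completeness")$label, c("zeta", "mid", "alpha"))
  # all sums tie: byte-order label sort decides
  expect_equal(rank_binnings(s, "purity_plus_completeness")$label,
               c("alpha", "mid", "zeta"))
  # brute-force sort oracle
  rk <- rank_binnings(s, "purity_plus_completeness")
  vals <- vapply(s, function(x) x$truncated_avg_purity + x$avg_completeness, 0)
  expect_equal(rk$value, sort(vals, decreasing = TRUE))
})

test_that("summary-level invariants hold across random instances", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    s <- suppressWarnings(evaluate_all(inst$gold, inst$binning))
    expect_equal(s$avg_contamination, 1 - s$avg_purity)
    expect_lte(s$accuracy, s$avg_purity_bp + 1e-12)
    if (s$pct_assigned_bp == 1) expect_equal(s$accuracy, s$avg_purity_bp)
    # completenesses of bins mapped to one genome sum to at most 1
    agg <- tapply(s$bin_metrics$completeness, s$bin_metrics$mapped_genome, sum)
    expect_true(all(agg <= 1 + 1e-12))
    ok <- c(s$avg_purity, s$truncated_avg_purity, s$avg_completeness,
            s$avg_purity_bp, s$avg_completeness_bp, s$accuracy,
            s$pct_assigned_bp, s$pct_assigned_seq)
    expect_true(all(ok >= 0 & ok <= 1))
  }
})

test_that("unassigning sequences never raises pct assigned nor touches other bins", {
  inst <- random_instance(101, max_seq = 30L)
  b <- inst$binning
  s_full <- suppressWarnings(evaluate_all(inst$gold, b))
  # drop all sequences of one bin (or half the sequences if there is one bin)
  victims <- if (length(unique(b$assignment)) > 1L) {
    names(b$assignment)[b$assignment == b$assignment[[1]]]
  } else {
    utils::head(names(b$assignment), length(b$assignment) %/% 2)
  }
  reduced <- binning(b$assignment[setdiff(names(b$assignment), victims)],
                     label = b$label)
  s_red <- suppressWarnings(evaluate_all(inst$gold, reduced))
  expect_lte(s_red$pct_assigned_bp, s_full$pct_assigned_bp)
  keep <- intersect(s_red$bin_metrics$bin_id, s_full$bin_metrics$bin_id)
  expect_equal(s_red$bin_metrics$purity[match(keep, s_red$bin_metrics$bin_id)],
               s_full$bin_metrics$purity[match(keep, s_full$bin_metrics$bin_id)])
})

test_that("evaluation is deterministic", {
  s1 <- f1_summary()
  s2 <- f1_summary()
  expect_identical(s1, s2)
})
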