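test_that("two_locus_counts counts the four gametes", {
  mat <- cbind(c(0, 0, 1, 1, 1, 0), c(0, 1, 0, 1, 1, 0))
  p <- toy_panel(mat)
  ct <- two_locus_counts(p, 1, 2)
  expect_equal(ct$n00, 2)
  expect_equal(ct$n01, 1)
  expect_equal(ct$n10, 1)
  expect_equal(ct$n11, 2)
  expect_error(two_locus_counts(p, 1, 1), "distinct")
  expect_error(two_locus_counts(p, 1, 9), "range")
})

test_that("ld_stats matches the frequency-formula oracle to 1e-12", {
  set.seed(11)
  mat <- matrix(rbinom(20 * 12, 1, 0.5), nrow = 20)
  p <- toy_panel(mat)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      st <- ld_stats(two_locus_counts(p, i, j))
      if (!st$informative) next
      or <- oracle_ld(p, i, j)
      expect_equal(st$D, or$D, tolerance = 1e-12)
      expect_equal(st$Dprime, or$Dprime, tolerance = 1e-12)
      expect_equal(st$r2, or$r2, tolerance = 1e-12)
      expect_gte(st$Dprime, 0)
      expect_lte(st$Dprime, 1 + 1e-12)
    }
  }
})

test_that("monomorphic pairs are uninformative", {
  mat <- cbind(rep(0, 6), c(0, 1, 0, 1, 0, 1))
  p <- toy_panel(mat)
  st <- ld_stats(two_locus_counts(p, 1, 2))
  expect_false(st$informative)
  expect_true(is.na(st$Dprime))
  ci <- dprime_ci(two_locus_counts(p, 1, 2))
  expect_false(ci$informative)
})

test_that("dprime_ci agrees with an independent grid-likelihood oracle", {
  cases <- list(
    c(30, 5, 4, 21), c(10, 10, 10, 10), c(50, 1, 0, 49),
    c(3, 17, 18, 2), c(25, 0, 0, 25), c(40, 7, 12, 1),
    c(2, 2, 2, 94), c(60, 20, 15, 5)
  )
  for (cs in cases) {
    counts <- list(n00 = cs[1], n01 = cs[2], n10 = cs[3], n11 = cs[4])
    got <- dprime_ci(counts)
    or <- oracle_dprime_ci(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$ci_low, or$lo, tolerance = 1e-12,
                 label = paste(cs, collapse = ","))
    expect_equal(got$ci_high, or$hi, tolerance = 1e-12)
    expect_gte(got$ci_high, got$ci_low)
  }
})

test_that("perfect LD yields a tight high CI; equilibrium does not", {
  perfect <- list(n00 = 50, n01 = 0, n10 = 0, n11 = 50)
  eq <- list(n00 = 25, n01 = 25, n10 = 25, n11 = 25)
  ci_p <- dprime_ci(perfect)
  ci_e <- dprime_ci(eq)
  expect_gte(ci_p$ci_low, 0.9)
  expect_equal(ci_p$ci_high, 1)
  expect_lt(ci_e$ci_high, 0.5)
})

test_that("classify_pair implements the Gabriel thresholds", {
  expect_equal(
    classify_pair(list(informative = TRUE, ci_low = 0.70, ci_high = 0.98)),
    "strong_ld"
  )
  expect_equal(
    classify_pair(list(informative = TRUE, ci_low = 0.69, ci_high = 1)),
    "inconclusive"
  )
  expect_equal(
    classify_pair(list(informative = TRUE, ci_low = 0.1, ci_high = 0.89)),
    "strong_recombination"
  )
  expect_equal(
    classify_pair(list(informative = TRUE, ci_low = 0.1, ci_high = 0.95)),
    "inconclusive"
  )
  expect_equal(classify_pair(list(informative = FALSE)), "uninformative")
})

test_that("detect_core_regions matches the exhaustive-interval oracle", {
  panels <- list(block_panel())
  set.seed(42)
  for (k in 1:3) {
    base <- rbind(matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), 6), nrow = 6,
                         byrow = TRUE),
                  matrix(rbinom(6 * 8, 1, 0.5), nrow = 6))
    panels[[k + 1]] <- toy_panel(base, pos = sort(sample(1e5, 8)))
  }
  for (p in panels) {
    got <- detect_core_regions(p)
    want <- oracle_blocks(p)
    expect_equal(got$first_idx, want$first_idx)
    expect_equal(got$last_idx, want$last_idx)
  }
})

test_that("block detection on the structured panel finds the two blocks", {
  p <- block_panel()
  regions <- detect_core_regions(p)
  expect_equal(nrow(regions), 2)
  expect_equal(regions$first_idx, c(1L, 7L))
  expect_equal(regions$last_idx, c(4L, 10L))
  expect_equal(regions$n_snps, c(4L, 4L))
  expect_equal(regions$length_kb, c(3, 3))
})

test_that("regions never overlap and respect the span cap", {
  set.seed(7)
  mat <- matrix(rbinom(30 * 40, 1, 0.5), nrow = 30)
  mat[, 11:16] <- mat[, 11]  # a perfect 6-marker block
  p <- toy_panel(mat, pos = sort(sample(5e6, 40)))
  regions <- detect_core_regions(p, max_pair_span_bp = 2e5)
  if (nrow(regions) > 1) {
    expect_true(all(regions$first_idx[-1] > regions$last_idx[-nrow(regions)]))
  }
  expect_true(all(regions$end_pos - regions$start_pos <= 2e5))
})

test_that("summarize_core_regions totals reconcile", {
  set.seed(3)
  mat <- matrix(rbinom(20 * 30, 1, 0.4), nrow = 20)
  mat[, 5:8] <- mat[, 5]
  mat[, 20:22] <- mat[, 20]
  pos <- c(sort(sample(1e6, 15)), sort(sample(1e6, 15)))
  p <- toy_panel(mat, pos = pos, chrom = rep(c("1", "2"), each = 15))
  regions <- detect_core_regions(p)
  summ <- summarize_core_regions(regions, p)
  tot <- summ[summ$chrom == "total", ]
  per <- summ[summ$chrom != "total", ]
  expect_equal(tot$n_cr, sum(per$n_cr))
  expect_equal(tot$n_snp, sum(per$n_snp))
  expect_equal(tot$cr_snps, sum(per$cr_snps))
  expect_equal(tot$n_cr, nrow(regions))
  expect_equal(tot$cr_snps, sum(regions$n_snps))
})
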