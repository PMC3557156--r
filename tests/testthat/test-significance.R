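test_that("equal-width binning maps frequency to the documented bin", {
  rec <- data.frame(frequency = c(0.02, 0.05, 0.051, 0.5, 0.951, 1.0))
  got <- bin_by_frequency(rec, n_bins = 20, scheme = "width")
  expect_equal(got$bin_index, c(0L, 0L, 1L, 9L, 19L, 19L))
  # every record in exactly one bin, counts reconcile
  expect_equal(sum(table(got$bin_index)), nrow(rec))
})

test_that("equal-count binning balances members", {
  set.seed(2)
  rec <- data.frame(frequency = runif(200, 0.02, 0.98))
  got <- bin_by_frequency(rec, n_bins = 20, scheme = "count")
  counts <- table(got$bin_index)
  expect_equal(sum(counts), 200)
  expect_lte(max(counts) - min(counts), 6)
})

test_that("empirical_p is the inclusive within-bin rank", {
  rec <- data.frame(frequency = rep(0.5, 5), rehh = c(1, 2, 3, 4, 5))
  rec <- bin_by_frequency(rec, scheme = "width")
  got <- empirical_p(rec)
  expect_equal(got$p_value[got$rehh == 5], 0.2)
  expect_equal(got$p_value[got$rehh == 1], 1)
  expect_equal(got$p_value[got$rehh == 3], 0.6)

  ties <- data.frame(frequency = rep(0.5, 4), rehh = c(2, 2, 2, 2))
  ties <- bin_by_frequency(ties, scheme = "width")
  expect_equal(empirical_p(ties)$p_value, rep(1, 4))
})

test_that("singleton bins yield p = 1 with a warning", {
  rec <- data.frame(frequency = c(0.1, 0.9), rehh = c(2, 3))
  rec <- bin_by_frequency(rec, scheme = "width")
  expect_warning(got <- empirical_p(rec), "singleton")
  expect_equal(got$p_value, c(1, 1))
})

test_that("lognormal_p gives an upper-tail normal probability", {
  set.seed(4)
  vals <- exp(rnorm(50))
  rec <- data.frame(frequency = rep(0.5, 50), rehh = vals)
  rec <- bin_by_frequency(rec, scheme = "width")
  got <- lognormal_p(rec)
  mu <- mean(log(vals))
  sdv <- sd(log(vals))
  expect_equal(got$p_value,
               pnorm(log(vals), mu, sdv, lower.tail = FALSE),
               tolerance = 1e-12)
  # monotone: larger REHH, smaller p
  o <- order(vals)
  expect_true(all(diff(got$p_value[o]) <= 0))
})

test_that("genome_scan outputs reconcile across tables", {
  set.seed(31)
  p <- simulate_neutral(
    sweep_sim_params(pop_size = 60, n_haplotypes = 60,
                     chrom_length_bp = 2e6, target_n_snps = 120,
                     n_generations = 10, n_founders = 24),
    seed = 31
  )
  sc <- genome_scan(p, scan_config(bin_scheme = "count"))
  r <- sc$records
  expect_true(nrow(r) > 0)
  # per-chromosome counts sum to totals
  pc <- sc$per_chrom
  tot <- pc[pc$chrom == "total", ]
  per <- pc[pc$chrom != "total", ]
  expect_equal(tot$n_tests, sum(per$n_tests))
  expect_equal(tot$p_lt_05, sum(per$p_lt_05))
  expect_equal(tot$p_lt_alpha, sum(per$p_lt_alpha))
  # significant table is exactly the records at the cut with p < alpha
  at_cut <- r[!is.na(r$p_value) &
                r$frequency >= sc$config$min_report_frequency, ]
  expect_equal(nrow(sc$significant),
               sum(at_cut$p_value < sc$config$alpha))
  # every scored record's REHH is ehh_t / ehh_bar
  ok <- r[r$status %in% c("ok", "truncated_end") & !is.na(r$rehh), ]
  expect_equal(ok$rehh, ok$ehh_t / ok$ehh_bar)
  # frequencies are carrier_count / H
  expect_equal(ok$frequency, ok$carrier_count / nrow(p$haplotypes))
  # BH column: present, valid adjustment, and never driving the flag
  expect_true("p_bh" %in% names(r))
  defined <- !is.na(r$p_value)
  expect_equal(r$p_bh, p.adjust(r$p_value, method = "BH"))
  expect_true(all(r$p_bh[defined] >= r$p_value[defined]))
  expect_equal(r$significant,
               !is.na(r$p_value) & r$p_value < sc$config$alpha)
})

test_that("empty region set produces empty outputs with a warning", {
  mat <- matrix(rbinom(20 * 4, 1, 0.5), nrow = 20)
  p <- toy_panel(mat, pos = c(1e5, 9e5, 1.8e6, 2.9e6))
  expect_warning(sc <- genome_scan(p, scan_config()), "region|empty")
  expect_equal(nrow(sc$records), 0)
  expect_equal(nrow(sc$significant), 0)
})

test_that("scan_report writes four stable TSVs", {
  set.seed(33)
  p <- simulate_neutral(
    sweep_sim_params(pop_size = 60, n_haplotypes = 60,
                     chrom_length_bp = 2e6, target_n_snps = 120,
                     n_generations = 10, n_founders = 24),
    seed = 33
  )
  sc <- genome_scan(p, scan_config(bin_scheme = "count"))
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  scan_report(sc, d1)
  scan_report(sc, d2)
  for (f in c("tests.tsv", "per_chrom_counts.tsv",
              "significant_regions.tsv", "manhattan.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  tests <- read.table(file.path(d1, "tests.tsv"), header = TRUE,
                      sep = "\t", colClasses = "character")
  expect_equal(nrow(tests), nrow(sc$records))
  # rounding contract: two decimals for REHH
  expect_true(all(grepl("^(NA|-?[0-9]+\\.[0-9]{2})$", tests$rehh)))
  expect_true(all(grepl("^(NA|[0-9]+\\.[0-9]{4})$", tests$p_value)))
})
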