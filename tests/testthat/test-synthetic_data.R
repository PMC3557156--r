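small_params <- function(...) {
  sweep_sim_params(pop_size = 60, n_haplotypes = 60, chrom_length_bp = 2e6,
                   target_n_snps = 120, n_generations = 10,
                   n_founders = 24, ...)
}

# Sweep-mode tests need a chromosome longer than the +/- 2 Mb injection
# window (so background diversity survives the carrier overwrite) and a
# deeper founder pool.
sweep_params <- function(...) {
  sweep_sim_params(pop_size = 100, n_haplotypes = 80, chrom_length_bp = 5e6,
                   target_n_snps = 150, n_generations = 10,
                   n_founders = 64, ...)
}

test_that("simulate_neutral is deterministic and panel-valid", {
  p1 <- simulate_neutral(small_params(), seed = 5)
  p2 <- simulate_neutral(small_params(), seed = 5)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$markers, p2$markers)
  p3 <- simulate_neutral(small_params(), seed = 6)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
  expect_silent(validate_panel(p1))
  expect_equal(nrow(p1$haplotypes), 60)
  # MAF floor respected
  expect_true(all(allele_frequencies(p1)$maf >= 0.05))
})

test_that("neutral panels keep multi-chromosome structure", {
  p <- simulate_neutral(small_params(n_chromosomes = 3), seed = 8)
  expect_equal(sort(unique(p$markers$chrom)), c("1", "2", "3"))
  for (chr in c("1", "2", "3")) {
    pos <- p$markers$pos[p$markers$chrom == chr]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1 & pos <= 2e6))
  }
})

test_that("pairwise r2 decays with distance on a neutral panel", {
  p <- simulate_neutral(
    sweep_sim_params(pop_size = 500, n_haplotypes = 100,
                     chrom_length_bp = 5e6, target_n_snps = 225,
                     n_generations = 10, n_founders = 64),
    seed = 470
  )
  pl <- pairwise_ld(p, "1", max_pair_span_bp = 2e6)
  pos <- p$markers$pos
  d <- pos[pl$j] - pos[pl$i]
  ok <- !is.na(pl$r2)
  dec <- cut(d[ok], quantile(d[ok], seq(0, 1, 0.1)), include.lowest = TRUE)
  m <- tapply(pl$r2[ok], dec, mean)
  # monotone trend: first-decile LD clearly above last, rank correlation < 0
  expect_gt(m[1], m[10])
  expect_lt(cor(seq_along(m), m, method = "spearman"), -0.5)
})

test_that("simulate_sweep raises the focal frequency and records truth", {
  params <- sweep_params(
    sweep = list(selection_coefficient = 0.5, start_frequency = 0.1)
  )
  finals <- vapply(1:8, function(s) {
    sim <- simulate_sweep(params, s)
    expect_equal(sim$truth$focal_chrom, "1")
    foc <- sim$truth$focal_pos
    expect_true(sim$truth$focal_marker_id %in% sim$panel$markers$id)
    idx <- match(sim$truth$focal_marker_id, sim$panel$markers$id)
    expect_equal(mean(sim$panel$haplotypes[, idx]),
                 sim$truth$focal_final_frequency)
    sim$truth$focal_final_frequency
  }, numeric(1))
  # selection pushes frequency up from 0.1 in a large majority of seeds
  expect_gte(mean(finals > 0.1), 0.75)
})

test_that("s = 0 sweep frequencies behave like drift around the start", {
  params <- sweep_params(
    sweep = list(selection_coefficient = 0, start_frequency = 0.3)
  )
  finals <- vapply(1:12, function(s) {
    simulate_sweep(params, s)$truth$focal_final_frequency
  }, numeric(1))
  # no systematic pull: mean within 3 SE of the start frequency
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 3 * se + 0.05)
})

test_that("final_frequency_range conditioning is honored", {
  params <- sweep_params(
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.2,
                 final_frequency_range = c(0.35, 0.9))
  )
  for (s in 1:4) {
    sim <- simulate_sweep(params, s)
    expect_gt(sim$truth$focal_final_frequency, 0.35)
    expect_lt(sim$truth$focal_final_frequency, 0.9)
  }
})

test_that("swept EHH beats frequency-matched neutral EHH at 500 kb", {
  n_pairs <- 12
  wins <- 0L
  for (s in seq_len(n_pairs)) {
    params <- sweep_sim_params(
      pop_size = 200, n_haplotypes = 100, chrom_length_bp = 3e6,
      target_n_snps = 140, n_generations = 10, n_founders = 64,
      sweep = list(selection_coefficient = 0.1, start_frequency = 0.2,
                   final_frequency_range = c(0.3, 0.9))
    )
    sim <- simulate_sweep(params, s)
    idx <- match(sim$truth$focal_marker_id, sim$panel$markers$id)
    region <- region_row(sim$panel, idx, idx)
    f <- sim$truth$focal_final_frequency
    ehh_sw <- ehh_at_distance(sim$panel, region, "1", 5e5)

    neu <- simulate_neutral(
      sweep_sim_params(pop_size = 200, n_haplotypes = 100,
                       chrom_length_bp = 3e6, target_n_snps = 140,
                       n_generations = 10, n_founders = 64),
      seed = 1000 + s
    )
    freq1 <- colMeans(neu$haplotypes)
    match_f <- pmin(abs(freq1 - f), abs(1 - freq1 - f))
    cand <- which(match_f < 0.1 & neu$markers$pos > 7e5 &
                    neu$markers$pos < 2.3e6)
    if (length(cand) == 0) next
    j <- cand[which.min(match_f[cand])]
    allele <- if (abs(freq1[j] - f) <= abs(1 - freq1[j] - f)) "1" else "0"
    region_n <- region_row(neu, j, j)
    ehh_ne <- ehh_at_distance(neu, region_n, allele, 5e5)
    if (is.na(ehh_sw) || is.na(ehh_ne)) next
    if (ehh_sw > ehh_ne) wins <- wins + 1L
  }
  expect_gt(wins / n_pairs, 0.5)
})

test_that("make_two_line_panel shares the marker map and diverges", {
  params <- sweep_sim_params(
    pop_size = 100, n_haplotypes = 60, chrom_length_bp = 3e6,
    target_n_snps = 140, n_generations = 15, n_founders = 32,
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.3)
  )
  tl <- make_two_line_panel(params, 4)
  expect_identical(tl$panel_up$markers[, c("chrom", "pos")],
                   tl$panel_down$markers[, c("chrom", "pos")])
  expect_equal(tl$panel_up$line_label, "up")
  expect_equal(tl$panel_down$line_label, "down")
  idx <- match(tl$truth$focal_marker_id, tl$panel_up$markers$id)
  fa <- mean(tl$panel_up$haplotypes[, idx])
  fb <- mean(tl$panel_down$haplotypes[, idx])
  expect_equal(unname(tl$truth$line_divergence["up"]), fa)
  expect_equal(unname(tl$truth$line_divergence["down"]), fb)
  # opposite-sign selection separates the lines at the focal site
  expect_gt(fa, fb)
})

test_that("two-line generation requires a single chromosome", {
  params <- small_params(
    n_chromosomes = 2,
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.3)
  )
  expect_error(make_two_line_panel(params, 1), "single|one chromosome")
})

test_that("focal loss exhausts retries with an informative error", {
  params <- small_params(
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.3,
                 final_frequency_range = c(0.999, 1))
  )
  expect_error(simulate_sweep(params, 1), "frequency|attempts")
})
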