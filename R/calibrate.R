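# Calibration studies: type-I error, sweep recovery power, two-line contrast
# null, and line-divergence checks on synthetic panels. The study conditions
# returned by calibration_design() are fixed design choices of the package;
# they are shared by the test suite and the acceptance script so that both
# evaluate the same experiment.

#' Frozen calibration study designs
#'
#' Returns the parameter sets used by the package's calibration studies.
#' `neutral` drives the type-I error study, `sweep` the sweep-recovery power
#' study, and `two_line` the contrast calibration. Multi-chromosome genomes
#' are used so that the ~2000 scored tests give 20 equal-count frequency bins
#' of >100 members each, the minimum resolution at which an empirical rank
#' p-value can fall below 0.01.
#'
#' @return A list with elements `neutral`, `sweep`, `two_line` (each a
#'   [sweep_sim_params()] object) and `scan` / `scan_lognormal`
#'   ([scan_config()] objects).
#' @export
calibration_design <- function() {
  neutral <- sweep_sim_params(
    pop_size = 500, n_haplotypes = 200, n_chromosomes = 10,
    chrom_length_bp = 5e6, target_n_snps = 225, n_founders = 100,
    n_generations = 10
  )
  sweep <- sweep_sim_params(
    pop_size = 500, n_haplotypes = 200, n_chromosomes = 10,
    chrom_length_bp = 5e6, target_n_snps = 225, n_founders = 100,
    n_generations = 10,
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.3,
                 final_frequency_range = c(0.4, 0.8))
  )
  two_line <- sweep_sim_params(
    pop_size = 500, n_haplotypes = 200, n_chromosomes = 1,
    chrom_length_bp = 5e6, target_n_snps = 225, n_founders = 100,
    n_generations = 10,
    sweep = list(selection_coefficient = 0.1, start_frequency = 0.3)
  )
  list(
    neutral = neutral,
    sweep = sweep,
    two_line = two_line,
    scan = scan_config(bin_scheme = "count", max_pair_span_bp = 1.2e6),
    scan_lognormal = scan_config(bin_scheme = "count", p_mode = "lognormal",
                                 max_pair_span_bp = 1.2e6)
  )
}

#' Type-I error of the scan on a neutral panel
#'
#' Simulates a neutral multi-chromosome genome, scans it, and reports the
#' fraction of scored tests with empirical p below `alpha`. Under the null
#' the within-bin rank p-values are (discretely) uniform, so the fraction is
#' expected to be close to `alpha`, up to the rank discreteness (p cannot
#' fall strictly below `alpha` for more than `floor(alpha * n)` members of a
#' bin of size n).
#'
#' @param seed Integer seed for the simulation.
#' @param alpha Significance threshold (default 0.01).
#' @param params Simulation parameters; defaults to
#'   `calibration_design()$neutral`.
#' @param config Scan configuration; defaults to `calibration_design()$scan`.
#' @return A list with `n_tests`, `n_significant`, `rate`, `expected`,
#'   `tolerance` (three binomial standard deviations plus one count of
#'   slack for rank discreteness) and `within_tolerance`.
#' @export
evaluate_type_i_error <- function(seed, alpha = 0.01, params = NULL,
                                  config = NULL) {
  design <- calibration_design()
  if (is.null(params)) params <- design$neutral
  if (is.null(config)) config <- design$scan
  panel <- simulate_neutral(params, seed)
  scan <- genome_scan(panel, config)
  p <- scan$records$p_value
  p <- p[!is.na(p)]
  n <- length(p)
  n_sig <- sum(p < alpha)
  tol <- 3 * sqrt(n * alpha * (1 - alpha)) + 1
  list(n_tests = n, n_significant = n_sig, rate = n_sig / n,
       expected = n * alpha, tolerance = tol,
       within_tolerance = abs(n_sig - n * alpha) <= tol)
}

#' Sweep-recovery power study
#'
#' For each seed, simulates a genome containing one selective sweep and asks
#' whether a core region overlapping the true focal position appears in the
#' scan's significant table (p < alpha and core haplotype frequency at or
#' above the reporting floor). The log-normal p-mode is used so that the
#' several adjacent core regions spanning the swept segment do not compete
#' with each other by rank.
#'
#' @param seeds Integer vector of simulation seeds (default 1:20).
#' @param params Simulation parameters; defaults to
#'   `calibration_design()$sweep`.
#' @param config Scan configuration; defaults to
#'   `calibration_design()$scan_lognormal`.
#' @return A list with `per_seed` (data.frame: seed, focal position, realized
#'   final frequency, best focal p, detected flag), `n_detected`, `n_seeds`
#'   and `rate`.
#' @export
evaluate_sweep_power <- function(seeds = 1:20, params = NULL, config = NULL) {
  design <- calibration_design()
  if (is.null(params)) params <- design$sweep
  if (is.null(config)) config <- design$scan_lognormal
  rows <- lapply(seeds, function(seed) {
    sim <- simulate_sweep(params, seed)
    scan <- genome_scan(sim$panel, config)
    foc <- sim$truth$focal_pos
    chrom <- sim$truth$focal_chrom
    sig <- scan$significant
    detected <- nrow(sig[sig$chrom == chrom & sig$core_start <= foc &
                           sig$core_end >= foc, , drop = FALSE]) > 0
    rec <- scan$records
    hit <- rec[rec$chrom == chrom & rec$core_start <= foc &
                 rec$core_end >= foc & !is.na(rec$p_value), , drop = FALSE]
    data.frame(seed = seed, focal_pos = foc,
               final_frequency = sim$truth$focal_final_frequency,
               best_focal_p = if (nrow(hit)) min(hit$p_value) else NA_real_,
               detected = detected)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, n_detected = sum(per_seed$detected),
       n_seeds = length(seeds), rate = mean(per_seed$detected))
}

#' Null calibration of the between-line haplotype contrast
#'
#' Simulates two lines split from one ancestral population with no selection
#' (s = 0), then pools the two lines' haplotypes and randomly re-assigns
#' them to two pseudo-lines of the original sizes. Under this exchangeable
#' relabelling the chi-square null (equal haplotype frequencies) holds
#' exactly, so the p-values over detected core regions should be
#' approximately uniform (pooling of rare haplotypes makes the test mildly
#' conservative). Note that the *unpermuted* s = 0 lines are not a null for
#' the test: independent drift after the line split makes their true
#' haplotype frequencies differ (an F\eqn{_{ST}} effect), which the contrast
#' correctly flags. [evaluate_line_divergence()] covers that direction.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param params Simulation parameters; defaults to
#'   `calibration_design()$two_line` with `selection_coefficient = 0`.
#' @return A list with the pooled p-values, `n_regions`, `frac_below_05`,
#'   `median_p`.
#' @export
evaluate_contrast_null <- function(seeds = 1:6, params = NULL) {
  if (is.null(params)) {
    params <- calibration_design()$two_line
    params$sweep$selection_coefficient <- 0
  }
  design <- calibration_design()
  pvals <- unlist(lapply(seeds, function(seed) {
    tl <- make_two_line_panel(params, seed)
    na <- nrow(tl$panel_up$haplotypes)
    pool <- rbind(tl$panel_up$haplotypes, tl$panel_down$haplotypes)
    set.seed(seed * 2 + 1)
    perm <- sample.int(nrow(pool))
    pa <- haplotype_panel(pool[perm[seq_len(na)], , drop = FALSE],
                          tl$panel_up$markers, line_label = "perm_a")
    pb <- haplotype_panel(pool[perm[-seq_len(na)], , drop = FALSE],
                          tl$panel_up$markers, line_label = "perm_b")
    contrast_scan_p(pa, pb, design$scan)
  }))
  list(p_values = pvals, n_regions = length(pvals),
       frac_below_05 = mean(pvals < 0.05), median_p = stats::median(pvals))
}

# Detect core regions on line A and contrast each against line B, returning
# the vector of defined chi-square p-values.
contrast_scan_p <- function(panel_a, panel_b, config) {
  fa <- filter_markers(panel_a, min_maf = config$min_maf)$panel
  regions <- detect_core_regions(
    fa, min_snps = config$min_core_snps,
    strong_fraction = config$strong_fraction,
    max_pair_span_bp = config$max_pair_span_bp,
    require_end_pair = config$require_end_pair,
    strong_low = config$strong_low, strong_high = config$strong_high,
    recomb_high = config$recomb_high
  )
  p <- vapply(seq_len(nrow(regions)), function(k) {
    ct <- haplotype_contrast(panel_a, panel_b, regions[k, ])
    if (identical(ct$status, "ok")) ct$p_value else NA_real_
  }, numeric(1))
  p[!is.na(p)]
}

#' Between-line divergence at the selected site
#'
#' For each seed, builds a two-line panel with opposite-sign selection and
#' asks whether the focal site's between-line allele-frequency difference
#' exceeds the genome-wide 95th percentile of per-site differences.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param params Simulation parameters; defaults to
#'   `calibration_design()$two_line`.
#' @return A list with `per_seed` data.frame (seed, focal difference, the
#'   95th-percentile threshold, exceeds flag), `n_exceeds` and `rate`.
#' @export
evaluate_line_divergence <- function(seeds = 1:20, params = NULL) {
  if (is.null(params)) params <- calibration_design()$two_line
  rows <- lapply(seeds, function(seed) {
    tl <- make_two_line_panel(params, seed)
    fa <- colMeans(tl$panel_up$haplotypes)
    fb <- colMeans(tl$panel_down$haplotypes)
    d <- abs(fa - fb)
    idx <- match(tl$truth$focal_marker_id, tl$panel_up$markers$id)
    thr <- stats::quantile(d[-idx], 0.95, names = FALSE)
    data.frame(seed = seed, focal_diff = d[idx], threshold_95 = thr,
               exceeds = d[idx] > thr)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, n_exceeds = sum(per_seed$exceeds),
       rate = mean(per_seed$exceeds))
}
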