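#' Scan configuration
#'
#' Bundles every tunable of the genome scan with its default. Defaults
#' follow the standard long-range-haplotype protocol for SNP-chip panels:
#' cores of at least two markers, REHH read 1 Mb from the core boundary on
#' both flanks, 20 equal-width core-haplotype frequency bins, empirical
#' within-bin p-values thresholded at 0.01, and a reporting cut at core
#' haplotype frequency 0.25.
#'
#' @param min_core_snps minimum markers per core region.
#' @param target_distance_bp REHH evaluation distance in bp.
#' @param n_bins number of core-haplotype frequency bins.
#' @param bin_scheme `"width"` (equal-width bins over (0, 1]) or
#'   `"count"` (equal-occupancy quantile bins).
#' @param alpha significance threshold on the p-value (strict `<`).
#' @param min_report_frequency frequency cut for the reporting tables; all
#'   tests are still computed and binned below the cut.
#' @param p_mode `"empirical"` or `"lognormal"`.
#' @param strong_low,strong_high,recomb_high D' confidence-bound
#'   thresholds for the pair classifier.
#' @param strong_fraction minimum strong-pair fraction within a block.
#' @param max_pair_span_bp LD pair-span cap in bp.
#' @param require_end_pair block ends must be a strong pair.
#' @param min_maf marker minor-allele-frequency filter.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_core_snps = 2L, target_distance_bp = 1e6,
                        n_bins = 20L, bin_scheme = c("width", "count"),
                        alpha = 0.01, min_report_frequency = 0.25,
                        p_mode = c("empirical", "lognormal"),
                        strong_low = 0.70, strong_high = 0.98,
                        recomb_high = 0.90, strong_fraction = 0.95,
                        max_pair_span_bp = 2.5e6, require_end_pair = TRUE,
                        min_maf = 0.05) {
  stopifnot(alpha > 0, alpha < 1, n_bins >= 1)
  structure(list(
    min_core_snps = as.integer(min_core_snps),
    target_distance_bp = target_distance_bp,
    n_bins = as.integer(n_bins),
    bin_scheme = match.arg(bin_scheme),
    alpha = alpha,
    min_report_frequency = min_report_frequency,
    p_mode = match.arg(p_mode),
    strong_low = strong_low, strong_high = strong_high,
    recomb_high = recomb_high, strong_fraction = strong_fraction,
    max_pair_span_bp = max_pair_span_bp,
    require_end_pair = require_end_pair,
    min_maf = min_maf
  ), class = "scan_config")
}

#' Assign REHH records to core-haplotype frequency bins
#'
#' Default equal-width binning partitions (0, 1] into `n_bins` right-closed
#' intervals of width `1/n_bins`; a record with frequency `f` lands in bin
#' `ceiling(f * n_bins) - 1` (0-based). The `"count"` alternative places
#' bin edges at frequency quantiles so occupancy is as even as ties allow.
#'
#' @param records data frame of [rehh_test()] rows.
#' @param n_bins number of bins (default 20).
#' @param scheme `"width"` or `"count"`.
#' @return `records` with columns `bin_index` (0-based) and `n_in_bin`.
#' @export
bin_by_frequency <- function(records, n_bins = 20L, scheme = c("width", "count")) {
  scheme <- match.arg(scheme)
  f <- records$frequency
  stopifnot(all(f > 0 & f <= 1))
  if (scheme == "width") {
    bin <- pmin(as.integer(ceiling(f * n_bins)) - 1L, n_bins - 1L)
    bin <- pmax(bin, 0L)
  } else {
    edges <- unique(stats::quantile(f, probs = seq(0, 1, length.out = n_bins + 1),
                                    type = 1))
    edges[1] <- 0
    edges[length(edges)] <- 1
    bin <- as.integer(cut(f, edges, include.lowest = FALSE,
                          right = TRUE, labels = FALSE)) - 1L
    bin[is.na(bin)] <- 0L
  }
  records$bin_index <- bin
  records$n_in_bin <- as.integer(ave(bin, bin, FUN = length))
  records
}

#' Within-bin empirical p-values
#'
#' A record's p-value is the fraction of records in its frequency bin
#' (itself included, ties counted inclusively) whose REHH is at least as
#' large, so `p >= 1/n_bin` and high-REHH outliers get small p. A
#' singleton bin yields `p = 1` and is flagged.
#'
#' @param records binned records from [bin_by_frequency()].
#' @return `records` with columns `p_value`, `neg_log10_p`,
#'   `singleton_bin`.
#' @export
empirical_p <- function(records) {
  p <- rep(NA_real_, nrow(records))
  for (b in unique(records$bin_index)) {
    w <- which(records$bin_index == b)
    r <- records$rehh[w]
    p[w] <- vapply(r, function(x) mean(r >= x), numeric(1))
  }
  records$p_value <- p
  records$neg_log10_p <- -log10(p)
  records$singleton_bin <- records$n_in_bin == 1L
  if (any(records$singleton_bin)) {
    warning(sum(records$singleton_bin),
            " record(s) in singleton bins were assigned p = 1")
  }
  records
}

#' Within-bin log-normal p-values
#'
#' Alternative parametric reading: within each bin, `ln(REHH)` is fitted
#' by a normal distribution and the p-value is the upper-tail probability
#' of the record's value. Records with non-positive REHH, or bins with
#' fewer than 3 usable records, get `NA`.
#'
#' @param records binned records from [bin_by_frequency()].
#' @return `records` with columns `p_value`, `neg_log10_p`.
#' @export
lognormal_p <- function(records) {
  p <- rep(NA_real_, nrow(records))
  for (b in unique(records$bin_index)) {
    w <- which(records$bin_index == b)
    lr <- log(records$rehh[w])
    ok <- is.finite(lr)
    if (sum(ok) >= 3) {
      mu <- mean(lr[ok]); sdv <- stats::sd(lr[ok])
      if (sdv > 0) p[w[ok]] <- stats::pnorm(lr[ok], mu, sdv, lower.tail = FALSE)
    }
  }
  records$p_value <- p
  records$neg_log10_p <- -log10(p)
  records
}

#' Genome-wide EHH/REHH selection-signature scan
#'
#' Orchestrates the whole pipeline on one panel: marker filtering, core
#' region detection, core-haplotype enumeration, the REHH test for every
#' testable core haplotype in both directions, frequency binning, within-
#' bin p-values, and the reporting tables. Records whose denominator is
#' undefined are excluded from binning; chromosome-end truncated records
#' are kept (flagged).
#'
#' @param panel a [haplotype_panel()]; filtering is applied internally
#'   with `config$min_maf` unless `filter = FALSE`.
#' @param config a [scan_config()].
#' @param regions optional precomputed [detect_core_regions()] table to
#'   reuse (skips block detection).
#' @param filter apply [filter_markers()] first (default `TRUE`).
#' @return A list of class `sweep_scan`: `records` (all tests),
#'   `regions`, `region_summary`, `per_chrom` (tests at the reporting
#'   frequency cut and significance tallies per chromosome),
#'   `significant` (records with `p < alpha` at the reporting cut),
#'   `filter_report`, `config`.
#' @export
genome_scan <- function(panel, config = scan_config(), regions = NULL,
                        filter = TRUE) {
  filter_report <- NULL
  if (filter) {
    fl <- filter_markers(panel, min_maf = config$min_maf)
    panel <- fl$panel
    filter_report <- fl$report
  }
  if (is.null(regions)) {
    regions <- detect_core_regions(
      panel, min_snps = config$min_core_snps,
      strong_fraction = config$strong_fraction,
      max_pair_span_bp = config$max_pair_span_bp,
      require_end_pair = config$require_end_pair,
      strong_low = config$strong_low, strong_high = config$strong_high,
      recomb_high = config$recomb_high
    )
  }
  if (nrow(regions) == 0) {
    warning("no core regions detected; scan output is empty")
    empty <- empty_scan_records()
    return(structure(list(records = empty, regions = regions,
                          region_summary = summarize_core_regions(regions, panel),
                          per_chrom = empty_per_chrom(),
                          significant = empty,
                          filter_report = filter_report, config = config),
                     class = "sweep_scan"))
  }
  recs <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    region <- regions[k, ]
    ch <- core_haplotypes(panel, region)
    testable <- ch[ch$carrier_count >= 2 &
                     nrow(panel$haplotypes) - ch$carrier_count >= 2, ,
                   drop = FALSE]
    if (nrow(testable) == 0) next
    out <- vector("list", 2L * nrow(testable))
    for (h in seq_len(nrow(testable))) {
      out[[2 * h - 1]] <- rehh_test(panel, region, testable$allele_string[h],
                                    "upstream", config$target_distance_bp)
      out[[2 * h]] <- rehh_test(panel, region, testable$allele_string[h],
                                "downstream", config$target_distance_bp)
    }
    recs[[k]] <- do.call(rbind, out)
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) records <- empty_scan_records()
  usable <- records[!is.na(records$rehh), , drop = FALSE]
  if (nrow(usable) > 0) {
    usable <- bin_by_frequency(usable, n_bins = config$n_bins,
                               scheme = config$bin_scheme)
    usable <- if (config$p_mode == "empirical") empirical_p(usable) else
      lognormal_p(usable)
    # BH-adjusted p is reported for convenience only; the significant flag
    # always uses the raw within-bin p against alpha.
    usable$p_bh <- stats::p.adjust(usable$p_value, method = "BH")
    usable$significant <- !is.na(usable$p_value) &
      usable$p_value < config$alpha
  } else {
    usable$bin_index <- integer(0)
    usable$n_in_bin <- integer(0)
    usable$p_value <- numeric(0)
    usable$neg_log10_p <- numeric(0)
    usable$p_bh <- numeric(0)
    usable$significant <- logical(0)
  }
  at_cut <- usable[usable$frequency >= config$min_report_frequency, ,
                   drop = FALSE]
  per_chrom <- per_chrom_counts(at_cut, config$alpha)
  significant <- at_cut[at_cut$significant, , drop = FALSE]
  structure(list(
    records = usable, regions = regions,
    region_summary = summarize_core_regions(regions, panel),
    per_chrom = per_chrom, significant = significant,
    filter_report = filter_report, config = config
  ), class = "sweep_scan")
}

empty_scan_records <- function() {
  data.frame(chrom = character(), core_start = numeric(),
             core_end = numeric(), allele_string = character(),
             carrier_count = integer(), frequency = numeric(),
             direction = character(), eval_pos = numeric(),
             distance_bp = numeric(), ehh_t = numeric(),
             ehh_bar = numeric(), rehh = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

empty_per_chrom <- function() {
  data.frame(chrom = character(), n_tests = integer(), p_lt_05 = integer(),
             p_lt_alpha = integer())
}

# Per-chromosome tallies of tests at the reporting cut, plus a total row.
per_chrom_counts <- function(at_cut, alpha) {
  if (nrow(at_cut) == 0) return(empty_per_chrom())
  chroms <- unique(at_cut$chrom)
  rows <- lapply(chroms, function(chr) {
    r <- at_cut[at_cut$chrom == chr, ]
    data.frame(chrom = chr, n_tests = nrow(r),
               p_lt_05 = sum(r$p_value < 0.05, na.rm = TRUE),
               p_lt_alpha = sum(r$p_value < alpha, na.rm = TRUE))
  })
  per <- do.call(rbind, rows)
  rbind(per, data.frame(chrom = "total", n_tests = sum(per$n_tests),
                        p_lt_05 = sum(per$p_lt_05),
                        p_lt_alpha = sum(per$p_lt_alpha)))
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("sweep_scan: %d core regions, %d REHH tests (%d at freq >= %.2f), %d significant at p < %g\n",
              nrow(x$regions), nrow(x$records),
              sum(x$records$frequency >= x$config$min_report_frequency),
              x$config$min_report_frequency, nrow(x$significant),
              x$config$alpha))
  invisible(x)
}

#' Write the scan's report files
#'
#' Emits four TSVs with frozen column order and rounding (EHH and REHH to
#' 2 decimals, p-values to 4 decimals, C's round-half-even) so reruns
#' diff cleanly: `tests.tsv` (every test), `per_chrom_counts.tsv`,
#' `significant_regions.tsv`, and `manhattan.tsv`
#' (chrom, pos, -log10 p at the reporting frequency cut).
#'
#' @param scan a `sweep_scan` from [genome_scan()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
scan_report <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt2 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))
  fmt4 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 4))
  r <- scan$records
  tests <- data.frame(
    chrom = r$chrom, core_start = r$core_start, core_end = r$core_end,
    haplotype = r$allele_string, frequency = fmt2(r$frequency),
    direction = r$direction, ehh = fmt2(r$ehh_t), ehh_bar = fmt2(r$ehh_bar),
    rehh = fmt2(r$rehh),
    p_value = if (nrow(r) > 0) fmt4(r$p_value) else character(0),
    p_bh = if (nrow(r) > 0) fmt4(r$p_bh) else character(0),
    status = r$status
  )
  paths <- file.path(dir, c("tests.tsv", "per_chrom_counts.tsv",
                            "significant_regions.tsv", "manhattan.tsv"))
  utils::write.table(tests, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$per_chrom, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- scan$significant
  sig <- data.frame(chrom = s$chrom, core_start = s$core_start,
                    core_end = s$core_end, haplotype = s$allele_string,
                    frequency = fmt2(s$frequency), direction = s$direction,
                    ehh = fmt2(s$ehh_t), rehh = fmt2(s$rehh),
                    p_value = if (nrow(s) > 0) fmt4(s$p_value) else character(0))
  utils::write.table(sig, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  at_cut <- r[!is.na(r$p_value) &
                r$frequency >= scan$config$min_report_frequency, ,
              drop = FALSE]
  man <- data.frame(chrom = at_cut$chrom,
                    pos = (at_cut$core_start + at_cut$core_end) / 2,
                    neg_log10_p = fmt4(at_cut$neg_log10_p))
  utils::write.table(man, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
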