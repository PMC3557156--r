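#' Enumerate core haplotypes of a region
#'
#' A core haplotype is a distinct allele string over the region's markers;
#' every chromosome in the panel carries exactly one, so carrier counts
#' partition H and frequencies sum to one. Results are sorted by
#' descending frequency, ties broken lexicographically by allele string.
#'
#' @param panel a [haplotype_panel()].
#' @param region one row of a [detect_core_regions()] table (or any list
#'   with `first_idx`, `last_idx`, `chrom`, `start_pos`, `end_pos`).
#' @return Data frame with columns `allele_string`, `carrier_count`,
#'   `frequency`; the region is attached as attribute `"region"`.
#' @export
core_haplotypes <- function(panel, region) {
  rng <- region$first_idx:region$last_idx
  s <- hap_strings(panel$haplotypes, rng)
  tab <- table(s)
  out <- data.frame(allele_string = names(tab),
                    carrier_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$carrier_count / nrow(panel$haplotypes)
  out <- out[order(-out$frequency, out$allele_string), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "region") <- region
  out
}

hap_strings <- function(X, cols) {
  if (length(cols) == 1) return(as.character(X[, cols]))
  do.call(paste0, as.data.frame(X[, cols, drop = FALSE]))
}

# Extension marker indices from the region boundary (exclusive) through
# eval_idx (inclusive), in the direction of travel. Upstream means lower
# positions; eval_idx must lie strictly outside the region.
extension_range <- function(region, direction, eval_idx) {
  if (direction == "upstream") {
    if (eval_idx >= region$first_idx) {
      stop("upstream evaluation marker must lie before the region start")
    }
    eval_idx:(region$first_idx - 1L)
  } else if (direction == "downstream") {
    if (eval_idx <= region$last_idx) {
      stop("downstream evaluation marker must lie after the region end")
    }
    (region$last_idx + 1L):eval_idx
  } else {
    stop("direction must be 'upstream' or 'downstream'")
  }
}

# Homozygosity of a partition given group sizes: sum C(e,2) / C(n,2).
pair_homozygosity <- function(group_sizes) {
  n <- sum(group_sizes)
  if (n < 2) return(NA_real_)
  sum(choose(group_sizes, 2)) / choose(n, 2)
}

#' Extended haplotype homozygosity at a marker
#'
#' EHH of a core haplotype at an evaluation marker is the probability that
#' two randomly chosen carriers of that core haplotype are identical over
#' the whole interval from the core boundary to the evaluation marker:
#' carriers are grouped by their allele string over that interval and
#' `EHH = sum(C(e_k, 2)) / C(c, 2)` over group sizes `e_k`.
#'
#' @param panel a [haplotype_panel()].
#' @param region the core region (row of a [detect_core_regions()] table).
#' @param core_allele the core haplotype's allele string over the region's
#'   markers.
#' @param direction `"upstream"` (towards lower positions) or
#'   `"downstream"`.
#' @param eval_idx global marker index strictly beyond the region boundary
#'   in the given direction.
#' @return EHH in `[0, 1]`, or `NA` when the core haplotype has fewer than
#'   2 carriers.
#' @export
ehh_at <- function(panel, region, core_allele, direction, eval_idx) {
  rng <- region$first_idx:region$last_idx
  carriers <- hap_strings(panel$haplotypes, rng) == core_allele
  if (sum(carriers) < 2) return(NA_real_)
  ext <- extension_range(region, direction, eval_idx)
  s <- hap_strings(panel$haplotypes[carriers, , drop = FALSE], ext)
  pair_homozygosity(as.integer(table(s)))
}

#' Pooled-other extended haplotype homozygosity at a marker
#'
#' The REHH denominator: all chromosomes NOT carrying the tested core
#' haplotype, pooled, grouped by their allele string over the core region
#' PLUS the extension through the evaluation marker. Including the core in
#' the interval means chromosomes with different core haplotypes are never
#' counted homozygous.
#'
#' @inheritParams ehh_at
#' @return EHH-bar in `[0, 1]`, or `NA` when fewer than 2 chromosomes
#'   carry other core haplotypes.
#' @export
ehh_bar_at <- function(panel, region, core_allele, direction, eval_idx) {
  rng <- region$first_idx:region$last_idx
  core_s <- hap_strings(panel$haplotypes, rng)
  others <- core_s != core_allele
  if (sum(others) < 2) return(NA_real_)
  ext <- extension_range(region, direction, eval_idx)
  cols <- if (direction == "upstream") c(ext, rng) else c(rng, ext)
  s <- hap_strings(panel$haplotypes[others, , drop = FALSE], cols)
  pair_homozygosity(as.integer(table(s)))
}

#' EHH decay curve away from a core region
#'
#' Evaluates [ehh_at()] and [ehh_bar_at()] at every marker moving outward
#' from the region boundary until EHH reaches zero or the chromosome ends.
#' Both value sequences are non-increasing in distance because each step
#' refines the identity partition.
#'
#' @inheritParams ehh_at
#' @return Data frame with columns `eval_idx`, `eval_pos`, `distance_bp`
#'   (from the boundary marker), `ehh`, `ehh_bar`.
#' @export
ehh_decay <- function(panel, region, core_allele, direction) {
  idx <- chrom_indices(panel, region$chrom)
  if (direction == "upstream") {
    steps <- rev(idx[idx < region$first_idx])
    boundary_pos <- region$start_pos
  } else {
    steps <- idx[idx > region$last_idx]
    boundary_pos <- region$end_pos
  }
  rows <- list()
  for (k in seq_along(steps)) {
    e <- ehh_at(panel, region, core_allele, direction, steps[k])
    eb <- ehh_bar_at(panel, region, core_allele, direction, steps[k])
    rows[[k]] <- data.frame(
      eval_idx = steps[k], eval_pos = panel$markers$pos[steps[k]],
      distance_bp = abs(panel$markers$pos[steps[k]] - boundary_pos),
      ehh = e, ehh_bar = eb
    )
    if (!is.na(e) && e == 0) break
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(eval_idx = integer(), eval_pos = numeric(),
                      distance_bp = numeric(), ehh = numeric(),
                      ehh_bar = numeric())
  }
  out
}

#' REHH test for one core haplotype in one direction
#'
#' Evaluates EHH and pooled-other EHH at the first marker lying at least
#' `target_distance_bp` beyond the region boundary in the direction of
#' travel, and reports their ratio `REHH = EHH_t / EHH-bar`. When the
#' chromosome ends before the target distance the outermost marker is used
#' and the record is flagged `truncated_end` (it still enters downstream
#' binning). Records without a usable denominator (`EHH-bar = 0` or fewer
#' than 2 non-carriers) are flagged and excluded from significance testing;
#' batch callers never see an exception.
#'
#' @inheritParams ehh_at
#' @param target_distance_bp nominal test distance from the region boundary
#'   (default 1 Mb).
#' @return One-row data frame: `chrom`, `core_start`, `core_end`,
#'   `allele_string`, `carrier_count`, `frequency`, `direction`,
#'   `eval_pos`, `distance_bp`, `ehh_t`, `ehh_bar`, `rehh`, `status`
#'   (one of `ok`, `truncated_end`, `undefined_core`, `undefined_bar`,
#'   `no_flank`).
#' @export
rehh_test <- function(panel, region, core_allele, direction,
                      target_distance_bp = 1e6) {
  rng <- region$first_idx:region$last_idx
  core_s <- hap_strings(panel$haplotypes, rng)
  c_n <- sum(core_s == core_allele)
  H <- nrow(panel$haplotypes)
  rec <- data.frame(
    chrom = region$chrom, core_start = region$start_pos,
    core_end = region$end_pos, allele_string = core_allele,
    carrier_count = c_n, frequency = c_n / H, direction = direction,
    eval_pos = NA_real_, distance_bp = NA_real_, ehh_t = NA_real_,
    ehh_bar = NA_real_, rehh = NA_real_, status = "ok",
    stringsAsFactors = FALSE
  )
  if (c_n < 2) { rec$status <- "undefined_core"; return(rec) }
  if (H - c_n < 2) { rec$status <- "undefined_bar"; return(rec) }
  idx <- chrom_indices(panel, region$chrom)
  pos <- panel$markers$pos
  if (direction == "upstream") {
    flank <- idx[idx < region$first_idx]
    boundary <- region$start_pos
    target <- flank[pos[flank] <= boundary - target_distance_bp]
    eval_idx <- if (length(target) > 0) max(target) else
      if (length(flank) > 0) min(flank) else NA_integer_
  } else {
    flank <- idx[idx > region$last_idx]
    boundary <- region$end_pos
    target <- flank[pos[flank] >= boundary + target_distance_bp]
    eval_idx <- if (length(target) > 0) min(target) else
      if (length(flank) > 0) max(flank) else NA_integer_
  }
  if (is.na(eval_idx)) { rec$status <- "no_flank"; return(rec) }
  if (length(target) == 0) rec$status <- "truncated_end"
  rec$eval_pos <- pos[eval_idx]
  rec$distance_bp <- abs(pos[eval_idx] - boundary)
  rec$ehh_t <- ehh_at(panel, region, core_allele, direction, eval_idx)
  rec$ehh_bar <- ehh_bar_at(panel, region, core_allele, direction, eval_idx)
  if (is.na(rec$ehh_bar) || rec$ehh_bar == 0) {
    rec$status <- "undefined_bar"
  } else {
    rec$rehh <- rec$ehh_t / rec$ehh_bar
  }
  rec
}
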