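#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` is the substrate of every analysis stage: an H x M
#' matrix of phased 0/1 alleles (rows are haplotypes, columns are markers)
#' together with a marker map and haplotype labels. Two consecutive rows
#' belong to one diploid individual, but nothing downstream depends on that
#' pairing: every statistic operates on chromosomes.
#'
#' @param haplotypes integer or numeric H x M matrix with entries in
#'   `{0, 1}`; rows are haplotypes, columns are markers.
#' @param markers data frame with one row per marker and columns `chrom`
#'   (character), `pos` (1-based base-pair coordinate), `id`, `ref`, `alt`.
#'   Markers must be sortable to strictly increasing `pos` within each
#'   chromosome; duplicated `(chrom, pos)` is an error.
#' @param sample_ids character vector of H haplotype labels.
#' @param line_label single string tagging the population (e.g. `"lean"`).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, markers, sample_ids = NULL,
                            line_label = "panel") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("hap%03d", seq_len(nrow(haplotypes)))
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  required <- c("chrom", "pos")
  if (!all(required %in% names(markers))) {
    stop("markers must have at least columns 'chrom' and 'pos'")
  }
  if (is.null(markers$id)) markers$id <- sprintf("m%06d", seq_len(nrow(markers)))
  if (is.null(markers$ref)) markers$ref <- "A"
  if (is.null(markers$alt)) markers$alt <- "G"
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)

  ord <- order(chrom_rank(markers$chrom), markers$pos)
  if (any(ord != seq_along(ord))) {
    markers <- markers[ord, , drop = FALSE]
    haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL

  panel <- structure(
    list(haplotypes = haplotypes, markers = markers,
         sample_ids = as.character(sample_ids),
         line_label = as.character(line_label)[1]),
    class = "haplotype_panel"
  )
  validate_panel(panel)
  panel
}

# Chromosome sort key: numeric labels in numeric order, then the rest
# alphabetically, so "2" sorts before "10". Equal labels share a key.
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(u))
  u_sorted <- u[order(is.na(num), num, u)]
  match(chrom, u_sorted)
}

#' Validate a haplotype panel
#'
#' Checks every structural invariant: 0/1 entries, at least 4 haplotypes,
#' markers sorted by (chrom, pos) with no duplicated position, and
#' consistent dimensions. Called by the constructor; exposed for use after
#' manual surgery on a panel.
#'
#' @param panel a [haplotype_panel()].
#' @return The panel, invisibly; errors describe the first violation found.
#' @export
validate_panel <- function(panel) {
  X <- panel$haplotypes
  mk <- panel$markers
  if (!all(X %in% c(0L, 1L))) stop("haplotype matrix entries must be 0 or 1")
  if (nrow(X) < 4L) stop("a panel needs at least 4 haplotypes (H >= 4)")
  if (ncol(X) != nrow(mk)) {
    stop("marker table has ", nrow(mk), " rows but matrix has ",
         ncol(X), " columns")
  }
  if (length(panel$sample_ids) != nrow(X)) {
    stop("sample_ids length must equal the number of haplotype rows")
  }
  for (chr in unique(mk$chrom)) {
    p <- mk$pos[mk$chrom == chr]
    if (any(!is.na(p) & p < 1)) stop("marker positions must be >= 1 on chrom ", chr)
    if (anyDuplicated(p[!is.na(p)])) {
      stop("duplicated marker position on chrom ", chr,
           " (ties in pos are rejected: distance grids require strict order)")
    }
    if (is.unsorted(p, na.rm = TRUE)) stop("markers not sorted on chrom ", chr)
  }
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes x %d markers on %d chromosome(s)\n",
              x$line_label, nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haplotypes)

#' Per-marker allele statistics
#'
#' Computes the minor allele frequency of every marker, flags monomorphic
#' markers (maf exactly 0) and markers lacking a usable position. A marker's
#' position is unusable when it is missing, non-positive, or its chromosome
#' label is the reserved "unplaced" tag `"un"`.
#'
#' @param panel a [haplotype_panel()].
#' @return Data frame with columns `maf`, `is_monomorphic`, `has_position`,
#'   one row per marker in panel order.
#' @export
allele_frequencies <- function(panel) {
  p <- colMeans(panel$haplotypes)
  maf <- pmin(p, 1 - p)
  data.frame(
    maf = maf,
    is_monomorphic = maf == 0,
    has_position = !is.na(panel$markers$pos) & panel$markers$pos >= 1 &
      tolower(panel$markers$chrom) != "un"
  )
}

#' Filter a panel's markers
#'
#' Applies the standard chip-QC cascade in a fixed order: (1) markers with
#' unknown position, (2) monomorphic markers, (3) markers with minor allele
#' frequency below `min_maf`. Each marker is counted in the first category
#' it fails, so the report's categories are disjoint and sum to the number
#' removed.
#'
#' @param panel a [haplotype_panel()].
#' @param min_maf minimum minor allele frequency retained; markers with
#'   `maf < min_maf` are removed. Default 0.05.
#' @return A list with elements `panel` (the filtered panel) and `report`,
#'   a one-row data frame with counts `n_input`, `n_removed_unplaced`,
#'   `n_removed_monomorphic`, `n_removed_maf`, `n_retained`.
#' @export
filter_markers <- function(panel, min_maf = 0.05) {
  st <- allele_frequencies(panel)
  unplaced <- !st$has_position
  mono <- !unplaced & st$is_monomorphic
  lowmaf <- !unplaced & !mono & st$maf < min_maf
  keep <- !(unplaced | mono | lowmaf)
  report <- data.frame(
    n_input = nrow(st),
    n_removed_unplaced = sum(unplaced),
    n_removed_monomorphic = sum(mono),
    n_removed_maf = sum(lowmaf),
    n_retained = sum(keep)
  )
  if (!any(keep)) {
    stop("all ", nrow(st), " markers removed by filtering; ",
         "review min_maf (", min_maf, ") and marker positions")
  }
  out <- panel
  out$haplotypes <- panel$haplotypes[, keep, drop = FALSE]
  out$markers <- panel$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  validate_panel(out)
  list(panel = out, report = report)
}

# Column indices of markers on one chromosome (in panel order).
chrom_indices <- function(panel, chrom) {
  which(panel$markers$chrom == chrom)
}
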