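#' Read a BED interval file
#'
#' BED is 0-based half-open; intervals are converted on read to the
#' 1-based inclusive convention used throughout the package
#' (`start + 1`, `end`). Output is sorted by (chrom, start).
#'
#' @param path 3+ column BED file (chrom, start, end, optional name).
#' @param source tag recorded on every interval (e.g. `"genes"`,
#'   `"qtl"`).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `source`.
#' @export
read_intervals <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      source = character()))
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- vapply(parts, length, integer(1))
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  }
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  if (any(is.na(start0) | is.na(end0))) {
    stop("malformed BED line ", which(is.na(start0) | is.na(end0))[1],
         ": non-numeric coordinates")
  }
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = start0 + 1,
    end = end0,
    name = ifelse(nf >= 4, vapply(parts, function(p) p[4][1], ""), NA_character_),
    source = source, stringsAsFactors = FALSE
  )
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals back to BED
#'
#' Inverse of [read_intervals()]: converts 1-based inclusive intervals
#' back to 0-based half-open coordinates.
#'
#' @param intervals data frame as returned by [read_intervals()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(intervals, path) {
  bed <- data.frame(intervals$chrom,
                    format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                    format(intervals$end, scientific = FALSE, trim = TRUE),
                    ifelse(is.na(intervals$name), ".", intervals$name))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap core regions with feature intervals
#'
#' Reports one row per (region, feature) pair sharing at least 1 bp on the
#' same chromosome, using inclusive coordinates on both sides. Regions
#' without any overlapping feature are emitted once with the feature field
#' set to `"/"`, matching the display convention for empty annotation.
#'
#' @param regions a [detect_core_regions()] table (or any data frame with
#'   `chrom`, `start_pos`, `end_pos`).
#' @param features data frame from [read_intervals()].
#' @return Data frame: `chrom`, `start_pos`, `end_pos`, `feature`,
#'   `feature_start`, `feature_end`, `overlap_bp`, `source`.
#' @export
overlap_regions <- function(regions, features) {
  # tolerate minimal feature tables (chrom/start/end only)
  if (is.null(features$name)) features$name <- NA_character_
  if (is.null(features$source)) features$source <- NA_character_
  none <- function(i) data.frame(
    chrom = regions$chrom[i], start_pos = regions$start_pos[i],
    end_pos = regions$end_pos[i], feature = "/",
    feature_start = NA_real_, feature_end = NA_real_,
    overlap_bp = 0, source = NA_character_, stringsAsFactors = FALSE
  )
  if (nrow(regions) == 0) return(none(integer(0)))
  if (nrow(features) == 0) return(do.call(rbind, lapply(seq_len(nrow(regions)), none)))
  # a shared seqlevels universe lets findOverlaps compare the two sets
  # even when their chromosome names are disjoint
  lev <- unique(c(regions$chrom, features$chrom))
  gr_r <- GenomicRanges::GRanges(
    factor(regions$chrom, levels = lev),
    IRanges::IRanges(regions$start_pos, regions$end_pos))
  gr_f <- GenomicRanges::GRanges(
    factor(features$chrom, levels = lev),
    IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_f)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    fs <- sh[qh == i]
    if (length(fs) == 0) {
      rows[[i]] <- none(i)
    } else {
      ov <- pmin(regions$end_pos[i], features$end[fs]) -
        pmax(regions$start_pos[i], features$start[fs]) + 1
      rows[[i]] <- data.frame(
        chrom = regions$chrom[i], start_pos = regions$start_pos[i],
        end_pos = regions$end_pos[i],
        feature = ifelse(is.na(features$name[fs]), ".", features$name[fs]),
        feature_start = features$start[fs], feature_end = features$end[fs],
        overlap_bp = ov, source = features$source[fs],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-line haplotype-frequency contrast
#'
#' Builds the core-haplotype-by-line count table over a region's markers
#' from two panels and applies a chi-square test of homogeneity. Rare
#' haplotypes are pooled (rarest first) into an `"other"` class until every
#' expected count reaches `min_expected`, or until only two classes remain;
#' pooling never changes the grand total. Counts are reconstructed from the
#' panels, never from rounded frequencies.
#'
#' @param panel_a,panel_b two [haplotype_panel()]s sharing the region's
#'   markers (matched by chromosome and position).
#' @param region a core-region row (needs `chrom`, `start_pos`,
#'   `end_pos`).
#' @param min_expected minimum expected cell count before pooling stops
#'   (default 1).
#' @return A list of class `haplotype_contrast`: `table` (counts,
#'   haplotype x line), `frequencies`, `chi2`, `df`, `p_value`,
#'   `pooled_rare`, `status` (`ok` or `undefined`).
#' @export
haplotype_contrast <- function(panel_a, panel_b, region, min_expected = 1) {
  cols_a <- region_columns(panel_a, region)
  cols_b <- region_columns(panel_b, region)
  if (length(cols_a) == 0 || length(cols_b) == 0 ||
      length(cols_a) != length(cols_b)) {
    stop("region markers absent from one panel or marker maps disagree")
  }
  sa <- hap_strings(panel_a$haplotypes, cols_a)
  sb <- hap_strings(panel_b$haplotypes, cols_b)
  haps <- sort(unique(c(sa, sb)))
  tab <- cbind(a = as.integer(table(factor(sa, levels = haps))),
               b = as.integer(table(factor(sb, levels = haps))))
  rownames(tab) <- haps
  colnames(tab) <- c(panel_a$line_label, panel_b$line_label)
  pooled <- FALSE
  repeat {
    if (nrow(tab) <= 2) break
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expd) >= min_expected) break
    o <- order(rowSums(tab))
    merge_into <- if ("other" %in% rownames(tab)) "other" else NA
    victim <- setdiff(rownames(tab)[o], "other")[1]
    if (is.na(merge_into)) {
      rownames(tab)[rownames(tab) == victim] <- "other"
    } else {
      tab[merge_into, ] <- tab[merge_into, ] + tab[victim, ]
      tab <- tab[rownames(tab) != victim, , drop = FALSE]
    }
    pooled <- TRUE
  }
  freqs <- sweep(tab, 2, colSums(tab), "/")
  if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
    return(structure(list(table = tab, frequencies = freqs,
                          chi2 = NA_real_, df = NA_integer_,
                          p_value = NA_real_, pooled_rare = pooled,
                          status = "undefined"),
                     class = "haplotype_contrast"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, frequencies = freqs,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), pooled_rare = pooled,
                 status = "ok"),
            class = "haplotype_contrast")
}

# Marker columns of `panel` falling inside the region (matched by chrom
# and position, so panels with different marker indexing line up).
region_columns <- function(panel, region) {
  which(panel$markers$chrom == region$chrom &
          panel$markers$pos >= region$start_pos &
          panel$markers$pos <= region$end_pos)
}

#' @export
print.haplotype_contrast <- function(x, ...) {
  cat("haplotype_contrast:", nrow(x$table), "haplotype classes; chi2 =",
      round(x$chi2, 3), "df =", x$df, "p =", signif(x$p_value, 3), "\n")
  invisible(x)
}
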