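#' Pairwise LD table for a chromosome
#'
#' Computes counts, D', r-squared, |D'| confidence bounds and the
#' strong-LD classification for every marker pair whose physical span does
#' not exceed `max_pair_span_bp`. Pairs involving a monomorphic marker are
#' reported `uninformative` with `NA` statistics.
#'
#' @param panel a [haplotype_panel()].
#' @param chrom chromosome label; `NULL` (default) means the panel must be
#'   single-chromosome.
#' @param max_pair_span_bp ignore pairs farther apart than this (default
#'   2.5 Mb, above the longest block scale of interest).
#' @param conf,grid_n,floor_p passed to [dprime_ci()].
#' @param strong_low,strong_high,recomb_high passed to [classify_pair()].
#' @return Data frame with columns `i`, `j` (global marker indices),
#'   `n00`, `n01`, `n10`, `n11`, `Dprime`, `r2`, `ci_low`, `ci_high`,
#'   `class`.
#' @export
pairwise_ld <- function(panel, chrom = NULL, max_pair_span_bp = 2.5e6,
                        conf = 0.90, grid_n = 101L, floor_p = 1e-10,
                        strong_low = 0.70, strong_high = 0.98,
                        recomb_high = 0.90) {
  if (is.null(chrom)) {
    chroms <- unique(panel$markers$chrom)
    if (length(chroms) > 1) stop("panel spans several chromosomes; pass chrom=")
    chrom <- chroms[1]
  }
  idx <- chrom_indices(panel, chrom)
  X <- panel$haplotypes[, idx, drop = FALSE]
  pos <- panel$markers$pos[idx]
  H <- nrow(X); M <- ncol(X)
  if (M < 2) {
    return(data.frame(i = integer(), j = integer(), n00 = integer(),
                      n01 = integer(), n10 = integer(), n11 = integer(),
                      Dprime = numeric(), r2 = numeric(), ci_low = numeric(),
                      ci_high = numeric(), class = character()))
  }
  n1 <- colSums(X)
  rows <- vector("list", M - 1L)
  for (d in seq_len(M - 1L)) {
    ii <- seq_len(M - d); jj <- ii + d
    ok <- pos[jj] - pos[ii] <= max_pair_span_bp
    if (!any(ok)) break
    ii <- ii[ok]; jj <- jj[ok]
    n11 <- colSums(X[, ii, drop = FALSE] * X[, jj, drop = FALSE])
    rows[[d]] <- data.frame(li = ii, lj = jj, n11 = n11,
                            n1i = n1[ii], n1j = n1[jj])
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(pairwise_ld(panel, chrom, max_pair_span_bp = Inf, conf = conf)[0, ])
  }
  n11 <- pairs$n11
  n10 <- pairs$n1i - n11
  n01 <- pairs$n1j - n11
  n00 <- H - n11 - n10 - n01
  pA <- pairs$n1i / H; pB <- pairs$n1j / H
  informative <- pA > 0 & pA < 1 & pB > 0 & pB < 1
  D <- n11 / H - pA * pB
  Dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  Dprime <- ifelse(D == 0, 0, abs(D) / Dmax)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  ci_low <- rep(NA_real_, nrow(pairs))
  ci_high <- rep(NA_real_, nrow(pairs))
  if (any(informative)) {
    # chunked so the P x grid_n likelihood matrix stays small
    w <- which(informative)
    for (chunk in split(w, ceiling(seq_along(w) / 50000L))) {
      ci <- dprime_ci_batch(n00[chunk], n01[chunk], n10[chunk], n11[chunk],
                            conf = conf, grid_n = grid_n, floor_p = floor_p)
      ci_low[chunk] <- ci$lo
      ci_high[chunk] <- ci$hi
    }
  }
  cls <- rep("uninformative", nrow(pairs))
  cls[informative & ci_low >= strong_low & ci_high >= strong_high] <- "strong_ld"
  cls[informative & cls == "uninformative" & ci_high < recomb_high] <-
    "strong_recombination"
  cls[informative & cls == "uninformative"] <- "inconclusive"
  data.frame(i = idx[pairs$li], j = idx[pairs$lj],
             n00 = n00, n01 = n01, n10 = n10, n11 = n11,
             Dprime = ifelse(informative, Dprime, NA_real_),
             r2 = ifelse(informative, r2, NA_real_),
             ci_low = ci_low, ci_high = ci_high, class = cls)
}

#' Detect core regions (strong-LD haplotype blocks)
#'
#' Scans each chromosome for runs of markers in strong pairwise LD under
#' the confidence-interval rule. A candidate interval `[i..j]` qualifies
#' when (a) the fraction of its informative marker pairs classified
#' `strong_ld` is at least `strong_fraction`, (b) its two end markers are
#' themselves a strong-LD pair (when `require_end_pair` is `TRUE`), and
#' (c) it holds at least `min_snps` markers. Qualifying intervals are
#' selected greedily by descending physical length (ties: leftmost first),
#' discarding any candidate that overlaps an already selected region, so
#' returned regions never overlap. Pairs spanning more than
#' `max_pair_span_bp` are skipped, which also caps the candidate span.
#'
#' @param panel a filtered [haplotype_panel()].
#' @param min_snps minimum markers per region (default 2).
#' @param strong_fraction minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @param max_pair_span_bp pair-span cap in bp (default 2.5 Mb).
#' @param require_end_pair require the end markers to be a strong pair
#'   (default `TRUE`).
#' @param strong_low,strong_high,recomb_high,conf,grid_n passed through to
#'   the pair classifier.
#' @return Data frame of class `core_regions` with columns `chrom`,
#'   `start_pos`, `end_pos`, `first_idx`, `last_idx`, `n_snps`,
#'   `length_kb`; indices refer to the panel's global marker order.
#' @export
detect_core_regions <- function(panel, min_snps = 2L, strong_fraction = 0.95,
                                max_pair_span_bp = 2.5e6,
                                require_end_pair = TRUE,
                                strong_low = 0.70, strong_high = 0.98,
                                recomb_high = 0.90, conf = 0.90,
                                grid_n = 101L) {
  out <- lapply(unique(panel$markers$chrom), function(chr) {
    idx <- chrom_indices(panel, chr)
    if (length(idx) < min_snps) return(NULL)
    pl <- pairwise_ld(panel, chr, max_pair_span_bp = max_pair_span_bp,
                      conf = conf, grid_n = grid_n,
                      strong_low = strong_low, strong_high = strong_high,
                      recomb_high = recomb_high)
    detect_blocks_chrom(pl, idx, panel$markers$pos[idx], chr,
                        min_snps, strong_fraction, max_pair_span_bp,
                        require_end_pair)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), first_idx = integer(),
                      last_idx = integer(), n_snps = integer(),
                      length_kb = numeric())
  }
  rownames(res) <- NULL
  class(res) <- c("core_regions", "data.frame")
  res
}

# One chromosome's block search on a precomputed pair table. Uses banded
# cumulative counts so each interval extension is scored in O(1).
detect_blocks_chrom <- function(pl, idx, pos, chr, min_snps, strong_fraction,
                                max_pair_span_bp, require_end_pair) {
  M <- length(idx)
  if (M < min_snps || nrow(pl) == 0) return(NULL)
  li <- match(pl$i, idx); lj <- match(pl$j, idx)
  d <- lj - li
  maxD <- max(d)
  strongM <- matrix(0L, maxD, M)
  informM <- matrix(0L, maxD, M)
  sel <- cbind(d, lj)
  strongM[sel] <- as.integer(pl$class == "strong_ld")
  informM[sel] <- as.integer(pl$class != "uninformative")
  cumS <- apply(strongM, 2, cumsum)
  cumI <- apply(informM, 2, cumsum)
  if (maxD == 1L) { cumS <- matrix(cumS, 1L); cumI <- matrix(cumI, 1L) }

  cand <- vector("list", M)
  for (i in seq_len(M - 1L)) {
    nS <- 0L; nI <- 0L
    jmax <- i
    while (jmax < M && pos[jmax + 1L] - pos[i] <= max_pair_span_bp) {
      jmax <- jmax + 1L
    }
    if (jmax - i + 1L < min_snps) next
    rows <- list(); nr <- 0L
    for (j in (i + 1L):jmax) {
      dd <- min(j - i, maxD)
      nS <- nS + cumS[dd, j]
      nI <- nI + cumI[dd, j]
      if (j - i + 1L < min_snps || nI == 0L) next
      if (nS / nI < strong_fraction) next
      if (require_end_pair) {
        de <- j - i
        if (de > maxD || strongM[de, j] == 0L) next
      }
      nr <- nr + 1L
      rows[[nr]] <- c(i, j)
    }
    if (nr > 0L) cand[[i]] <- do.call(rbind, rows)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand)) return(NULL)
  len <- pos[cand[, 2]] - pos[cand[, 1]]
  ord <- order(-len, pos[cand[, 1]], cand[, 1])
  used <- rep(FALSE, M)
  keep <- integer(0)
  for (k in ord) {
    span <- cand[k, 1]:cand[k, 2]
    if (any(used[span])) next
    used[span] <- TRUE
    keep <- c(keep, k)
  }
  keep <- keep[order(cand[keep, 1])]
  data.frame(chrom = chr,
             start_pos = pos[cand[keep, 1]],
             end_pos = pos[cand[keep, 2]],
             first_idx = idx[cand[keep, 1]],
             last_idx = idx[cand[keep, 2]],
             n_snps = cand[keep, 2] - cand[keep, 1] + 1L,
             length_kb = (pos[cand[keep, 2]] - pos[cand[keep, 1]]) / 1000)
}

#' Summarise core regions per chromosome
#'
#' Produces the standard per-chromosome bookkeeping table: marker counts,
#' chromosome span, mean adjacent-marker spacing, region count, mean /
#' summed / maximum region length, fraction of the chromosome covered by
#' regions, markers participating in regions, and their fraction of all
#' markers. A final `total` row aggregates the genome (mean region length
#' there is coverage divided by region count; ratios use genome-wide
#' totals).
#'
#' @param regions output of [detect_core_regions()].
#' @param panel the panel the regions were detected on.
#' @return Data frame with one row per chromosome plus a `total` row.
#' @export
summarize_core_regions <- function(regions, panel) {
  chroms <- unique(panel$markers$chrom)
  rows <- lapply(chroms, function(chr) {
    idx <- chrom_indices(panel, chr)
    pos <- panel$markers$pos[idx]
    rg <- regions[regions$chrom == chr, , drop = FALSE]
    chrom_len_kb <- if (length(pos) > 1) (max(pos) - min(pos)) / 1000 else 0
    cr_snps <- sum(rg$n_snps)
    data.frame(
      chrom = chr,
      n_snp = length(idx),
      chrom_length_kb = chrom_len_kb,
      mean_spacing_kb = if (length(pos) > 1) mean(diff(pos)) / 1000 else NA_real_,
      n_cr = nrow(rg),
      mean_cr_length_kb = if (nrow(rg) > 0) mean(rg$length_kb) else 0,
      coverage_cr_kb = sum(rg$length_kb),
      max_cr_length_kb = if (nrow(rg) > 0) max(rg$length_kb) else 0,
      cr_length_ratio = if (chrom_len_kb > 0) sum(rg$length_kb) / chrom_len_kb else 0,
      cr_snps = cr_snps,
      max_cr_snps = if (nrow(rg) > 0) max(rg$n_snps) else 0L,
      cr_snp_ratio = if (length(idx) > 0) cr_snps / length(idx) else 0
    )
  })
  per <- do.call(rbind, rows)
  tot <- data.frame(
    chrom = "total",
    n_snp = sum(per$n_snp),
    chrom_length_kb = sum(per$chrom_length_kb),
    mean_spacing_kb = {
      sp <- unlist(lapply(chroms, function(chr) {
        diff(panel$markers$pos[chrom_indices(panel, chr)])
      }))
      if (length(sp) > 0) mean(sp) / 1000 else NA_real_
    },
    n_cr = sum(per$n_cr),
    mean_cr_length_kb = if (sum(per$n_cr) > 0)
      sum(per$coverage_cr_kb) / sum(per$n_cr) else 0,
    coverage_cr_kb = sum(per$coverage_cr_kb),
    max_cr_length_kb = max(per$max_cr_length_kb),
    cr_length_ratio = if (sum(per$chrom_length_kb) > 0)
      sum(per$coverage_cr_kb) / sum(per$chrom_length_kb) else 0,
    cr_snps = sum(per$cr_snps),
    max_cr_snps = max(per$max_cr_snps),
    cr_snp_ratio = if (sum(per$n_snp) > 0) sum(per$cr_snps) / sum(per$n_snp) else 0
  )
  out <- rbind(per, tot)
  rownames(out) <- NULL
  out
}
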