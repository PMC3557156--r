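#' Phased two-locus haplotype counts
#'
#' Because input haplotypes are phased, two-locus haplotype counts are a
#' direct tally over rows: `n00` counts haplotypes carrying allele 0 at
#' both markers, `n01` allele 0 at marker `i` and allele 1 at marker `j`,
#' and so on.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j distinct marker column indices.
#' @return Named list `n00`, `n01`, `n10`, `n11`, `n` (= H).
#' @export
two_locus_counts <- function(panel, i, j) {
  M <- ncol(panel$haplotypes)
  if (i == j) stop("two_locus_counts needs two distinct markers")
  if (i < 1 || j < 1 || i > M || j > M) {
    stop("marker index out of range (M = ", M, ")")
  }
  a <- panel$haplotypes[, i]
  b <- panel$haplotypes[, j]
  n11 <- sum(a == 1L & b == 1L)
  n10 <- sum(a == 1L & b == 0L)
  n01 <- sum(a == 0L & b == 1L)
  n00 <- sum(a == 0L & b == 0L)
  list(n00 = n00, n01 = n01, n10 = n10, n11 = n11, n = length(a))
}

#' Two-locus LD coefficients D, D' and r-squared
#'
#' Frequency-based estimates from phased counts. With `pA`, `pB` the
#' frequencies of allele 1 at the two markers and `p11` the frequency of
#' the 1-1 haplotype: `D = p11 - pA*pB`; `D' = |D| / Dmax`, where `Dmax`
#' is `min(pA*(1-pB), (1-pA)*pB)` for positive `D` and
#' `min(pA*pB, (1-pA)*(1-pB))` for negative `D`; and
#' `r2 = D^2 / (pA*(1-pA)*pB*(1-pB))`. `D = 0` yields `D' = 0`.
#'
#' @param counts output of [two_locus_counts()] (or a compatible list).
#' @return List `D`, `Dprime`, `r2`, `informative`. A pair involving a
#'   monomorphic marker is flagged `informative = FALSE` with `NA` stats.
#' @export
ld_stats <- function(counts) {
  n <- counts$n00 + counts$n01 + counts$n10 + counts$n11
  pA <- (counts$n10 + counts$n11) / n
  pB <- (counts$n01 + counts$n11) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                informative = FALSE))
  }
  D <- counts$n11 / n - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, Dprime = Dprime, r2 = r2, informative = TRUE)
}

#' Likelihood-based confidence bounds on |D'|
#'
#' Evaluates the multinomial likelihood of the observed two-locus counts on
#' an even grid of |D'| values in [0, 1], holding allele frequencies fixed
#' at their sample estimates and reconstructing the four haplotype
#' probabilities from each grid value (floored at a small positive constant
#' before taking logs). The likelihood is normalised to sum to one over the
#' grid; the bounds are the smallest grid values at which the cumulative
#' normalised likelihood reaches `(1 - conf)/2` and `1 - (1 - conf)/2`.
#' With the default 0.90 two-sided coverage these are the 5th and 95th
#' percentile bounds used by the confidence-interval block rule.
#'
#' @param counts output of [two_locus_counts()].
#' @param conf two-sided coverage of the interval (default 0.90).
#' @param grid_n number of grid points on [0, 1] (default 101).
#' @param floor_p likelihood floor for degenerate haplotype probabilities.
#' @return List `ci_low`, `ci_high`, `informative`.
#' @export
dprime_ci <- function(counts, conf = 0.90, grid_n = 101L, floor_p = 1e-10) {
  st <- ld_stats(counts)
  if (!st$informative) {
    return(list(ci_low = NA_real_, ci_high = NA_real_, informative = FALSE))
  }
  ci <- dprime_ci_batch(counts$n00, counts$n01, counts$n10, counts$n11,
                        conf = conf, grid_n = grid_n, floor_p = floor_p)
  list(ci_low = ci$lo[1], ci_high = ci$hi[1], informative = TRUE)
}

# Vectorised CI over many pairs at once; the single-pair exported wrapper
# and the genome scan share this code path.
dprime_ci_batch <- function(n00, n01, n10, n11, conf = 0.90, grid_n = 101L,
                            floor_p = 1e-10) {
  n <- n00 + n01 + n10 + n11
  pA <- (n10 + n11) / n
  pB <- (n01 + n11) / n
  D <- n11 / n - pA * pB
  neg <- D < 0
  if (any(neg)) {          # recode allele B so D >= 0 for every pair
    tmp <- n00[neg]; n00[neg] <- n01[neg]; n01[neg] <- tmp
    tmp <- n10[neg]; n10[neg] <- n11[neg]; n11[neg] <- tmp
    pB[neg] <- 1 - pB[neg]
  }
  Dmax <- pmin(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(0, 1, length.out = grid_n)
  P <- length(n00)
  ll <- matrix(0, P, grid_n)
  for (k in seq_len(grid_n)) {
    Dk <- grid[k] * Dmax
    p11 <- pmax(pA * pB + Dk, floor_p)
    p10 <- pmax(pA * (1 - pB) - Dk, floor_p)
    p01 <- pmax((1 - pA) * pB - Dk, floor_p)
    p00 <- pmax((1 - pA) * (1 - pB) + Dk, floor_p)
    ll[, k] <- n00 * log(p00) + n01 * log(p01) + n10 * log(p10) +
      n11 * log(p11)
  }
  w <- exp(ll - apply(ll, 1, max))
  cw <- matrixStats_row_cumsum(w)
  cw <- cw / cw[, grid_n]
  alpha <- (1 - conf) / 2
  lo <- grid[first_reach(cw, alpha)]
  hi <- grid[first_reach(cw, 1 - alpha)]
  list(lo = lo, hi = hi)
}

# Row-wise cumulative sums without transposing twice per call.
matrixStats_row_cumsum <- function(m) {
  out <- m
  for (k in 2:ncol(m)) out[, k] <- out[, k - 1] + m[, k]
  out
}

# First column index where each row reaches `thr` (cumulative rows end at 1,
# so a hit always exists up to numerical slack at the last column).
first_reach <- function(cw, thr) {
  hit <- cw >= thr - 1e-12
  hit[, ncol(cw)] <- TRUE
  max.col(hit, ties.method = "first")
}

#' Classify a marker pair by its D' confidence bounds
#'
#' Implements the confidence-interval rule used for haplotype-block
#' detection: a pair is `strong_ld` when the lower bound clears
#' `strong_low` and the upper bound clears `strong_high`; it shows
#' `strong_recombination` when the upper bound falls below `recomb_high`;
#' anything else is `inconclusive`. A pair without bounds (monomorphic
#' marker) is `uninformative`.
#'
#' @param stats list with `ci_low`, `ci_high` (and optionally
#'   `informative`), e.g. the output of [dprime_ci()].
#' @param strong_low lower-bound threshold for strong LD (default 0.70).
#' @param strong_high upper-bound threshold for strong LD (default 0.98).
#' @param recomb_high upper-bound threshold below which historical
#'   recombination is evident (default 0.90).
#' @return One of `"strong_ld"`, `"strong_recombination"`,
#'   `"inconclusive"`, `"uninformative"`.
#' @export
classify_pair <- function(stats, strong_low = 0.70, strong_high = 0.98,
                          recomb_high = 0.90) {
  if (!is.null(stats$informative) && !stats$informative) return("uninformative")
  if (is.na(stats$ci_low) || is.na(stats$ci_high)) return("uninformative")
  if (stats$ci_low >= strong_low && stats$ci_high >= strong_high) {
    "strong_ld"
  } else if (stats$ci_high < recomb_high) {
    "strong_recombination"
  } else {
    "inconclusive"
  }
}
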