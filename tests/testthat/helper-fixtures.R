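# Shared fixtures and independent oracle implementations. Every oracle is
# deliberately written in the most literal style possible (explicit loops
# over pairs / intervals) so that agreement with the vectorized package
# code is meaningful.

toy_panel <- function(mat, pos = NULL, chrom = "1", line_label = "toy") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  n <- ncol(mat)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  markers <- data.frame(
    chrom = rep(chrom, length.out = n), pos = pos,
    id = sprintf("m%02d", seq_len(n)),
    ref_allele = rep("A", n), alt_allele = rep("G", n),
    stringsAsFactors = FALSE
  )
  haplotype_panel(mat, markers, line_label = line_label)
}

region_row <- function(panel, first_idx, last_idx) {
  data.frame(chrom = panel$markers$chrom[first_idx],
             start_pos = panel$markers$pos[first_idx],
             end_pos = panel$markers$pos[last_idx],
             first_idx = first_idx, last_idx = last_idx,
             n_snps = last_idx - first_idx + 1L,
             stringsAsFactors = FALSE)
}

# --- EHH oracle: literal pair counting --------------------------------

strings_over <- function(X, cols) {
  apply(X[, cols, drop = FALSE], 1, paste, collapse = "")
}

oracle_ehh <- function(panel, region, core_allele, direction, eval_idx) {
  X <- panel$haplotypes
  core_cols <- region$first_idx:region$last_idx
  carriers <- which(strings_over(X, core_cols) == core_allele)
  if (length(carriers) < 2) return(NA_real_)
  ext <- if (direction == "upstream") {
    eval_idx:(region$first_idx - 1L)
  } else {
    (region$last_idx + 1L):eval_idx
  }
  same <- 0L
  total <- 0L
  for (a in seq_along(carriers)) {
    for (b in seq_along(carriers)) {
      if (b <= a) next
      total <- total + 1L
      if (all(X[carriers[a], ext] == X[carriers[b], ext])) same <- same + 1L
    }
  }
  same / total
}

oracle_ehh_bar <- function(panel, region, core_allele, direction, eval_idx) {
  X <- panel$haplotypes
  core_cols <- region$first_idx:region$last_idx
  others <- which(strings_over(X, core_cols) != core_allele)
  if (length(others) < 2) return(NA_real_)
  ext <- if (direction == "upstream") {
    eval_idx:(region$first_idx - 1L)
  } else {
    (region$last_idx + 1L):eval_idx
  }
  span <- c(core_cols, ext)
  same <- 0L
  total <- 0L
  for (a in seq_along(others)) {
    for (b in seq_along(others)) {
      if (b <= a) next
      total <- total + 1L
      if (all(X[others[a], span] == X[others[b], span])) same <- same + 1L
    }
  }
  same / total
}

# --- LD oracle: textbook frequency formulas ---------------------------

oracle_ld <- function(panel, i, j) {
  a <- panel$haplotypes[, i]
  b <- panel$haplotypes[, j]
  n <- length(a)
  pA <- mean(a)
  pB <- mean(b)
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       Dprime = if (D == 0) 0 else abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# --- D' confidence-interval oracle: independent grid likelihood -------

oracle_dprime_ci <- function(n00, n01, n10, n11, conf = 0.90,
                             grid_n = 101, floor_p = 1e-10) {
  n <- n00 + n01 + n10 + n11
  pA <- (n10 + n11) / n   # allele 1 at locus A
  pB <- (n01 + n11) / n   # allele 1 at locus B
  pAB_obs <- n11 / n
  D_obs <- pAB_obs - pA * pB
  # orient so that D >= 0 by swapping allele coding at locus B
  if (D_obs < 0) {
    tmp <- n00; n00 <- n01; n01 <- tmp
    tmp <- n10; n10 <- n11; n11 <- tmp
    pB <- 1 - pB
  }
  Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(0, 1, length.out = grid_n)
  loglik <- numeric(grid_n)
  for (k in seq_len(grid_n)) {
    D <- grid[k] * Dmax
    p11 <- pA * pB + D
    p10 <- pA * (1 - pB) - D
    p01 <- (1 - pA) * pB - D
    p00 <- (1 - pA) * (1 - pB) + D
    ps <- pmax(c(p00, p01, p10, p11), floor_p)
    loglik[k] <- n00 * log(ps[1]) + n01 * log(ps[2]) +
      n10 * log(ps[3]) + n11 * log(ps[4])
  }
  lik <- exp(loglik - max(loglik))
  cum <- cumsum(lik) / sum(lik)
  lo_q <- (1 - conf) / 2
  hi_q <- 1 - lo_q
  lo <- grid[which(cum >= lo_q - 1e-12)[1]]
  hi <- grid[which(cum >= hi_q - 1e-12)[1]]
  list(lo = lo, hi = hi)
}

# --- Block-detection oracle: exhaustive interval enumeration ----------

oracle_blocks <- function(panel, chrom = "1", min_snps = 2,
                          strong_fraction = 0.95,
                          max_pair_span_bp = 2.5e6,
                          require_end_pair = TRUE, ...) {
  idx <- which(panel$markers$chrom == chrom)
  pos <- panel$markers$pos
  cls <- function(i, j) {
    st <- ld_stats(two_locus_counts(panel, i, j))
    classify_pair(c(st, dprime_ci(two_locus_counts(panel, i, j), ...)))
  }
  cands <- list()
  for (i in idx) {
    for (j in idx) {
      if (j <= i || j - i + 1 < min_snps) next
      if (pos[j] - pos[i] > max_pair_span_bp) next
      n_strong <- 0L
      n_inform <- 0L
      for (a in i:j) {
        for (b in i:j) {
          if (b <= a) next
          cl <- cls(a, b)
          if (cl != "uninformative") n_inform <- n_inform + 1L
          if (cl == "strong_ld") n_strong <- n_strong + 1L
        }
      }
      if (n_inform == 0) next
      if (n_strong / n_inform < strong_fraction) next
      if (require_end_pair && cls(i, j) != "strong_ld") next
      cands[[length(cands) + 1L]] <-
        data.frame(first_idx = i, last_idx = j, len = pos[j] - pos[i])
    }
  }
  if (length(cands) == 0) {
    return(data.frame(first_idx = integer(), last_idx = integer()))
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(-cands$len, cands$first_idx), , drop = FALSE]
  used <- logical(length(pos))
  keep <- list()
  for (k in seq_len(nrow(cands))) {
    span <- cands$first_idx[k]:cands$last_idx[k]
    if (any(used[span])) next
    used[span] <- TRUE
    keep[[length(keep) + 1L]] <- cands[k, c("first_idx", "last_idx")]
  }
  out <- do.call(rbind, keep)
  out[order(out$first_idx), , drop = FALSE]
}

# --- Interval-overlap oracle: all pairs -------------------------------

oracle_overlap <- function(regions, features) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    found <- FALSE
    for (k in seq_len(nrow(features))) {
      if (regions$chrom[i] != features$chrom[k]) next
      ov <- min(regions$end_pos[i], features$end[k]) -
        max(regions$start_pos[i], features$start[k]) + 1
      if (ov <= 0) next
      found <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = regions$chrom[i], start_pos = regions$start_pos[i],
        end_pos = regions$end_pos[i], feature = features$name[k],
        overlap_bp = ov, stringsAsFactors = FALSE
      )
    }
    if (!found) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = regions$chrom[i], start_pos = regions$start_pos[i],
        end_pos = regions$end_pos[i], feature = "/",
        overlap_bp = 0, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# EHH of a core haplotype at the first marker at least `distance_bp`
# beyond the region boundary (NA when the chromosome ends first).
ehh_at_distance <- function(panel, region, core_allele, distance_bp,
                            direction = "downstream") {
  idx <- which(panel$markers$chrom == region$chrom)
  pos <- panel$markers$pos
  if (direction == "downstream") {
    flank <- idx[idx > region$last_idx]
    target <- flank[pos[flank] >= region$end_pos + distance_bp]
    if (length(target) == 0) return(NA_real_)
    ehh_at(panel, region, core_allele, "downstream", min(target))
  } else {
    flank <- idx[idx < region$first_idx]
    target <- flank[pos[flank] <= region$start_pos - distance_bp]
    if (length(target) == 0) return(NA_real_)
    ehh_at(panel, region, core_allele, "upstream", max(target))
  }
}

# --- File fixtures ----------------------------------------------------

write_toy_vcf <- function(path, panel) {
  H <- nrow(panel$haplotypes)
  stopifnot(H %% 2 == 0)
  n_samp <- H / 2
  samples <- sprintf("S%02d", seq_len(n_samp))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(panel$markers)), function(k) {
    gts <- vapply(seq_len(n_samp), function(s) {
      paste0(panel$haplotypes[2 * s - 1, k], "|", panel$haplotypes[2 * s, k])
    }, character(1))
    paste(c(panel$markers$chrom[k], panel$markers$pos[k],
            panel$markers$id[k], panel$markers$ref_allele[k],
            panel$markers$alt_allele[k], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# A deterministic 48-haplotype x 10-marker panel with clear block structure:
# markers 1-4 and 7-10 each form two perfectly correlated haplotype groups
# (the 12 distinct rows are replicated 4x so the D' confidence bounds are
# tight enough for the Gabriel rule), while markers 5-6 are unlinked.
block_panel <- function() {
  g1 <- c(0, 0, 0, 0)
  g2 <- c(1, 1, 1, 1)
  left <- rbind(g1, g1, g1, g1, g1, g1, g1, g2, g2, g2, g2, g2)
  mid <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1,
                  0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1), ncol = 2)
  right <- rbind(g2, g1, g2, g1, g2, g1, g2, g1, g2, g1, g2, g1)
  mat <- cbind(left, mid, right)
  mat <- mat[rep(seq_len(nrow(mat)), times = 4), ]
  rownames(mat) <- NULL
  toy_panel(mat, pos = c(1000, 2000, 3000, 4000, 20000, 40000,
                         61000, 62000, 63000, 64000))
}
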