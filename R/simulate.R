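#' Parameters for the haplotype-panel simulator
#'
#' The generator emulates a SNP-chip panel from a small, recently founded
#' population under truncating MAF ascertainment: a founder pool carrying
#' standing variation drawn from the neutral 1/x frequency spectrum is
#' propagated by forward Wright-Fisher reproduction with per-generation
#' recombination (crossover count ~ Poisson(r * L), uniform breakpoints)
#' and infinite-sites mutation; haplotypes are sampled at the end and
#' markers below the MAF floor are dropped, mirroring chip filtering.
#' Defaults give ~22 kb marker spacing after filtering and block-scale LD
#' from the founder bottleneck.
#'
#' @param n_haplotypes haplotypes sampled per panel (even; default 100).
#' @param pop_size N, diploid population size (default 100, so 2N = 200
#'   haplotypes evolve).
#' @param n_generations generations of the final phase: the selection
#'   phase of [simulate_sweep()] and the post-split phase of
#'   [make_two_line_panel()]; extra neutral generations in
#'   [simulate_neutral()] (default 50).
#' @param chrom_length_bp L, chromosome length in bp (default 8 Mb).
#' @param n_chromosomes number of freely recombining chromosomes, each
#'   simulated with an independent genealogy (default 1).
#' @param target_n_snps target marker count per chromosome after the MAF
#'   floor (default 360; initial site count is twice this because drift
#'   fixes roughly half).
#' @param recomb_rate_per_bp r, crossover rate per bp per generation
#'   (default 3e-8).
#' @param mutation_rate_per_bp mu, infinite-sites mutation rate per bp per
#'   generation (default 1e-9; founder variation dominates).
#' @param n_founders founder haplotypes in the initial pool (default 32;
#'   fewer founders means stronger background LD).
#' @param maf_floor minor-allele-frequency ascertainment floor applied at
#'   sampling (default 0.05); the focal site is exempt.
#' @param sweep `NULL`, or a list with `focal_pos` (bp on chromosome 1;
#'   default mid-chromosome), `selection_coefficient` (s >= 0 for
#'   [simulate_sweep()]; applied as +s / -s to the two lines of
#'   [make_two_line_panel()]), `start_frequency` of the focal allele at
#'   the onset of selection, and optionally `final_frequency_range`, a
#'   sampled-frequency window the sweep replicate must realize (rejection
#'   over derived sub-seeds; default `c(0, 1)` rejects only loss and
#'   fixation).
#' @param n_burnin_generations neutral generations preceding the final
#'   phase; this is where background LD equilibrates (default 100).
#' @return A list of class `sweep_sim_params`.
#' @export
sweep_sim_params <- function(n_haplotypes = 100L, pop_size = 100L,
                             n_generations = 50L, chrom_length_bp = 8e6,
                             n_chromosomes = 1L, target_n_snps = 360L,
                             recomb_rate_per_bp = 3e-8,
                             mutation_rate_per_bp = 1e-9,
                             n_founders = 32L, maf_floor = 0.05,
                             sweep = NULL, n_burnin_generations = 100L) {
  stopifnot(n_haplotypes %% 2 == 0, n_haplotypes >= 4,
            n_haplotypes <= 2 * pop_size, n_generations >= 0,
            chrom_length_bp >= 1e5, n_founders >= 2)
  if (!is.null(sweep)) {
    if (is.null(sweep$focal_pos)) sweep$focal_pos <- chrom_length_bp / 2
    if (is.null(sweep$start_frequency)) sweep$start_frequency <- 0.1
    if (is.null(sweep$final_frequency_range)) {
      sweep$final_frequency_range <- c(0, 1)  # open interval: lost/fixed rejected
    }
    stopifnot(sweep$selection_coefficient > -1,
              sweep$start_frequency > 0, sweep$start_frequency < 1,
              length(sweep$final_frequency_range) == 2)
  }
  structure(list(
    n_haplotypes = as.integer(n_haplotypes), pop_size = as.integer(pop_size),
    n_generations = as.integer(n_generations),
    chrom_length_bp = chrom_length_bp,
    n_chromosomes = as.integer(n_chromosomes),
    target_n_snps = as.integer(target_n_snps),
    recomb_rate_per_bp = recomb_rate_per_bp,
    mutation_rate_per_bp = mutation_rate_per_bp,
    n_founders = as.integer(n_founders), maf_floor = maf_floor,
    sweep = sweep, n_burnin_generations = as.integer(n_burnin_generations)
  ), class = "sweep_sim_params")
}

# Integer sub-seed derivation, stable and below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629 + 1)
}

# Founder pool + initial population. Site frequencies follow the neutral
# 1/x spectrum truncated to [0.05, 0.95].
init_population <- function(params, L) {
  n_init <- 2L * params$target_n_snps
  pos <- sort(unique(ceiling(stats::runif(n_init) * (L - 1))))
  p0 <- 0.05 * 19^stats::runif(length(pos))
  founders <- matrix(
    stats::rbinom(params$n_founders * length(pos), 1L,
                  rep(p0, each = params$n_founders)),
    nrow = params$n_founders
  )
  fid <- sample.int(params$n_founders, 2L * params$pop_size, replace = TRUE)
  list(pop = founders[fid, , drop = FALSE], pos = pos, founder_id = fid)
}

# Insert the focal column at selection onset. Carriers are the k extant
# haplotypes most similar (Hamming distance within +/- 1 Mb of the focal
# position) to a randomly chosen seed haplotype, so the derived allele
# sits on one coherent extended background, as a recent mutation would.
inject_focal <- function(state, focal_pos, start_frequency) {
  if (is.unsorted(state$pos)) {   # mutations are appended out of order
    ord <- order(state$pos)
    state$pop <- state$pop[, ord, drop = FALSE]
    state$pos <- state$pos[ord]
  }
  twoN <- nrow(state$pop)
  k_target <- max(2L, round(start_frequency * twoN))
  win <- which(state$pos >= focal_pos - 2e6 & state$pos <= focal_pos + 2e6)
  seed_row <- sample.int(twoN, 1)
  if (length(win) > 0) {
    W <- state$pop[, win, drop = FALSE]
    ham <- rowSums(W != rep(W[seed_row, ], each = twoN))
    carriers <- order(ham, seq_len(twoN))[seq_len(k_target)]
    # Hard-sweep model: the favored allele arises on a single haplotype and
    # the injection frequency represents the early stochastic phase
    # conditioned on establishment, so every carrier starts as a copy of the
    # seed haplotype across the +/- 1 Mb window. Overwriting the rows most
    # similar to the seed minimizes the allele-frequency distortion.
    state$pop[carriers, win] <- rep(W[seed_row, ], each = k_target)
  } else {
    carriers <- seq_len(k_target)
  }
  col <- integer(twoN)
  col[carriers] <- 1L
  ins <- findInterval(focal_pos, state$pos)
  state$pop <- cbind(state$pop[, seq_len(ins), drop = FALSE], col,
                     if (ins < length(state$pos))
                       state$pop[, (ins + 1L):length(state$pos), drop = FALSE])
  colnames(state$pop) <- NULL
  state$pos <- append(state$pos, focal_pos, after = ins)
  state$focal_idx <- ins + 1L
  state
}

# One chromosome's Wright-Fisher propagation. Haploid-gamete scheme: each
# child haplotype recombines two parent haplotypes drawn (with fitness
# weighting at the focal site) from the previous generation.
evolve_population <- function(state, params, G, s = 0) {
  pop <- state$pop
  pos <- state$pos
  twoN <- nrow(pop)
  L <- params$chrom_length_bp
  rL <- params$recomb_rate_per_bp * L
  muL <- params$mutation_rate_per_bp * L
  focal <- state$focal_idx
  for (g in seq_len(G)) {
    w <- NULL
    if (s != 0 && !is.null(focal) && !is.na(focal)) {
      w <- 1 + s * pop[, focal]
      if (all(pop[, focal] == pop[1, focal])) w <- NULL  # fixed or lost
    }
    pa <- sample.int(twoN, twoN, replace = TRUE, prob = w)
    pb <- sample.int(twoN, twoN, replace = TRUE, prob = w)
    nx <- stats::rpois(twoN, rL)
    child <- pop[pa, , drop = FALSE]
    for (i in which(nx > 0)) {
      bp <- sort(stats::runif(nx[i], 0, L))
      seg <- findInterval(pos, bp) %% 2L == 1L
      if (any(seg)) child[i, seg] <- pop[pb[i], seg]
    }
    pop <- child
    nmut <- stats::rpois(1, twoN * muL)
    if (nmut > 0) {
      newcols <- matrix(0L, twoN, nmut)
      newcols[cbind(sample.int(twoN, nmut, replace = TRUE), seq_len(nmut))] <- 1L
      pop <- cbind(pop, newcols)
      pos <- c(pos, ceiling(stats::runif(nmut) * (L - 1)))
    }
  }
  state$pop <- pop
  state$pos <- pos
  state
}

# Sample H haplotypes and apply the MAF ascertainment floor.
sample_panel_chrom <- function(state, params, chrom_label) {
  rows <- sample.int(nrow(state$pop), params$n_haplotypes)
  X <- state$pop[rows, , drop = FALSE]
  p <- colMeans(X)
  maf <- pmin(p, 1 - p)
  keep <- maf >= params$maf_floor
  if (!is.null(state$focal_idx) && !is.na(state$focal_idx)) {
    keep[state$focal_idx] <- TRUE
  }
  # de-duplicate positions (mutation can hit an occupied bp)
  keep <- keep & !duplicated(state$pos)
  ord <- order(state$pos[keep])
  X <- X[, keep, drop = FALSE][, ord, drop = FALSE]
  pos <- state$pos[keep][ord]
  focal_pos <- if (!is.null(state$focal_idx) && !is.na(state$focal_idx))
    state$pos[state$focal_idx] else NA_real_
  list(X = X, pos = pos, chrom = chrom_label,
       focal_col = if (is.na(focal_pos)) NA_integer_ else match(focal_pos, pos))
}

assemble_panel <- function(chrom_parts, params, line_label) {
  X <- do.call(cbind, lapply(chrom_parts, `[[`, "X"))
  markers <- do.call(rbind, lapply(chrom_parts, function(p) {
    data.frame(chrom = p$chrom, pos = p$pos,
               id = sprintf("c%s_%09d", p$chrom, p$pos),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }))
  min_sites <- min(50L, params$target_n_snps * params$n_chromosomes)
  if (ncol(X) < min_sites) {
    stop("only ", ncol(X), " polymorphic sites survived sampling; ",
         "increase mutation_rate_per_bp, target_n_snps or n_founders")
  }
  n_ind <- params$n_haplotypes / 2
  ids <- as.vector(rbind(sprintf("ind%03d_1", seq_len(n_ind)),
                         sprintf("ind%03d_2", seq_len(n_ind))))
  haplotype_panel(X, markers, ids, line_label)
}

#' Simulate a neutral phased haplotype panel
#'
#' Forward Wright-Fisher simulation without selection; see
#' [sweep_sim_params()] for the generative model. Deterministic given
#' `(params, seed)`.
#'
#' @param params a [sweep_sim_params()] (the `sweep` element is ignored).
#' @param seed integer seed.
#' @return A [haplotype_panel()].
#' @export
simulate_neutral <- function(params = sweep_sim_params(), seed = 1L) {
  G <- params$n_burnin_generations + params$n_generations
  parts <- lapply(seq_len(params$n_chromosomes), function(chr) {
    set.seed(derive_seed(seed, chr))
    st <- init_population(params, params$chrom_length_bp)
    st$focal_idx <- NA_integer_
    st <- evolve_population(st, params, G, s = 0)
    sample_panel_chrom(st, params, as.character(chr))
  })
  assemble_panel(parts, params, "neutral")
}

#' Simulate a panel carrying a selective sweep
#'
#' As [simulate_neutral()], but on chromosome 1 a focal allele is placed
#' at `sweep$start_frequency` on a coherent extant haplotype background
#' after the neutral burn-in, and its carriers gain relative fitness
#' `1 + s` per generation for the `n_generations` selection phase. If the
#' focal allele is lost (or fixes) in the sampled panel the simulation
#' retries with derived sub-seeds up to 8 times, then errors.
#'
#' @param params a [sweep_sim_params()] with a non-`NULL` `sweep` element.
#' @param seed integer seed.
#' @return List with `panel` (a [haplotype_panel()]) and `truth`: the
#'   realized `focal_pos`, `focal_chrom`, `focal_marker_id`,
#'   `start_frequency_realized` (population frequency after injection),
#'   `focal_final_frequency` (in the sampled panel), and `attempt`.
#' @export
simulate_sweep <- function(params, seed = 1L) {
  if (is.null(params$sweep)) stop("params$sweep must be set for simulate_sweep")
  s <- params$sweep$selection_coefficient
  frange <- params$sweep$final_frequency_range
  max_attempts <- if (identical(frange, c(0, 1))) 8L else 40L
  for (attempt in seq_len(max_attempts)) {
    sub <- derive_seed(seed, 1000 + attempt)
    set.seed(sub)
    st <- init_population(params, params$chrom_length_bp)
    st$focal_idx <- NA_integer_
    st <- evolve_population(st, params, params$n_burnin_generations, s = 0)
    st <- inject_focal(st, params$sweep$focal_pos,
                       params$sweep$start_frequency)
    start_realized <- mean(st$pop[, st$focal_idx])
    st <- evolve_population(st, params, params$n_generations, s = s)
    part1 <- sample_panel_chrom(st, params, "1")
    f_final <- mean(part1$X[, part1$focal_col])
    if (f_final <= max(0, frange[1]) || f_final >= min(1, frange[2])) next
    parts <- c(list(part1), lapply(seq_len(params$n_chromosomes - 1L) + 1L,
      function(chr) {
        set.seed(derive_seed(seed, 2000 * attempt + chr))
        stn <- init_population(params, params$chrom_length_bp)
        stn$focal_idx <- NA_integer_
        stn <- evolve_population(
          stn, params, params$n_burnin_generations + params$n_generations,
          s = 0)
        sample_panel_chrom(stn, params, as.character(chr))
      }))
    panel <- assemble_panel(parts, params, "sweep")
    focal_pos <- part1$pos[part1$focal_col]
    truth <- list(
      focal_pos = focal_pos, focal_chrom = "1",
      focal_marker_id = sprintf("c1_%09d", focal_pos),
      start_frequency_realized = start_realized,
      focal_final_frequency = f_final, attempt = attempt
    )
    return(list(panel = panel, truth = truth))
  }
  stop("no attempt realized a focal frequency inside (",
       frange[1], ", ", frange[2], ") in ", max_attempts,
       " tries; adjust selection_coefficient, start_frequency or ",
       "n_generations")
}

#' Simulate a divergently selected pair of lines
#'
#' One ancestral population evolves neutrally for
#' `n_burnin_generations`; the focal allele is then placed on a coherent
#' haplotype background as in [simulate_sweep()], the population is split
#' into two daughter populations of the same size, and the two lines
#' experience opposite-sign selection (+s and -s) at the focal site for
#' `n_generations`. Both sampled panels share one marker map: sites
#' passing the MAF floor in the pooled sample are retained.
#'
#' @param params a [sweep_sim_params()] with a non-`NULL` `sweep` element
#'   (`selection_coefficient` is the magnitude applied as +s / -s).
#' @param seed integer seed.
#' @return List with `panel_up` (line selected for the focal allele,
#'   label `"up"`), `panel_down` (label `"down"`), and `truth` carrying
#'   the focal position and per-line final frequencies.
#' @export
make_two_line_panel <- function(params, seed = 1L) {
  if (is.null(params$sweep)) stop("params$sweep must be set")
  s <- params$sweep$selection_coefficient
  if (params$n_chromosomes != 1L) {
    stop("make_two_line_panel supports single-chromosome panels; ",
         "combine independent seeds for a larger genome")
  }
  for (attempt in 1:8) {
    set.seed(derive_seed(seed, 3000 + attempt))
    st <- init_population(params, params$chrom_length_bp)
    st$focal_idx <- NA_integer_
    st <- evolve_population(st, params, params$n_burnin_generations, s = 0)
    st <- inject_focal(st, params$sweep$focal_pos,
                       params$sweep$start_frequency)
    twoN <- nrow(st$pop)
    split_a <- st; split_a$pop <- st$pop[sample.int(twoN, twoN, replace = TRUE), ,
                                         drop = FALSE]
    split_b <- st; split_b$pop <- st$pop[sample.int(twoN, twoN, replace = TRUE), ,
                                         drop = FALSE]
    split_a <- evolve_population(split_a, params, params$n_generations, s = s)
    split_b <- evolve_population(split_b, params, params$n_generations, s = -s)
    rows_a <- sample.int(twoN, params$n_haplotypes)
    rows_b <- sample.int(twoN, params$n_haplotypes)
    # shared map: sites must align, so mutations after the split are
    # excluded and the pooled-sample MAF floor is applied jointly
    n_shared <- length(st$pos)
    Xa <- split_a$pop[rows_a, seq_len(n_shared), drop = FALSE]
    Xb <- split_b$pop[rows_b, seq_len(n_shared), drop = FALSE]
    pos <- st$pos[seq_len(n_shared)]
    p_pool <- colMeans(rbind(Xa, Xb))
    keep <- pmin(p_pool, 1 - p_pool) >= params$maf_floor
    keep[st$focal_idx] <- TRUE
    keep <- keep & !duplicated(pos)
    ord <- order(pos[keep])
    fa <- mean(Xa[, st$focal_idx]); fb <- mean(Xb[, st$focal_idx])
    if ((fa <= 0 || fa >= 1) && (fb <= 0 || fb >= 1) && s != 0) next
    mk <- function(X, label) {
      part <- list(X = X[, keep, drop = FALSE][, ord, drop = FALSE],
                   pos = pos[keep][ord], chrom = "1", focal_col = NA_integer_)
      assemble_panel(list(part), params, label)
    }
    truth <- list(
      focal_pos = st$pos[st$focal_idx], focal_chrom = "1",
      focal_marker_id = sprintf("c1_%09d", st$pos[st$focal_idx]),
      line_divergence = c(up = fa, down = fb), attempt = attempt
    )
    return(list(panel_up = mk(Xa, "up"), panel_down = mk(Xb, "down"),
                truth = truth))
  }
  stop("focal allele degenerate in both lines over 8 attempts; ",
       "adjust sweep parameters")
}
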