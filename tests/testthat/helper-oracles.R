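# Independent re-implementations used as oracles. These deliberately share
# no code with the package internals: the scoring model is re-derived from
# its documented definition and alignments are found by exhaustive
# enumeration rather than dynamic programming.

oracle_model <- function(p) {
  fp_frac <- p$fp_per_100kbp / (p$fp_per_100kbp + p$site_density_per_100kbp)
  p_err <- p$fn_rate + fp_frac - p$fn_rate * fp_frac
  p_err <- min(max(p_err, 1e-6), 0.999)
  mean_spacing <- 1e5 / p$site_density_per_100kbp
  sigma_bar <- p$sizing_sd_bp_per_kbp * mean_spacing / 1000
  p_chance <- min(max(4 * sigma_bar / mean_spacing, 1e-6), 0.9)
  list(skip = -log(p_err), reward = -log(p_chance),
       sizing_sd = p$sizing_sd_bp_per_kbp, max_skip = p$max_skip)
}

oracle_matching_score <- function(a, b, ia, ib, m) {
  # score of the monotone matching a[ia[k]] ~ b[ib[k]]; -Inf when a skip
  # bound is exceeded
  s <- m$reward
  if (length(ia) > 1) {
    for (k in 2:length(ia)) {
      ka <- ia[k] - ia[k - 1] - 1
      kb <- ib[k] - ib[k - 1] - 1
      if (ka > m$max_skip || kb > m$max_skip) return(-Inf)
      ga <- a[ia[k]] - a[ia[k - 1]]
      gb <- b[ib[k]] - b[ib[k - 1]]
      sigma <- max(m$sizing_sd * sqrt(ga^2 + gb^2) / 1000, 1e-6)
      s <- s + m$reward - 0.5 * (ga - gb)^2 / sigma^2 - (ka + kb) * m$skip
    }
  }
  s
}

# Best score over ALL monotone matchings with >= 2 pairs, both orientations
# of b; exhaustive enumeration, tractable for maps with <= 6 labels.
oracle_best_score <- function(a, b, len_b, p) {
  m <- oracle_model(p)
  best <- -Inf
  for (bo in list(b, len_b - rev(b))) {
    na <- length(a); nb <- length(bo)
    for (k in 2:min(na, nb)) {
      ia_sets <- utils::combn(na, k, simplify = FALSE)
      ib_sets <- utils::combn(nb, k, simplify = FALSE)
      for (ia in ia_sets) for (ib in ib_sets) {
        s <- oracle_matching_score(a, bo, ia, ib, m)
        if (s > best) best <- s
      }
    }
  }
  best
}

# A random labeled map: n labels over len bp with a minimum spacing.
random_map <- function(n, len = 1e5, min_gap = 2000) {
  repeat {
    pos <- sort(runif(n, min_gap, len))
    if (n < 2 || all(diff(pos) >= min_gap)) return(pos)
  }
}

# Random valid molecule set for round-trip property tests.
random_molecule_set <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- runif(n, 5e4, 3e5)
  labs <- lapply(lens, function(L) {
    k <- rpois(1, L / 1e4)
    sort(runif(k, 0.1, L))
  })
  molecules(seq_len(n), lens, labs)
}

random_contig_set <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- runif(n, 1e5, 1e6)
  labs <- lapply(lens, function(L) sort(runif(1 + rpois(1, L / 2e4), 0.1, L)))
  cov <- lapply(labs, function(l) 1L + rpois(length(l), 5))
  occ <- lapply(cov, function(cv) pmax(1L, cv - rpois(length(cv), 2)))
  contigs(seq_len(n), lens, labs, occurrence = occ, coverage = cov)
}

# Small simulated dataset shared by assembly-level tests.
toy_simulation <- function(ref_len = 4e5, coverage = 15, fp = 1, fn = 0.1,
                           seed = 5, mean_kbp = 60, min_kbp = 30) {
  set.seed(seed)
  ref <- random_reference(ref_len, 11)
  sim <- simulate_molecules(ref, coverage, length_model(mean_kbp, min_kbp),
                            error_profile(fp, fn, 30, seed = seed + 1))
  list(ref = ref, molecules = sim$molecules, truth = sim$truth)
}
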