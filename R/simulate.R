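#' Error profile for molecule simulation
#'
#' Describes the noise the nanochannel platform imposes on a true
#' restriction map: spurious labels, unlabeled sites, interval sizing
#' noise, and a global stretch. These are the same three error quantities
#' the aligner's parameters describe, so simulation and alignment share a
#' vocabulary.
#'
#' @param fp_per_100kbp Density of false-positive labels (labels observed at
#'   non-site positions), per 100 kbp of molecule length.
#' @param fn_rate Proportion of true restriction sites that go unlabeled
#'   (enzyme inefficiency), in `[0, 1]`.
#' @param sizing_sd_bp_per_kbp Standard deviation of inter-label distance
#'   noise, in bp per kbp of interval length (an interval of `g` kbp gets
#'   zero-mean Gaussian noise with sd `g * sizing_sd_bp_per_kbp`).
#' @param stretch_factor Global multiplicative length scaling (non-uniform
#'   stain/stretch behaviour); 1.0 = none.
#' @param chimera_rate Probability a simulated molecule is a chimeric join
#'   of two unrelated genomic intervals; 0 by default.
#' @param seed Optional integer seed applied by [simulate_molecules()].
#' @return A list of class `om_error_profile`.
#' @export
error_profile <- function(fp_per_100kbp = 1.0, fn_rate = 0.10,
                          sizing_sd_bp_per_kbp = 30, stretch_factor = 1.0,
                          chimera_rate = 0, seed = NULL) {
  stopifnot(fp_per_100kbp >= 0, fn_rate >= 0, fn_rate <= 1,
            sizing_sd_bp_per_kbp >= 0, stretch_factor > 0,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(fp_per_100kbp = fp_per_100kbp, fn_rate = fn_rate,
                 sizing_sd_bp_per_kbp = sizing_sd_bp_per_kbp,
                 stretch_factor = stretch_factor, chimera_rate = chimera_rate,
                 seed = seed),
            class = "om_error_profile")
}

#' Molecule length model
#'
#' Truncated-exponential molecule lengths: a hard minimum (molecules below
#' the instrument reporting threshold are never seen) plus an exponential
#' tail. The defaults give a length-weighted N50 near 165 kbp, matching
#' nanochannel runs of high-molecular-weight plant DNA.
#'
#' @param mean_kbp Mean molecule length in kbp.
#' @param min_kbp Minimum molecule length in kbp.
#' @param dist Distribution name; only `"truncexp"` is implemented.
#' @return A list of class `om_length_model`.
#' @export
length_model <- function(mean_kbp = 163, min_kbp = 100, dist = "truncexp") {
  stopifnot(mean_kbp > min_kbp, min_kbp > 0, dist == "truncexp")
  structure(list(mean_kbp = mean_kbp, min_kbp = min_kbp, dist = dist),
            class = "om_length_model")
}

draw_length_bp <- function(lm) {
  (lm$min_kbp + rexp(1, rate = 1 / (lm$mean_kbp - lm$min_kbp))) * 1000
}

# Extract one noisy molecule from a reference interval. Returns positions,
# realized length, and per-label provenance (global site index or NA for FP).
sim_one_interval <- function(ref_labels, start, len, orientation, err) {
  in_win <- which(ref_labels > start & ref_labels <= start + len)
  if (orientation > 0) {
    local <- ref_labels[in_win] - start
    prov <- in_win
  } else {
    local <- rev((start + len) - ref_labels[in_win])
    prov <- rev(in_win)
  }
  # false negatives: each true site labeled with probability 1 - fn_rate
  keep <- runif(length(local)) >= err$fn_rate
  local <- local[keep]; prov <- prov[keep]
  # false positives: homogeneous Poisson over the molecule
  n_fp <- rpois(1, err$fp_per_100kbp * len / 1e5)
  if (n_fp > 0) {
    fp_pos <- runif(n_fp, 0, len)
    ord <- order(c(local, fp_pos))
    prov <- c(prov, rep(NA_integer_, n_fp))[ord]
    local <- sort(c(local, fp_pos))
  }
  # drop coincident positions (measure-zero, but keep invariants exact)
  if (length(local) > 1) {
    dup <- c(FALSE, diff(local) <= 0)
    local <- local[!dup]; prov <- prov[!dup]
  }
  list(pos = local, prov = prov, len = len)
}

# Interval-proportional Gaussian sizing noise, clamped to preserve order.
apply_sizing_noise <- function(pos, len, sd_per_kbp) {
  if (sd_per_kbp <= 0) return(list(pos = pos, len = len))
  gaps <- diff(c(0, pos, len))
  sds <- sd_per_kbp * gaps / 1000
  noisy <- gaps + rnorm(length(gaps), 0, sds)
  noisy <- pmax(noisy, pmin(gaps * 0.1, 1))
  cum <- cumsum(noisy)
  n <- length(pos)
  list(pos = if (n) cum[seq_len(n)] else numeric(0), len = cum[length(cum)])
}

#' Simulate noisy molecules from a reference map
#'
#' Draws molecules from uniformly random reference intervals in random
#' orientation until the requested fold coverage is reached (within one
#' molecule), applying the error model: each true site in the interval is
#' retained with probability `1 - fn_rate`, false-positive labels arrive as
#' a Poisson process at `fp_per_100kbp`, inter-label distances receive
#' interval-proportional Gaussian sizing noise (clamped so label order is
#' preserved), and all coordinates are scaled by `stretch_factor`.
#'
#' @param ref An `om_contigs` reference map (e.g. from [digest_sequence()]
#'   or [random_reference()]).
#' @param coverage_fold Target fold coverage of the reference.
#' @param lmodel An [length_model()].
#' @param err An [error_profile()].
#' @return A list with elements `molecules` (an `om_molecules` table) and
#'   `truth`, a tibble recording each molecule's origin (`contig_id`,
#'   `start_bp`, `end_bp`, `orientation`) plus a `provenance` list-column
#'   giving, for each retained label, the reference site index (or `NA` for
#'   a false-positive label). The truth sidecar makes simulated datasets
#'   usable as accuracy oracles.
#' @export
simulate_molecules <- function(ref, coverage_fold, lmodel = length_model(),
                               err = error_profile()) {
  stopifnot(coverage_fold > 0, nrow(ref) >= 1)
  if (!is.null(err$seed)) set.seed(err$seed)
  if (lmodel$min_kbp * 1000 > max(ref$length_bp)) {
    abort("length model minimum exceeds every reference contig length")
  }
  ref_total <- sum(ref$length_bp)
  target <- coverage_fold * ref_total
  usable <- which(ref$length_bp >= lmodel$min_kbp * 1000)
  w <- ref$length_bp[usable]

  ids <- integer(0); lens <- numeric(0); labs <- list()
  t_contig <- integer(0); t_start <- numeric(0); t_end <- numeric(0)
  t_orient <- character(0); t_chim <- logical(0); t_prov <- list()
  total <- 0; id <- 0L
  while (total < target) {
    id <- id + 1L
    ci <- usable[sample.int(length(usable), 1, prob = w)]
    len <- min(draw_length_bp(lmodel), ref$length_bp[ci])
    start <- runif(1, 0, ref$length_bp[ci] - len)
    orient <- if (runif(1) < 0.5) 1 else -1
    one <- sim_one_interval(ref$labels_bp[[ci]], start, len, orient, err)
    chim <- runif(1) < err$chimera_rate
    if (chim) {
      cj <- usable[sample.int(length(usable), 1, prob = w)]
      len2 <- min(draw_length_bp(lmodel), ref$length_bp[cj])
      start2 <- runif(1, 0, ref$length_bp[cj] - len2)
      two <- sim_one_interval(ref$labels_bp[[cj]], start2, len2,
                              if (runif(1) < 0.5) 1 else -1, err)
      one <- list(pos = c(one$pos, one$len + two$pos),
                  prov = c(one$prov, rep(NA_integer_, length(two$prov))),
                  len = one$len + two$len)
    }
    noised <- apply_sizing_noise(one$pos, one$len, err$sizing_sd_bp_per_kbp)
    pos <- noised$pos * err$stretch_factor
    mlen <- noised$len * err$stretch_factor

    ids <- c(ids, id); lens <- c(lens, mlen); labs[[id]] <- pos
    t_contig <- c(t_contig, ref$contig_id[ci])
    t_start <- c(t_start, start); t_end <- c(t_end, start + len)
    t_orient <- c(t_orient, if (orient > 0) "+" else "-")
    t_chim <- c(t_chim, chim); t_prov[[id]] <- one$prov
    total <- total + mlen
  }
  ms <- molecules(ids, lens, labs,
                  metadata = c("# BNX File Version:\t1.2",
                               "# Label Channels:\t1",
                               sprintf("# omsweep simulated: coverage %.1f fp %.2f fn %.2f",
                                       coverage_fold, err$fp_per_100kbp, err$fn_rate)))
  truth <- tibble(molecule_id = ids, contig_id = t_contig, start_bp = t_start,
                  end_bp = t_end, orientation = t_orient, chimeric = t_chim,
                  provenance = t_prov)
  list(molecules = ms, truth = truth)
}

#' Write a simulation truth sidecar
#'
#' Tab-separated per-molecule origin records (molecule_id, contig_id,
#' start_bp, end_bp, orientation), the plain-text companion of a simulated
#' BNX file.
#'
#' @param truth Truth tibble from [simulate_molecules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- truth[, c("molecule_id", "contig_id", "start_bp", "end_bp", "orientation")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
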