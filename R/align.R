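#' Alignment parameters
#'
#' The error-model parameters that drive pairwise Rmap alignment, plus the
#' significance threshold for accepting an overlap. The three error
#' parameters mirror [error_profile()]: they are the aligner's *assumptions*
#' about the data, and sweeping them is how the assembler is tuned when the
#' true error profile is unknown.
#'
#' @param pvalue_threshold Overlap significance threshold: alignments with a
#'   larger p-value are rejected. An assumption about genome complexity.
#' @param fp_per_100kbp Assumed false-positive label density per 100 kbp.
#' @param fn_rate Assumed proportion of unlabeled true sites, in `[0, 1]`.
#' @param sizing_sd_bp_per_kbp Assumed sizing-noise sd, bp per kbp of
#'   interval.
#' @param site_density_per_100kbp Assumed true site density, used to convert
#'   the FP density into a per-label error probability and to set the
#'   chance-match baseline.
#' @param max_skip Maximum skipped labels per side between consecutive
#'   matched pairs in the DP (accuracy/speed knob).
#' @param null_reps Permutation replicates for [alignment_pvalue()].
#' @param pvalue_method `"auto"` (empirical, falling back to a fitted Gumbel
#'   upper tail when the observed score exceeds every permutation score),
#'   `"empirical"`, or `"gumbel"`.
#' @param null_score_min Score floor below which all-pairs scanning assigns
#'   p = 1 without running the permutation null (the null is only spent on
#'   overlaps that could possibly be significant).
#' @return A list of class `om_align_params`.
#' @export
align_params <- function(pvalue_threshold = 1e-4, fp_per_100kbp = 1.0,
                         fn_rate = 0.10, sizing_sd_bp_per_kbp = 30,
                         site_density_per_100kbp = 10, max_skip = 3,
                         null_reps = 100, pvalue_method = c("auto", "empirical", "gumbel"),
                         null_score_min = 0) {
  stopifnot(pvalue_threshold > 0, pvalue_threshold < 1,
            fp_per_100kbp >= 0, fn_rate >= 0, fn_rate <= 1,
            sizing_sd_bp_per_kbp > 0, site_density_per_100kbp > 0,
            max_skip >= 0, null_reps >= 0)
  structure(list(pvalue_threshold = pvalue_threshold,
                 fp_per_100kbp = fp_per_100kbp, fn_rate = fn_rate,
                 sizing_sd_bp_per_kbp = sizing_sd_bp_per_kbp,
                 site_density_per_100kbp = site_density_per_100kbp,
                 max_skip = as.integer(max_skip),
                 null_reps = as.integer(null_reps),
                 pvalue_method = match.arg(pvalue_method),
                 null_score_min = null_score_min),
            class = "om_align_params")
}

# Coerce a one-row molecule/contig table (or a bare list) to id/length/labels.
as_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    id <- if ("molecule_id" %in% names(x)) x$molecule_id else x$contig_id
    return(list(id = id, length_bp = x$length_bp, labels_bp = x$labels_bp[[1]]))
  }
  stopifnot(is.list(x), !is.null(x$length_bp), !is.null(x$labels_bp))
  list(id = x$id %||% NA_integer_, length_bp = x$length_bp,
       labels_bp = as.numeric(x$labels_bp))
}

#' Align two restriction maps
#'
#' Ends-free (overlap) dynamic-programming alignment of two label
#' sequences, in both orientations of `b`. A matched interval pair with
#' gaps `ga`, `gb` (skipping `ka`/`kb` labels since the previous match)
#' contributes
#' \deqn{R - (ga - gb)^2 / (2 \sigma^2) - (ka + kb) P}
#' where \eqn{\sigma^2 = (s/1000)^2 (ga^2 + gb^2)} combines the
#' interval-proportional sizing noise of both maps (sd `s` bp per kbp),
#' \eqn{P = -\log p_{err}} penalizes a skipped label as a false positive or
#' an unlabeled partner site, and the match reward \eqn{R = -\log p_{chance}}
#' is the log-odds against two labels co-locating by chance. Ties are broken
#' by more matched pairs, then smaller absolute offset, then forward
#' orientation. Reverse orientation reflects `b`'s labels through its
#' length; only `b` is ever reversed.
#'
#' @param a,b One-row `om_molecules`/`om_contigs` tables (or lists with
#'   `length_bp` and `labels_bp`).
#' @param p An [align_params()] object.
#' @param null_reps If > 0, a permutation p-value is attached (see
#'   [alignment_pvalue()]); the permutation stream is drawn from R's RNG, so
#'   set the seed for reproducibility.
#' @return A one-row tibble of class `om_alignment` with columns `id_a`,
#'   `id_b`, `orientation` (`"+"`/`"-"`), `offset_bp`, `score`, `n_matched`,
#'   `unmatched_a`, `unmatched_b`, `pvalue`, and a `matched_pairs`
#'   list-column (two-column matrix of label indices, `b` indices referring
#'   to the oriented label order); or `NULL` when no alignment with at least
#'   two matched pairs exists.
#' @export
align_pair <- function(a, b, p = align_params(), null_reps = 0) {
  ma <- as_map(a); mb <- as_map(b)
  if (!length(ma$labels_bp) || !length(mb$labels_bp)) {
    abort("both maps must carry at least one label")
  }
  if (any(!is.finite(ma$labels_bp)) || any(!is.finite(mb$labels_bp))) {
    abort("non-finite label positions")
  }
  r <- rmap_align_core(ma$labels_bp, mb$labels_bp, mb$length_bp,
                       p$fp_per_100kbp, p$fn_rate, p$sizing_sd_bp_per_kbp,
                       p$site_density_per_100kbp, p$max_skip, as.integer(null_reps))
  if (!isTRUE(r$found)) return(NULL)
  pv <- NA_real_
  if (null_reps > 0) pv <- pvalue_from_null(r$score, r$null_scores, p$pvalue_method)
  out <- tibble(
    id_a = as.integer(ma$id), id_b = as.integer(mb$id),
    orientation = if (r$orientation > 0) "+" else "-",
    offset_bp = r$offset_bp, score = r$score,
    n_matched = length(r$idx_a),
    unmatched_a = r$unmatched_a, unmatched_b = r$unmatched_b,
    pvalue = pv,
    matched_pairs = list(cbind(idx_a = r$idx_a, idx_b = r$idx_b))
  )
  class(out) <- c("om_alignment", class(out))
  out
}

# Empirical tail probability with +1 smoothing; Gumbel upper-tail
# extrapolation (moment fit) when the observed score exceeds every
# permutation score and the method allows it.
pvalue_from_null <- function(score, null_scores, method = "auto") {
  reps <- length(null_scores)
  finite <- null_scores[null_scores > -1e299]
  exceed <- sum(null_scores >= score)
  p_emp <- (1 + exceed) / (reps + 1)
  if (method == "empirical") return(p_emp)
  if (exceed > 0 && method == "auto") return(p_emp)
  if (length(finite) < 10 || sd(finite) == 0) return(p_emp)
  beta <- sd(finite) * sqrt(6) / pi
  mu <- mean(finite) - 0.5772156649 * beta
  z <- (score - mu) / beta
  p_g <- if (z > 30) exp(-z) else 1 - exp(-exp(-z))
  max(min(p_g, p_emp), 1e-300)
}

#' Permutation p-value for an alignment
#'
#' How probable is an overlap score this good between two *unrelated* maps?
#' The inter-label gaps of `b` are shuffled `null_reps` times, each shuffle
#' is realigned to `a` (both orientations), and the p-value is the fraction
#' of null scores at least as large as the observed score, with +1
#' smoothing: `p = (1 + #{null >= obs}) / (null_reps + 1)`. With
#' `method = "empirical"` the p-value therefore never falls below
#' `1/(null_reps + 1)`; `"auto"` (default) extrapolates below that
#' resolution with a Gumbel upper tail fitted to the null scores, which the
#' deep significance thresholds used in assembly sweeps require.
#'
#' @param al An `om_alignment` row from [align_pair()] on `(a, b)`.
#' @param a,b The aligned maps.
#' @param p An [align_params()] object.
#' @param null_reps Number of permutation replicates (>= 1).
#' @param seed Optional seed for the permutation stream.
#' @return A p-value in `(0, 1]`.
#' @export
alignment_pvalue <- function(al, a, b, p = align_params(),
                             null_reps = p$null_reps, seed = NULL) {
  if (null_reps < 1) abort("null_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ma <- as_map(a); mb <- as_map(b)
  r <- rmap_align_core(ma$labels_bp, mb$labels_bp, mb$length_bp,
                       p$fp_per_100kbp, p$fn_rate, p$sizing_sd_bp_per_kbp,
                       p$site_density_per_100kbp, p$max_skip,
                       as.integer(null_reps))
  if (!isTRUE(r$found)) abort("alignment not reproducible on (a, b)")
  pvalue_from_null(al$score, r$null_scores, p$pvalue_method)
}

#' Confidence score of an alignment p-value
#'
#' Confidence is the negative base-10 logarithm of the alignment p-value;
#' [pvalue_from_confidence()] is the inverse.
#'
#' @param pvalue P-value(s) in `(0, 1]`.
#' @return Non-negative confidence score(s).
#' @examples
#' confidence(1e-6)           # 6
#' pvalue_from_confidence(21.4)  # ~3.98e-22
#' @export
confidence <- function(pvalue) {
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  -log10(pvalue)
}

#' @rdname confidence
#' @param conf Non-negative confidence score(s).
#' @export
pvalue_from_confidence <- function(conf) {
  if (any(!is.finite(conf)) || any(conf < 0)) abort("confidence must be >= 0")
  10^(-conf)
}

# Deterministic, order-independent per-pair seed so p-values do not depend
# on the order or chunking in which pairs are evaluated.
pair_seed <- function(seed, id_a, id_b) {
  h <- rlang::hash(list(as.integer(seed), min(id_a, id_b), max(id_a, id_b)))
  strtoi(substr(h, 1, 7), 16L)
}
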