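#' Assembly contiguity metrics
#'
#' @param ct An `om_contigs` table (empty allowed).
#' @return A tibble with `total_length_bp`, `n50_bp` (length of the contig
#'   at which the descending cumulative sum first reaches half the total)
#'   and `longest_contig_bp`; zeros for an empty assembly.
#' @export
contiguity <- function(ct) {
  if (!nrow(ct)) {
    return(tibble(total_length_bp = 0, n50_bp = 0, longest_contig_bp = 0))
  }
  len <- sort(ct$length_bp, decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  tibble(total_length_bp = total, n50_bp = n50, longest_contig_bp = len[1])
}

#' Internal-consistency metrics of an assembly
#'
#' Two reference-free quality signals: the mean number of molecules in
#' which each consensus label was observed (`mean_label_depth`, the mean of
#' the per-label occurrence counts; 0 for an assembly with no contigs), and
#' the proportion of filtered input molecules that were incorporated rather
#' than excluded as singletons. The singleton denominator is the
#' post-filter molecule count.
#'
#' @param asm An `om_assembly`.
#' @param filtered_input The filtered `om_molecules` the assembly was built
#'   from.
#' @return A tibble with `mean_label_depth` and `nonsingleton_proportion`.
#' @export
internal_consistency <- function(asm, filtered_input) {
  occ <- unlist(asm$contigs$occurrence)
  depth <- if (length(occ)) mean(occ) else 0
  n_in <- nrow(filtered_input)
  prop <- if (n_in) 1 - length(asm$singletons) / n_in else 0
  tibble(mean_label_depth = depth, nonsingleton_proportion = prop)
}

#' Reference accuracy of an assembly
#'
#' Each contig is aligned to the reference map and its alignment
#' significance is expressed as a confidence score (the negative base-10
#' logarithm of the alignment p-value). The aggregate is the
#' contig-length-weighted mean confidence over contigs that align;
#' unaligned contigs are counted separately rather than contributing zero.
#'
#' The default alignment parameters here differ from molecule-level
#' alignment: consensus maps carry residual layout drift (label positions
#' are means over molecules placed by noisy pairwise offsets) and unmerged
#' spurious labels, so the sizing tolerance and assumed spurious-label
#' density are substantially larger than the raw-molecule error rates.
#'
#' @param ct An `om_contigs` table of assembled contigs.
#' @param reference An `om_contigs` reference map.
#' @param p An [align_params()] describing consensus-map (not molecule)
#'   error; its `null_reps` sets the permutation budget per contig.
#' @param seed Seed for the permutation streams.
#' @return A tibble with `weighted_mean_confidence` (NA when nothing
#'   aligns), `n_aligned`, `n_unaligned`, and a `per_contig` list-column
#'   (contig_id, length_bp, pvalue, confidence).
#' @export
accuracy <- function(ct, reference, p = consensus_align_params(), seed = 1L) {
  if (!nrow(reference)) abort("reference is empty")
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    best <- NULL
    for (r in seq_len(nrow(reference))) {
      if (ct$n_labels[i] < 2 || reference$n_labels[r] < 2) next
      set.seed(pair_seed(seed, ct$contig_id[i], 10000L + reference$contig_id[r]))
      al <- align_pair(ct[i, ], reference[r, ], p, null_reps = p$null_reps)
      if (is.null(al)) next
      if (is.null(best) || al$pvalue < best$pvalue) best <- al
    }
    tibble(contig_id = ct$contig_id[i], length_bp = ct$length_bp[i],
           pvalue = if (is.null(best)) NA_real_ else best$pvalue)
  })
  per <- dplyr::bind_rows(rows)
  if (!nrow(per)) {
    return(tibble(weighted_mean_confidence = NA_real_, n_aligned = 0L,
                  n_unaligned = 0L, per_contig = list(per)))
  }
  per$confidence <- ifelse(is.na(per$pvalue), NA_real_, confidence(pmax(per$pvalue, 1e-300)))
  ok <- !is.na(per$pvalue)
  wmc <- if (any(ok)) {
    sum(per$length_bp[ok] * per$confidence[ok]) / sum(per$length_bp[ok])
  } else NA_real_
  tibble(weighted_mean_confidence = wmc, n_aligned = sum(ok),
         n_unaligned = sum(!ok), per_contig = list(per))
}

#' Alignment parameters for consensus-vs-reference comparison
#'
#' Consensus label positions are cluster means over molecules placed by
#' noisy pairwise offsets, so adjacent labels carry several hundred bp of
#' quasi-independent drift, and unmerged false-positive clusters appear as
#' extra labels at a density well above the raw-molecule FP rate. These
#' defaults describe that consensus error model.
#'
#' @inheritParams align_params
#' @return An [align_params()] object.
#' @export
consensus_align_params <- function(pvalue_threshold = 0.5, fp_per_100kbp = 5,
                                   fn_rate = 0.15, sizing_sd_bp_per_kbp = 60,
                                   max_skip = 5, null_reps = 100,
                                   pvalue_method = "auto") {
  align_params(pvalue_threshold = pvalue_threshold,
               fp_per_100kbp = fp_per_100kbp, fn_rate = fn_rate,
               sizing_sd_bp_per_kbp = sizing_sd_bp_per_kbp,
               max_skip = max_skip, null_reps = null_reps,
               pvalue_method = pvalue_method)
}

#' Full quality report for one assembly
#'
#' Combines contiguity, internal consistency, and (when a reference is
#' supplied) reference accuracy into a one-row tibble, the per-assembly
#' record a parameter sweep tabulates.
#'
#' @param asm An `om_assembly`.
#' @param filtered_input The filtered input molecule set.
#' @param reference Optional `om_contigs` reference map.
#' @param opts [sweep_options()] supplying aligner settings for accuracy.
#' @param seed Seed for accuracy permutation streams.
#' @return A one-row tibble: `n_contigs`, contiguity columns,
#'   internal-consistency columns, and `weighted_mean_confidence` (NA
#'   without a reference).
#' @export
quality_report <- function(asm, filtered_input, reference = NULL,
                           opts = sweep_options(), seed = 1L) {
  qc <- dplyr::bind_cols(tibble(n_contigs = nrow(asm$contigs)),
                         contiguity(asm$contigs),
                         internal_consistency(asm, filtered_input))
  if (!is.null(reference)) {
    p <- consensus_align_params(null_reps = opts$null_reps,
                                pvalue_method = opts$pvalue_method)
    acc <- accuracy(asm$contigs, reference, p, seed = seed)
    qc$weighted_mean_confidence <- acc$weighted_mean_confidence
    qc$n_contigs_aligned <- acc$n_aligned
  } else {
    qc$weighted_mean_confidence <- NA_real_
    qc$n_contigs_aligned <- NA_integer_
  }
  qc
}

#' Flow-cell run statistics shipped with the package
#'
#' Per-flow-cell data-collection statistics for the nineteen nanochannel
#' runs of the *Gossypium raimondii* mapping dataset: date, quantity of
#' data (Mbp), molecule N50 (kbp) and observed label density per 100 kbp.
#'
#' @return A tibble with columns `date_run`, `quantity_mbp`,
#'   `molecule_n50_kbp`, `labels_per_100kbp`.
#' @export
flowcell_runs <- function() {
  path <- system.file("extdata", "flowcell_runs.tsv", package = "omsweep")
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Dataset-level summary of flow-cell runs
#'
#' Aggregates per-run statistics with quantity weighting: total data
#' collected, quantity-weighted mean molecule N50 and label density, the
#' maximum per-run density, and the implied fold coverage of the genome
#' (rounded to the nearest integer, as conventionally reported with "~").
#'
#' @param runs A tibble with `quantity_mbp`, `molecule_n50_kbp`,
#'   `labels_per_100kbp` (see [flowcell_runs()]).
#' @param genome_size_mbp Genome size in Mbp used for fold coverage.
#' @return A one-row tibble: `total_gbp`, `weighted_mean_n50_kbp`,
#'   `weighted_mean_density`, `max_density`, `coverage_fold`.
#' @export
dataset_stats <- function(runs, genome_size_mbp) {
  stopifnot(nrow(runs) >= 1, genome_size_mbp > 0)
  w <- runs$quantity_mbp
  tibble(
    total_gbp = sum(w) / 1000,
    weighted_mean_n50_kbp = sum(w * runs$molecule_n50_kbp) / sum(w),
    weighted_mean_density = sum(w * runs$labels_per_100kbp) / sum(w),
    max_density = max(runs$labels_per_100kbp),
    coverage_fold = round(sum(w) / genome_size_mbp))
}

#' Compare an assembly of simulated data against the simulation truth
#'
#' Uses the truth sidecar from [simulate_molecules()] to score an assembly
#' without alignment ambiguity: a contig is *consistent* when its member
#' molecules' true reference intervals chain into a single connected
#' region (any contig mixing disconnected regions is a false join), and
#' label recall is the fraction of reference sites that fall inside the
#' truth span of some consistent contig.
#'
#' @param asm An `om_assembly` built from simulated molecules.
#' @param truth Truth tibble from [simulate_molecules()].
#' @param reference The `om_contigs` reference the simulation drew from.
#' @return A one-row tibble: `n_contigs`, `false_joins`, `label_recall`.
#' @export
assembly_truth_metrics <- function(asm, truth, reference) {
  n_false <- 0L
  covered <- lapply(seq_len(nrow(reference)), function(i) {
    logical(reference$n_labels[i])
  })
  names(covered) <- as.character(reference$contig_id)
  if (nrow(asm$placements)) {
    for (ci in unique(asm$placements$contig_id)) {
      ids <- asm$placements$molecule_id[asm$placements$contig_id == ci]
      tr <- truth[truth$molecule_id %in% ids, , drop = FALSE]
      if (length(unique(tr$contig_id)) > 1L) { n_false <- n_false + 1L; next }
      iv <- tr[order(tr$start_bp), c("start_bp", "end_bp")]
      reach <- iv$end_bp[1]; connected <- TRUE
      for (k in seq_len(nrow(iv))[-1]) {
        if (iv$start_bp[k] > reach) { connected <- FALSE; break }
        reach <- max(reach, iv$end_bp[k])
      }
      if (!connected) { n_false <- n_false + 1L; next }
      rc <- as.character(tr$contig_id[1])
      sites <- reference$labels_bp[[match(tr$contig_id[1], reference$contig_id)]]
      hit <- sites >= min(iv$start_bp) & sites <= max(iv$end_bp)
      covered[[rc]] <- covered[[rc]] | hit
    }
  }
  n_sites <- sum(reference$n_labels)
  tibble(n_contigs = nrow(asm$contigs), false_joins = n_false,
         label_recall = if (n_sites) sum(unlist(covered)) / n_sites else NA_real_)
}
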