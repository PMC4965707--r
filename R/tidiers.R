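#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembly into a per-contig table
#'
#' @param x An `om_assembly`.
#' @param ... Unused.
#' @return A tibble with one row per contig: id, length, label count, mean
#'   occurrence and supporting molecule count.
#' @export
tidy.om_assembly <- function(x, ...) {
  support <- table(x$placements$contig_id)
  tibble(
    contig_id = x$contigs$contig_id,
    length_bp = x$contigs$length_bp,
    n_labels = x$contigs$n_labels,
    mean_occurrence = vapply(x$contigs$occurrence, function(o) {
      if (length(o)) mean(o) else 0
    }, numeric(1)),
    n_molecules = as.integer(support[as.character(x$contigs$contig_id)]))
}

#' One-row assembly summary
#'
#' @param x An `om_assembly`.
#' @param ... Unused.
#' @return A one-row tibble: contig count, contiguity metrics, placed and
#'   singleton molecule counts.
#' @export
glance.om_assembly <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_contigs = nrow(x$contigs)),
    contiguity(x$contigs),
    tibble(n_placed = nrow(x$placements),
           n_singletons = length(x$singletons)))
}

#' Per-combination sweep results as a flat table
#'
#' @param x An `om_sweep_result`.
#' @param ... Unused.
#' @return The `results` tibble without the `assembly` list-column.
#' @export
tidy.om_sweep_result <- function(x, ...) {
  dplyr::select(x$results, -"assembly")
}

#' One-row sweep summary
#'
#' @param x An `om_sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble: combination count, executed/planned step
#'   counts, and the naive-vs-planned savings ratio.
#' @export
glance.om_sweep_result <- function(x, ...) {
  rr <- resource_report(x)
  tot <- rr[rr$step_type == "total", ]
  tibble(n_combinations = nrow(x$results),
         steps_planned = tot$planned,
         steps_executed = tot$executed,
         steps_naive = tot$naive,
         savings_ratio = tot$savings_ratio)
}
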