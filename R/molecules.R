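#' Build a molecule table
#'
#' A molecule set is the package's representation of single-molecule
#' restriction maps (Rmaps): one row per molecule, with the ordered label
#' positions held in a list-column. All downstream steps (filtering,
#' alignment, assembly) consume and produce this shape, so results chain
#' with the pipe.
#'
#' @param molecule_id Positive integer ids, unique within the set.
#' @param length_bp Molecule lengths in base pairs (positive reals).
#' @param labels_bp List of numeric vectors: label positions in bp from the
#'   molecule start, strictly increasing, each in `(0, length_bp]`.
#' @param channel Label channel index (single-channel data uses 1).
#' @param source_run Optional free-text provenance tag per molecule.
#' @param metadata Named character vector of header metadata (kept as an
#'   attribute and written back to BNX headers).
#'
#' @return A tibble of class `om_molecules` with columns `molecule_id`,
#'   `length_bp`, `labels_bp` (list-column), `n_labels`, `channel`,
#'   `source_run`.
#' @examples
#' molecules(1:2, c(150e3, 2e5),
#'           list(c(1e4, 9e4), c(5e3, 1e5, 1.8e5)))
#' @export
molecules <- function(molecule_id = integer(), length_bp = numeric(),
                      labels_bp = list(), channel = 1L, source_run = NA_character_,
                      metadata = character()) {
  tb <- tibble(
    molecule_id = as.integer(molecule_id),
    length_bp = as.numeric(length_bp),
    labels_bp = unname(lapply(labels_bp, as.numeric)),
    n_labels = vapply(labels_bp, length, integer(1)),
    channel = as.integer(channel),
    source_run = as.character(source_run)
  )
  new_om_molecules(tb, metadata = metadata)
}

new_om_molecules <- function(tb, metadata = character()) {
  tb <- as_tibble(tb)
  if (!"n_labels" %in% names(tb)) {
    tb$n_labels <- vapply(tb$labels_bp, length, integer(1))
  }
  if (!"channel" %in% names(tb)) tb$channel <- 1L
  if (!"source_run" %in% names(tb)) tb$source_run <- NA_character_
  structure(tb, metadata = metadata,
            class = c("om_molecules", class(as_tibble(tb))))
}

#' Validate a molecule table
#'
#' Checks the structural invariants every Rmap must satisfy: unique positive
#' ids, positive lengths, strictly increasing label positions, and all
#' positions within `(0, length_bp]`.
#'
#' @param ms An `om_molecules` table.
#' @return `ms`, invisibly, if valid; otherwise an error naming the first
#'   offending molecule.
#' @export
validate_molecules <- function(ms) {
  stopifnot(is.data.frame(ms))
  if (anyDuplicated(ms$molecule_id)) {
    abort(paste0("duplicate molecule_id: ",
                 ms$molecule_id[anyDuplicated(ms$molecule_id)][1]))
  }
  if (nrow(ms) && (any(!is.finite(ms$length_bp)) || any(ms$length_bp <= 0))) {
    abort("molecule lengths must be finite and positive")
  }
  if (nrow(ms) && any(ms$molecule_id <= 0L)) abort("molecule ids must be positive")
  for (i in seq_len(nrow(ms))) {
    lab <- ms$labels_bp[[i]]
    if (!length(lab)) next
    if (any(!is.finite(lab))) {
      abort(sprintf("molecule %d: non-finite label position", ms$molecule_id[i]))
    }
    if (any(diff(lab) <= 0)) {
      abort(sprintf("molecule %d: label positions not strictly increasing",
                    ms$molecule_id[i]))
    }
    if (lab[1] <= 0 || lab[length(lab)] > ms$length_bp[i]) {
      abort(sprintf("molecule %d: label position outside (0, length]",
                    ms$molecule_id[i]))
    }
  }
  invisible(ms)
}

#' @export
print.om_molecules <- function(x, ...) {
  cat(sprintf("# Molecule set: %d molecules, %.2f Mbp total\n",
              nrow(x), sum(x$length_bp) / 1e6))
  NextMethod()
}

om_metadata <- function(ms) attr(ms, "metadata") %||% character()

#' Build a consensus / reference map table
#'
#' Consensus maps (assembled contigs) and in-silico digested references share
#' one representation: one row per contig with ordered label positions plus
#' per-label `occurrence` (molecules contributing the label) and `coverage`
#' (molecules spanning its position). For references both default to 1.
#'
#' @param contig_id Positive integer ids, unique.
#' @param length_bp Contig lengths in bp.
#' @param labels_bp List of strictly increasing numeric vectors.
#' @param occurrence,coverage Lists of non-negative integer vectors, same
#'   lengths as `labels_bp`; `occurrence[i] <= coverage[i]` element-wise.
#' @return A tibble of class `om_contigs`.
#' @export
contigs <- function(contig_id = integer(), length_bp = numeric(),
                    labels_bp = list(), occurrence = NULL, coverage = NULL) {
  labels_bp <- unname(lapply(labels_bp, as.numeric))
  if (is.null(occurrence)) occurrence <- lapply(labels_bp, function(l) rep(1L, length(l)))
  if (is.null(coverage)) coverage <- lapply(labels_bp, function(l) rep(1L, length(l)))
  tb <- tibble(
    contig_id = as.integer(contig_id),
    length_bp = as.numeric(length_bp),
    labels_bp = labels_bp,
    n_labels = vapply(labels_bp, length, integer(1)),
    occurrence = unname(lapply(occurrence, as.integer)),
    coverage = unname(lapply(coverage, as.integer))
  )
  structure(tb, class = c("om_contigs", class(tb)))
}

#' Validate a contig table
#'
#' @param ct An `om_contigs` table.
#' @return `ct` invisibly, or an error describing the violated invariant.
#' @export
validate_contigs <- function(ct) {
  stopifnot(is.data.frame(ct))
  if (anyDuplicated(ct$contig_id)) abort("duplicate contig_id")
  for (i in seq_len(nrow(ct))) {
    lab <- ct$labels_bp[[i]]
    occ <- ct$occurrence[[i]]
    cov <- ct$coverage[[i]]
    if (length(occ) != length(lab) || length(cov) != length(lab)) {
      abort(sprintf("contig %d: occurrence/coverage length mismatch", ct$contig_id[i]))
    }
    if (length(lab) && any(diff(lab) <= 0)) {
      abort(sprintf("contig %d: labels not strictly increasing", ct$contig_id[i]))
    }
    if (any(occ < 0) || any(cov < 0) || any(occ > cov)) {
      abort(sprintf("contig %d: requires 0 <= occurrence <= coverage", ct$contig_id[i]))
    }
  }
  invisible(ct)
}

#' @export
print.om_contigs <- function(x, ...) {
  cat(sprintf("# Consensus map set: %d contigs, %.2f Mbp, %d labels\n",
              nrow(x), sum(x$length_bp) / 1e6, sum(x$n_labels)))
  NextMethod()
}
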