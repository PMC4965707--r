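#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an assembly as consensus maps
#'
#' Draws each contig as a horizontal backbone with one tick per consensus
#' label, tick height proportional to label occurrence — the standard way
#' to eyeball an optical-map assembly.
#'
#' @param object An `om_assembly`.
#' @param max_contigs Plot at most this many contigs (longest first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.om_assembly <- function(object, max_contigs = 20, ...) {
  ct <- object$contigs
  ct <- ct[order(-ct$length_bp), , drop = FALSE]
  ct <- head(ct, max_contigs)
  if (!nrow(ct)) abort("assembly has no contigs to plot")
  labs <- dplyr::bind_rows(lapply(seq_len(nrow(ct)), function(i) {
    tibble(contig = factor(ct$contig_id[i]),
           pos_kbp = ct$labels_bp[[i]] / 1000,
           occurrence = ct$occurrence[[i]])
  }))
  backbones <- tibble(contig = factor(ct$contig_id),
                      len_kbp = ct$length_bp / 1000)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = backbones,
                          ggplot2::aes(x = 0, xend = .data$len_kbp,
                                       y = .data$contig, yend = .data$contig),
                          linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_point(data = labs,
                        ggplot2::aes(x = .data$pos_kbp, y = .data$contig,
                                     size = .data$occurrence),
                        shape = "|") +
    ggplot2::scale_size_continuous(range = c(2, 6)) +
    ggplot2::labs(x = "position (kbp)", y = "contig",
                  size = "label\noccurrence") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise alignment as a match diagram
#'
#' @param object An `om_alignment` row from [align_pair()].
#' @param a,b The two aligned maps.
#' @param ... Unused.
#' @return A ggplot object: the two label tracks with matched labels
#'   connected.
#' @export
autoplot.om_alignment <- function(object, a, b, ...) {
  ma <- as_map(a); mb <- as_map(b)
  bo <- if (object$orientation == "-") {
    rev(mb$length_bp - mb$labels_bp)
  } else mb$labels_bp
  mp <- object$matched_pairs[[1]]
  tracks <- dplyr::bind_rows(
    tibble(map = "a", pos_kbp = ma$labels_bp / 1000, y = 1),
    tibble(map = "b", pos_kbp = (bo + object$offset_bp) / 1000, y = 0))
  links <- tibble(xa = ma$labels_bp[mp[, 1]] / 1000,
                  xb = (bo[mp[, 2]] + object$offset_bp) / 1000)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = links,
                          ggplot2::aes(x = .data$xa, xend = .data$xb,
                                       y = 1, yend = 0),
                          colour = "steelblue") +
    ggplot2::geom_point(data = tracks,
                        ggplot2::aes(x = .data$pos_kbp, y = .data$y),
                        shape = "|", size = 4) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("b", "a"),
                                limits = c(-0.2, 1.2)) +
    ggplot2::labs(x = "position (kbp)", y = NULL,
                  title = sprintf("score %.1f, %d matched pairs, p = %.3g",
                                  object$score, object$n_matched,
                                  object$pvalue)) +
    ggplot2::theme_minimal()
}

#' Contiguity versus accuracy across a sweep
#'
#' Scatter of contig N50 against weighted mean confidence, one point per
#' parameter combination, faceted nowhere but coloured by significance
#' threshold — the diagnostic for whether reference-free metrics predict
#' accuracy on a given dataset.
#'
#' @param swept An `om_sweep_result` run with a reference.
#' @return A ggplot object.
#' @export
plot_sweep_quality <- function(swept) {
  df <- tidy(swept)
  if (all(is.na(df$weighted_mean_confidence))) {
    abort("sweep was run without a reference; no accuracy to plot")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n50_bp / 1000,
                                   y = .data$weighted_mean_confidence,
                                   colour = factor(.data$pvalue_threshold))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "contig N50 (kbp)", y = "weighted mean confidence",
                  colour = "significance\nthreshold") +
    ggplot2::theme_minimal()
}
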