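# CMAP: tab-separated consensus-map records, 9 canonical columns
# (CMapId ContigLength NumSites SiteID LabelChannel Position StdDev
#  Coverage Occurrence), one row per consensus label, grouped by contig.

cmap_cols <- c("CMapId", "ContigLength", "NumSites", "SiteID", "LabelChannel",
               "Position", "StdDev", "Coverage", "Occurrence")

#' Read a CMAP consensus-map file
#'
#' Records may be interleaved across contig ids; they are regrouped by
#' `CMapId` and ordered by `SiteID`. Per-label `Coverage` and `Occurrence`
#' columns are preserved.
#'
#' @param path Path to a CMAP file.
#' @return An `om_contigs` table (see [contigs()]).
#' @export
read_cmap <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) {
    return(contigs())
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9)) {
    abort(paste0("line ", which(nf < 9)[1], " of data: fewer than 9 CMAP columns"))
  }
  m <- do.call(rbind, lapply(f, function(x) as.numeric(x[1:9])))
  if (anyNA(m)) abort("non-numeric value in CMAP data row")
  colnames(m) <- cmap_cols
  df <- as.data.frame(m)
  df <- df[order(df$CMapId, df$SiteID), , drop = FALSE]
  by_id <- split(df, df$CMapId)
  ct <- contigs(
    contig_id = as.integer(names(by_id)),
    length_bp = vapply(by_id, function(d) d$ContigLength[1], numeric(1)),
    labels_bp = lapply(by_id, function(d) d$Position),
    occurrence = lapply(by_id, function(d) as.integer(d$Occurrence)),
    coverage = lapply(by_id, function(d) as.integer(d$Coverage))
  )
  validate_contigs(ct)
  ct
}

#' Write a CMAP consensus-map file
#'
#' Positions are written with one decimal place (round-trip stable to
#' 0.1 bp); `StdDev` is written as 0.0.
#'
#' @param ct An `om_contigs` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(ct, path) {
  validate_contigs(ct)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# CMAP File Version:\t0.1",
               "# Label Channels:\t1",
               paste0("#h ", paste(cmap_cols, collapse = "\t")),
               "#f int float int int int float float int int"), con)
  for (i in seq_len(nrow(ct))) {
    lab <- ct$labels_bp[[i]]
    if (!length(lab)) next
    rows <- sprintf("%d\t%.1f\t%d\t%d\t1\t%.1f\t0.0\t%d\t%d",
                    ct$contig_id[i], ct$length_bp[i], length(lab),
                    seq_along(lab), lab, ct$coverage[[i]], ct$occurrence[[i]])
    writeLines(rows, con)
  }
  invisible(path)
}
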