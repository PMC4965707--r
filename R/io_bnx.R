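# BNX 1.x, single label channel: '# '-prefixed header, then per molecule a
# '0' line (id, length), a '1' line (label positions, terminated by the
# molecule length), and optional QX quality lines which are ignored.

#' Read a BNX molecule file
#'
#' Parses the single-channel BNX 1.x layout used for nanochannel
#' single-molecule label data. Quality rows (`QX..`) are accepted and
#' ignored; unknown header lines are retained verbatim and written back by
#' [write_bnx()]. Record order is preserved.
#'
#' @param path Path to a BNX file.
#' @return An `om_molecules` table (see [molecules()]) with the file header
#'   in `attr(, "metadata")`.
#' @export
read_bnx <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  ver <- grep("^#\\s*BNX File Version", header, value = TRUE)
  if (!length(ver)) abort("not a BNX file: missing '# BNX File Version' header")
  vnum <- trimws(sub("^[^:]*:", "", ver[1]))
  if (!grepl("^1\\.", vnum)) {
    abort(paste0("unsupported BNX dialect: version ", vnum, " (only 1.x is supported)"))
  }

  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  ids <- integer(0); lens <- numeric(0); labs <- list()
  cur_id <- NA_integer_; cur_len <- NA_real_; pending <- FALSE
  flush <- function() {
    if (pending) abort(sprintf("molecule %d: missing '1' label line", cur_id))
  }
  for (k in body_idx) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    tag <- f[1]
    if (tag == "0") {
      flush()
      if (length(f) < 3) abort(paste0("line ", k, ": malformed molecule record"))
      cur_id <- as.integer(f[2]); cur_len <- as.numeric(f[3])
      if (is.na(cur_id) || is.na(cur_len) || cur_len <= 0) {
        abort(paste0("line ", k, ": malformed molecule record"))
      }
      pending <- TRUE
    } else if (tag == "1") {
      if (!pending) abort(paste0("line ", k, ": label line without molecule record"))
      pos <- as.numeric(f[-1])
      if (anyNA(pos)) abort(paste0("line ", k, ": non-numeric label position"))
      # the label line is terminated by the molecule length; drop that marker
      n <- length(pos)
      if (n && abs(pos[n] - cur_len) < 0.05) pos <- pos[-n]
      if (length(pos)) {
        if (any(diff(pos) <= 0)) {
          abort(paste0("line ", k, ": label positions not strictly increasing"))
        }
        if (pos[1] <= 0 || pos[length(pos)] > cur_len) {
          abort(paste0("line ", k, ": label position outside molecule length"))
        }
      }
      ids <- c(ids, cur_id); lens <- c(lens, cur_len); labs[[length(labs) + 1L]] <- pos
      pending <- FALSE
    } else if (grepl("^QX", tag)) {
      next
    } else {
      abort(paste0("line ", k, ": unrecognized record tag '", tag, "'"))
    }
  }
  flush()
  ms <- molecules(ids, lens, labs, metadata = header)
  validate_molecules(ms)
  ms
}

#' Write a BNX molecule file
#'
#' Inverse of [read_bnx()]: positions are written with one decimal place, so
#' a read/write round trip reproduces all fields to 0.1 bp. The set is
#' validated first; invalid input (e.g. duplicate ids) errors before any
#' output is produced.
#'
#' @param ms An `om_molecules` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(ms, path) {
  validate_molecules(ms)
  header <- om_metadata(ms)
  if (!any(grepl("^#\\s*BNX File Version", header))) {
    header <- c("# BNX File Version:\t1.2", "# Label Channels:\t1", header)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  for (i in seq_len(nrow(ms))) {
    writeLines(sprintf("0\t%d\t%.1f", ms$molecule_id[i], ms$length_bp[i]), con)
    pos <- c(ms$labels_bp[[i]], ms$length_bp[i])
    writeLines(paste(c("1", sprintf("%.1f", pos)), collapse = "\t"), con)
  }
  invisible(path)
}
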