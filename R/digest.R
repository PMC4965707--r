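#' In-silico digestion of a nucleotide sequence
#'
#' Finds every occurrence of one or two nicking-enzyme recognition motifs on
#' either strand and records the occurrence start (forward-strand
#' coordinates) as a label. Hits from both motifs and both strands are
#' merged into a single label channel, sorted, and duplicate positions
#' collapsed — mirroring dual-nicking experiments where two enzymes label
#' the same channel.
#'
#' @param sequence A nucleotide string over `{A,C,G,T,N}` (or a
#'   `Biostrings::DNAString`).
#' @param motifs Character vector of one or two recognition-site strings,
#'   e.g. `c("GCTCTTC", "CCTCAGC")` for Nt.BspQI and Nt.BbvCI.
#' @param contig_id Id for the resulting reference map.
#' @return A one-row `om_contigs` table.
#' @export
digest_sequence <- function(sequence, motifs, contig_id = 1L) {
  seq_str <- as.character(sequence)
  if (!nzchar(seq_str)) abort("empty sequence")
  if (!length(motifs) || any(!nzchar(motifs))) abort("motifs must be non-empty")
  subj <- Biostrings::DNAString(seq_str)
  hits <- unlist(lapply(motifs, function(m) {
    fwd <- Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(m), subj))
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(m)), subj))
    c(fwd, rev)
  }))
  pos <- sort(unique(as.numeric(hits)))
  contigs(contig_id = contig_id, length_bp = nchar(seq_str), labels_bp = list(pos))
}

#' Digest every sequence in a FASTA file
#'
#' @param fasta_path Path to a FASTA file.
#' @inheritParams digest_sequence
#' @return An `om_contigs` table, one row per FASTA record.
#' @export
digest_fasta <- function(fasta_path, motifs) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) abort("no sequences in FASTA")
  out <- lapply(seq_along(seqs), function(i) {
    digest_sequence(as.character(seqs[[i]]), motifs, contig_id = i)
  })
  dplyr::bind_rows(out)
}

#' Label density of a reference map
#'
#' @param ct An `om_contigs` table.
#' @return Labels per 100 kbp, aggregated over all contigs
#'   (`sum(n_labels) / sum(length_bp) * 1e5`).
#' @examples
#' expected_density(contigs(1, 100000, list(seq(5e3, 95e3, by = 1e4))))
#' @export
expected_density <- function(ct) {
  if (!nrow(ct) || sum(ct$length_bp) <= 0) abort("reference has zero length")
  sum(ct$n_labels) / sum(ct$length_bp) * 1e5
}

#' Synthetic reference map with Poisson-distributed sites
#'
#' Generates a reference restriction map directly in label space: site
#' positions follow a homogeneous Poisson process at the requested density.
#' Useful for assembly experiments where only the label pattern matters.
#'
#' @param length_bp Reference length in bp.
#' @param density_per_100kbp Expected sites per 100 kbp (the dual-nickase
#'   design target for cotton was ~11).
#' @param min_gap_bp Minimum distance between successive sites (nanochannel
#'   imaging cannot resolve closer labels); closer sites are dropped.
#' @param contig_id Id of the generated contig.
#' @return A one-row `om_contigs` table.
#' @export
random_reference <- function(length_bp, density_per_100kbp = 11,
                             min_gap_bp = 1000, contig_id = 1L) {
  stopifnot(length_bp > 0, density_per_100kbp >= 0)
  n <- rpois(1, length_bp * density_per_100kbp / 1e5)
  pos <- sort(runif(n, 0, length_bp))
  if (length(pos) > 1) {
    keep <- c(TRUE, diff(pos) >= min_gap_bp)
    while (any(!keep)) {
      pos <- pos[keep]
      keep <- c(TRUE, diff(pos) >= min_gap_bp)
    }
  }
  pos <- pos[pos > 0]
  contigs(contig_id = contig_id, length_bp = length_bp, labels_bp = list(pos))
}

#' Random nucleotide sequence
#'
#' Uniform i.i.d. bases; handy for exercising [digest_sequence()].
#'
#' @param n Sequence length.
#' @return A single character string.
#' @export
random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
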