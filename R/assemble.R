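#' Filter molecules by length and label count
#'
#' The two data-inclusion parameters of the assembler: longer, more
#' label-dense molecules are more reliable, so molecules below either
#' threshold are excluded before assembly. Both thresholds are inclusive
#' (`>=`). Order is preserved.
#'
#' @param ms An `om_molecules` table.
#' @param min_length_kbp Minimum molecule length in kbp.
#' @param min_labels Minimum number of labels per molecule.
#' @return The filtered `om_molecules` table.
#' @export
filter_molecules <- function(ms, min_length_kbp = 0, min_labels = 0L) {
  keep <- ms$length_bp >= min_length_kbp * 1000 & ms$n_labels >= min_labels
  new_om_molecules(ms[keep, , drop = FALSE], metadata = om_metadata(ms))
}

#' Sort molecules by descending length
#'
#' The first assembly step: a stable sort by descending length, ties broken
#' by ascending id. Content is unchanged.
#'
#' @param ms An `om_molecules` table.
#' @return The sorted `om_molecules` table.
#' @export
sort_molecules <- function(ms) {
  ord <- order(-ms$length_bp, ms$molecule_id)
  new_om_molecules(ms[ord, , drop = FALSE], metadata = om_metadata(ms))
}

#' Split molecules into balanced chunks
#'
#' The second assembly step: round-robin assignment over the (sorted) input
#' order, which keeps chunk total lengths within one molecule of each other
#' and makes the chunking invertible.
#'
#' @param ms An `om_molecules` table (typically from [sort_molecules()]).
#' @param n_chunks Number of chunks (>= 1).
#' @return A list of `n_chunks` `om_molecules` tables; chunk `k` holds input
#'   rows `k, k + n_chunks, k + 2 n_chunks, ...`.
#' @export
split_molecules <- function(ms, n_chunks = 1L) {
  stopifnot(n_chunks >= 1)
  idx <- seq_len(nrow(ms))
  lapply(seq_len(n_chunks), function(k) {
    new_om_molecules(ms[idx[(idx - 1L) %% n_chunks == (k - 1L)], , drop = FALSE],
                     metadata = om_metadata(ms))
  })
}

#' Align every unique pair of molecules
#'
#' The third assembly step: each unordered pair of molecules (within and
#' between chunks) is aligned once; alignments whose permutation p-value
#' passes `p$pvalue_threshold` are retained. Each pair's permutation stream
#' is seeded from `(seed, id_a, id_b)`, so the retained set is identical
#' for any chunking and any evaluation order. Pairs whose best score falls
#' below `p$null_score_min` are assigned p = 1 without spending permutation
#' replicates.
#'
#' @param chunks A list of `om_molecules` chunks from [split_molecules()]
#'   (a single `om_molecules` table is treated as one chunk).
#' @param p An [align_params()] object.
#' @param seed Integer root seed for the per-pair permutation streams.
#' @return A tibble of retained alignments (columns as [align_pair()]),
#'   ordered by `(id_a, id_b)` with `id_a < id_b`.
#' @export
all_pairs_overlaps <- function(chunks, p = align_params(), seed = 1L) {
  if (is.data.frame(chunks)) chunks <- list(chunks)
  ms <- dplyr::bind_rows(chunks)
  ms <- ms[order(ms$molecule_id), , drop = FALSE]
  n <- nrow(ms)
  out <- vector("list", 256L); nout <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      ai <- ms$labels_bp[[i]]
      if (length(ai) < 2) next
      for (j in (i + 1L):n) {
        bj <- ms$labels_bp[[j]]
        if (length(bj) < 2) next
        r <- rmap_align_core(ai, bj, ms$length_bp[j],
                             p$fp_per_100kbp, p$fn_rate, p$sizing_sd_bp_per_kbp,
                             p$site_density_per_100kbp, p$max_skip, 0L)
        if (!isTRUE(r$found) || r$score < p$null_score_min) next
        set.seed(pair_seed(seed, ms$molecule_id[i], ms$molecule_id[j]))
        rn <- rmap_align_core(ai, bj, ms$length_bp[j],
                              p$fp_per_100kbp, p$fn_rate, p$sizing_sd_bp_per_kbp,
                              p$site_density_per_100kbp, p$max_skip,
                              p$null_reps)
        pv <- pvalue_from_null(rn$score, rn$null_scores, p$pvalue_method)
        if (pv > p$pvalue_threshold) next
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- tibble(
          id_a = ms$molecule_id[i], id_b = ms$molecule_id[j],
          orientation = if (rn$orientation > 0) "+" else "-",
          offset_bp = rn$offset_bp, score = rn$score,
          n_matched = length(rn$idx_a),
          unmatched_a = rn$unmatched_a, unmatched_b = rn$unmatched_b,
          pvalue = pv,
          matched_pairs = list(cbind(idx_a = rn$idx_a, idx_b = rn$idx_b)))
      }
    }
  }
  if (nout == 0L) {
    return(tibble(id_a = integer(), id_b = integer(), orientation = character(),
                  offset_bp = numeric(), score = numeric(), n_matched = integer(),
                  unmatched_a = integer(), unmatched_b = integer(),
                  pvalue = numeric(), matched_pairs = list()))
  }
  dplyr::bind_rows(out[seq_len(nout)])
}

#' Overlap-layout-consensus assembly
#'
#' The fourth assembly step. Layout is greedy best-edge-first: retained
#' overlaps are processed in increasing p-value and merged with union-find,
#' maintaining a consistent coordinate frame per component; an edge whose
#' implied placement contradicts an existing one by more than
#' `placement_tolerance_bp` (or by orientation) is rejected. Consensus:
#' member labels are transformed to contig coordinates and clustered by
#' single linkage within `merge_radius_bp`; each cluster becomes one
#' consensus label at the cluster mean, with `occurrence` = number of
#' molecules contributing a label and `coverage` = number of molecules
#' spanning the position. Each contig's frame is anchored to its longest
#' member molecule (kept forward) and contig ids are assigned in descending
#' contig length. Molecules with no accepted edge become singletons.
#'
#' @param ms The filtered `om_molecules` the overlaps were computed on.
#' @param overlaps Alignment tibble from [all_pairs_overlaps()].
#' @param placement_tolerance_bp Maximum disagreement between an edge and an
#'   existing placement before the edge is rejected.
#' @param merge_radius_bp Single-linkage radius for consensus label
#'   clustering.
#' @param params Optional parameter provenance stored on the result.
#' @return An `om_assembly` object: list with `contigs` (an `om_contigs`
#'   table), `placements` (tibble: molecule_id, contig_id, offset_bp,
#'   orientation), `singletons` (integer ids), `params`, `n_input`.
#' @export
assemble_olc <- function(ms, overlaps, placement_tolerance_bp = 2000,
                         merge_radius_bp = 1500, params = NULL) {
  n <- nrow(ms)
  idx_of <- setNames(seq_len(n), ms$molecule_id)
  if (nrow(overlaps)) {
    unknown <- setdiff(c(overlaps$id_a, overlaps$id_b), ms$molecule_id)
    if (length(unknown)) {
      abort(paste0("overlap references unknown molecule id ", unknown[1]))
    }
  }
  parent <- seq_len(n); tr_s <- rep(1, n); tr_t <- rep(0, n); csize <- rep(1L, n)
  has_edge <- rep(FALSE, n)

  find <- function(i) {
    # returns c(root, s, t) with pos_root = s * pos_i + t
    s <- 1; t <- 0; j <- i
    while (parent[j] != j) {
      t <- tr_s[j] * t + tr_t[j]
      s <- tr_s[j] * s
      j <- parent[j]
    }
    c(j, s, t)
  }

  if (nrow(overlaps)) {
    ord <- order(overlaps$pvalue, -overlaps$score,
                 pmin(overlaps$id_a, overlaps$id_b),
                 pmax(overlaps$id_a, overlaps$id_b))
    for (e in ord) {
      ia <- idx_of[[as.character(overlaps$id_a[e])]]
      ib <- idx_of[[as.character(overlaps$id_b[e])]]
      # transform of b into a's frame
      if (overlaps$orientation[e] == "+") {
        es <- 1; et <- overlaps$offset_bp[e]
      } else {
        es <- -1; et <- overlaps$offset_bp[e] + ms$length_bp[ib]
      }
      fa <- find(ia); fb <- find(ib)
      # b -> root(a): compose a->roota with b->a
      bs <- fa[2] * es; bt <- fa[2] * et + fa[3]
      if (fa[1] == fb[1]) {
        ok <- fb[2] == bs && abs(fb[3] - bt) <= placement_tolerance_bp
        if (ok) { has_edge[ia] <- TRUE; has_edge[ib] <- TRUE }
        next
      }
      # attach root(b) under root(a): rootb -> roota = (b->roota) o (b->rootb)^-1
      rs <- bs * fb[2]; rt <- bt - rs * fb[3]
      parent[fb[1]] <- fa[1]; tr_s[fb[1]] <- rs; tr_t[fb[1]] <- rt
      csize[fa[1]] <- csize[fa[1]] + csize[fb[1]]
      has_edge[ia] <- TRUE; has_edge[ib] <- TRUE
    }
  }

  root <- integer(n); ps <- numeric(n); pt <- numeric(n)
  for (i in seq_len(n)) {
    f <- find(i); root[i] <- f[1]; ps[i] <- f[2]; pt[i] <- f[3]
  }
  comp <- split(seq_len(n), root)
  comp <- comp[vapply(comp, length, integer(1)) >= 2]

  built <- list()
  for (members in comp) {
    s <- ps[members]; t <- pt[members]
    starts <- ifelse(s > 0, t, t - ms$length_bp[members])
    ends <- starts + ms$length_bp[members]
    # anchor: longest member forward
    anchor <- members[which.max(ms$length_bp[members])]
    if (ps[anchor] < 0) {
      s <- -s; t <- -t
      starts2 <- ifelse(s > 0, t, t - ms$length_bp[members])
      ends <- starts2 + ms$length_bp[members]
      starts <- starts2
    }
    shift <- min(starts)
    starts <- starts - shift; ends <- ends - shift; t <- t - shift
    lab_pos <- numeric(0); lab_mol <- integer(0)
    for (k in seq_along(members)) {
      i <- members[k]
      lab <- s[k] * ms$labels_bp[[i]] + t[k]
      lab_pos <- c(lab_pos, lab)
      lab_mol <- c(lab_mol, rep(i, length(lab)))
    }
    clen <- max(ends)
    cons <- consensus_labels(lab_pos, lab_mol, starts, ends, members,
                             merge_radius_bp, clen)
    built[[length(built) + 1L]] <- list(
      members = members, starts = starts, s = s, length = clen,
      labels = cons$pos, occurrence = cons$occ, coverage = cons$cov)
  }

  # contig ids in descending contig length
  if (length(built)) {
    built <- built[order(-vapply(built, function(x) x$length, numeric(1)))]
  }
  placements <- tibble(molecule_id = integer(), contig_id = integer(),
                       offset_bp = numeric(), orientation = character())
  ct <- contigs()
  if (length(built)) {
    ct <- contigs(
      contig_id = seq_along(built),
      length_bp = vapply(built, function(x) x$length, numeric(1)),
      labels_bp = lapply(built, function(x) x$labels),
      occurrence = lapply(built, function(x) x$occ),
      coverage = lapply(built, function(x) x$cov))
    placements <- dplyr::bind_rows(lapply(seq_along(built), function(ci) {
      b <- built[[ci]]
      tibble(molecule_id = ms$molecule_id[b$members], contig_id = ci,
             offset_bp = b$starts,
             orientation = ifelse(b$s > 0, "+", "-"))
    }))
    placements <- placements[order(placements$molecule_id), , drop = FALSE]
  }
  placed <- unique(placements$molecule_id)
  singletons <- sort(setdiff(ms$molecule_id, placed))
  validate_contigs(ct)
  structure(list(contigs = ct, placements = placements,
                 singletons = singletons, params = params, n_input = n),
            class = "om_assembly")
}

# Single-linkage 1-D clustering of member labels into consensus labels.
consensus_labels <- function(lab_pos, lab_mol, starts, ends, members,
                             merge_radius_bp, contig_len) {
  if (!length(lab_pos)) {
    return(list(pos = numeric(0), occ = integer(0), cov = integer(0)))
  }
  ord <- order(lab_pos)
  lab_pos <- lab_pos[ord]; lab_mol <- lab_mol[ord]
  brk <- c(0L, which(diff(lab_pos) > merge_radius_bp), length(lab_pos))
  pos <- numeric(0); occ <- integer(0); cov <- integer(0)
  for (k in seq_len(length(brk) - 1L)) {
    sel <- (brk[k] + 1L):brk[k + 1L]
    p <- mean(lab_pos[sel])
    contributors <- unique(lab_mol[sel])
    spanning <- members[starts <= p & ends >= p]
    pos <- c(pos, p)
    occ <- c(occ, length(contributors))
    cov <- c(cov, length(union(contributors, spanning)))
  }
  # keep consensus labels inside (0, contig_len]
  pos[1] <- max(pos[1], min(0.05, contig_len))
  pos <- pmin(pos, contig_len)
  keep <- c(TRUE, diff(pos) > 0)
  list(pos = pos[keep], occ = occ[keep], cov = cov[keep])
}

#' @export
print.om_assembly <- function(x, ...) {
  cat(sprintf("# Assembly: %d contigs, %d placed molecules, %d singletons (of %d)\n",
              nrow(x$contigs), nrow(x$placements), length(x$singletons), x$n_input))
  invisible(x)
}

#' Run one complete assembly for a parameter combination
#'
#' Convenience wrapper chaining the four assembly steps — filter + sort,
#' split, all-pairs alignment, overlap-layout-consensus — for a single
#' [param_set()]. This is the "naive" execution path; [run_sweep()] produces
#' identical results per combination while sharing compatible intermediates
#' across a grid.
#'
#' @param ms An `om_molecules` table.
#' @param pset A [param_set()].
#' @param opts [sweep_options()] controlling the shared aligner/layout
#'   settings.
#' @param seed Root seed for the per-pair permutation streams.
#' @return An `om_assembly`.
#' @export
assemble_one <- function(ms, pset, opts = sweep_options(), seed = 1L) {
  filtered <- filter_molecules(ms, pset$min_length_kbp, pset$min_labels)
  sorted <- sort_molecules(filtered)
  chunks <- split_molecules(sorted, opts$n_chunks)
  ap <- align_params_for(pset, opts)
  ov <- all_pairs_overlaps(chunks, ap, seed = seed)
  assemble_olc(filtered, ov, opts$placement_tolerance_bp,
               opts$merge_radius_bp, params = pset)
}

align_params_for <- function(pset, opts) {
  align_params(pvalue_threshold = pset$pvalue_threshold,
               fp_per_100kbp = pset$fp_per_100kbp,
               fn_rate = pset$fn_rate,
               sizing_sd_bp_per_kbp = opts$sizing_sd_bp_per_kbp,
               site_density_per_100kbp = opts$site_density_per_100kbp,
               max_skip = opts$max_skip,
               null_reps = opts$null_reps,
               pvalue_method = opts$pvalue_method,
               null_score_min = opts$null_score_min)
}
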