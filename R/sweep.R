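#' A full assembly parameter combination
#'
#' The five swept parameters: the overlap significance threshold, the two
#' label error rates the aligner assumes, and the two data-inclusion
#' filters.
#'
#' @param pvalue_threshold Overlap significance threshold in `(0, 1)`.
#' @param fp_per_100kbp Assumed false-positive labels per 100 kbp.
#' @param fn_rate Assumed proportion of restriction sites unlabeled.
#' @param min_length_kbp Minimum molecule length, kbp.
#' @param min_labels Minimum labels per molecule.
#' @return A list of class `om_param_set`.
#' @export
param_set <- function(pvalue_threshold, fp_per_100kbp, fn_rate,
                      min_length_kbp, min_labels) {
  stopifnot(pvalue_threshold > 0, pvalue_threshold < 1)
  structure(list(pvalue_threshold = pvalue_threshold,
                 fp_per_100kbp = fp_per_100kbp, fn_rate = fn_rate,
                 min_length_kbp = min_length_kbp,
                 min_labels = as.integer(min_labels)),
            class = "om_param_set")
}

#' A parameter grid for a trial-and-error sweep
#'
#' One value list per swept parameter; the sweep assembles every combination
#' (the Cartesian product).
#'
#' @inheritParams param_set
#' @return A list of class `om_param_grid`.
#' @export
param_grid <- function(pvalue_threshold, fp_per_100kbp, fn_rate,
                       min_length_kbp, min_labels) {
  g <- list(pvalue_threshold = as.numeric(pvalue_threshold),
            fp_per_100kbp = as.numeric(fp_per_100kbp),
            fn_rate = as.numeric(fn_rate),
            min_length_kbp = as.numeric(min_length_kbp),
            min_labels = as.integer(min_labels))
  if (any(lengths(g) == 0)) abort("every grid dimension needs at least one value")
  if (any(g$pvalue_threshold <= 0 | g$pvalue_threshold >= 1)) {
    abort("significance thresholds must lie in (0, 1)")
  }
  structure(g, class = "om_param_grid")
}

#' The full-scale five-parameter grid for a ~900 Mbp plant genome
#'
#' Five overlap significance thresholds spanning eight orders of magnitude,
#' three false-positive densities, three false-negative proportions, three
#' minimum lengths and three minimum label counts: 405 combinations, the
#' grid used to sweep the *Gossypium raimondii* nanochannel dataset.
#'
#' @return An [param_grid()] with 405 combinations.
#' @export
default_sweep_grid <- function() {
  param_grid(
    pvalue_threshold = 1.11 * 10^-c(4, 6, 8, 10, 12),
    fp_per_100kbp = c(0.5, 1.5, 2.5),
    fn_rate = c(0.15, 0.30, 0.45),
    min_length_kbp = c(100, 150, 180),
    min_labels = c(6L, 8L, 10L))
}

#' Shared execution options for assembly and sweeps
#'
#' Settings that are held fixed across a sweep (they are not part of the
#' swept parameter space): the sizing-noise model, DP limits, permutation
#' budget, chunking, and layout tolerances.
#'
#' The assembly default `null_score_min = 8` requires roughly four cleanly
#' matched intervals of overlap evidence before an alignment is considered
#' a candidate edge; pairs below it are never significant in practice, and
#' their concentrated permutation nulls are exactly the ones for which tail
#' extrapolation is least reliable, so excluding them up front buys both
#' specificity and speed.
#'
#' @inheritParams align_params
#' @param n_chunks Number of chunks for the split step.
#' @param placement_tolerance_bp,merge_radius_bp See [assemble_olc()].
#' @return A list of class `om_sweep_options`.
#' @export
sweep_options <- function(sizing_sd_bp_per_kbp = 30,
                          site_density_per_100kbp = 10, max_skip = 3,
                          null_reps = 100, pvalue_method = "auto",
                          null_score_min = 8, n_chunks = 4,
                          placement_tolerance_bp = 2000,
                          merge_radius_bp = 1500) {
  structure(list(sizing_sd_bp_per_kbp = sizing_sd_bp_per_kbp,
                 site_density_per_100kbp = site_density_per_100kbp,
                 max_skip = as.integer(max_skip),
                 null_reps = as.integer(null_reps),
                 pvalue_method = pvalue_method,
                 null_score_min = null_score_min,
                 n_chunks = as.integer(n_chunks),
                 placement_tolerance_bp = placement_tolerance_bp,
                 merge_radius_bp = merge_radius_bp),
            class = "om_sweep_options")
}

#' All parameter combinations of a grid
#'
#' @param grid An [param_grid()].
#' @return A tibble with one row per combination, columns in canonical
#'   parameter order.
#' @export
grid_combinations <- function(grid) {
  as_tibble(expand.grid(pvalue_threshold = grid$pvalue_threshold,
                        fp_per_100kbp = grid$fp_per_100kbp,
                        fn_rate = grid$fn_rate,
                        min_length_kbp = grid$min_length_kbp,
                        min_labels = grid$min_labels,
                        KEEP.OUT.ATTRS = FALSE))
}

# The most lenient value of each filter-only parameter in the active grid:
# one run at these values dominates (contains the output of) every
# dependent stringent run.
lenient_dominators <- function(grid) {
  list(pvalue_threshold = max(grid$pvalue_threshold),
       min_length_kbp = min(grid$min_length_kbp),
       min_labels = min(grid$min_labels))
}

#' Project a parameter combination onto a pipeline step's key
#'
#' Each assembly step is affected by only a subset of the five parameters;
#' the rest act purely as output filters, so a single run at the most
#' lenient filter values can serve every dependent combination. The step
#' key is the combination projected accordingly: `sort` and `split` depend
#' on no swept parameter; `pairwise` depends on the two error rates;
#' `assembly` depends on all five. Filter-only fields in the key are
#' replaced by the grid's lenient dominators (largest threshold, smallest
#' minimum length and label count).
#'
#' @param step_type One of `"sort"`, `"split"`, `"pairwise"`, `"assembly"`.
#' @param pset A [param_set()] (or one row of [grid_combinations()]).
#' @param grid The active [param_grid()].
#' @return A list of class `om_step_key` with fields `step_type`,
#'   `effective` (the parameter subset that alters the computation) and
#'   `run_params` (the full parameter values the shared run uses).
#' @export
project_step_key <- function(step_type, pset, grid) {
  dom <- lenient_dominators(grid)
  eff <- switch(step_type,
    sort = list(),
    split = list(),
    pairwise = list(fp_per_100kbp = pset$fp_per_100kbp, fn_rate = pset$fn_rate),
    assembly = list(pvalue_threshold = pset$pvalue_threshold,
                    fp_per_100kbp = pset$fp_per_100kbp, fn_rate = pset$fn_rate,
                    min_length_kbp = pset$min_length_kbp,
                    min_labels = pset$min_labels),
    abort(paste0("unknown step type: ", step_type)))
  run <- switch(step_type,
    sort = ,
    split = list(min_length_kbp = dom$min_length_kbp,
                 min_labels = dom$min_labels),
    pairwise = list(fp_per_100kbp = pset$fp_per_100kbp, fn_rate = pset$fn_rate,
                    pvalue_threshold = dom$pvalue_threshold,
                    min_length_kbp = dom$min_length_kbp,
                    min_labels = dom$min_labels),
    assembly = eff)
  structure(list(step_type = step_type, effective = eff, run_params = run),
            class = "om_step_key")
}

step_key_id <- function(key) {
  rlang::hash(list(key$step_type, key$run_params))
}

#' Plan a parameter sweep as a step DAG
#'
#' Projects every grid combination onto each of the four assembly steps and
#' deduplicates the resulting step keys: the plan runs each distinct key
#' once. For a grid with value counts `(n_thr, n_fp, n_fn, n_len, n_lab)`
#' the plan has 1 sort node, 1 split node, `n_fp * n_fn` pairwise nodes and
#' `prod(counts)` assembly nodes, connected sort -> split -> pairwise ->
#' assembly by matching projections.
#'
#' @param grid An [param_grid()].
#' @return An `om_sweep_plan`: list with `grid`, `psets` (combination
#'   tibble), `nodes` (tibble: node_id, step_type, key list-column,
#'   dependents list-column of combination row indices, precursor node_id)
#'   and `counts` (named integer vector per step type).
#' @export
plan_sweep <- function(grid) {
  psets <- grid_combinations(grid)
  nodes <- list(); dep <- list(); types <- character(0); pre <- character(0)
  add_nodes <- function(step_type, precursor_of) {
    keys <- lapply(seq_len(nrow(psets)), function(i) {
      project_step_key(step_type, as.list(psets[i, ]), grid)
    })
    ids <- vapply(keys, step_key_id, character(1))
    for (u in unique(ids)) {
      sel <- which(ids == u)
      nodes[[length(nodes) + 1L]] <<- keys[[sel[1]]]
      dep[[length(dep) + 1L]] <<- sel
      types <<- c(types, step_type)
      pre <<- c(pre, precursor_of(keys[[sel[1]]], sel[1]))
    }
    ids
  }
  sort_ids <- add_nodes("sort", function(k, i) NA_character_)
  split_ids <- add_nodes("split", function(k, i) sort_ids[i])
  pair_ids <- add_nodes("pairwise", function(k, i) split_ids[i])
  add_nodes("assembly", function(k, i) pair_ids[i])
  node_tb <- tibble(
    node_id = vapply(nodes, step_key_id, character(1)),
    step_type = types,
    key = nodes,
    dependents = dep,
    precursor = pre)
  counts <- table(factor(types, levels = c("sort", "split", "pairwise", "assembly")))
  structure(list(grid = grid, psets = psets, nodes = node_tb,
                 counts = setNames(as.integer(counts), names(counts))),
            class = "om_sweep_plan")
}

#' @export
print.om_sweep_plan <- function(x, ...) {
  cat(sprintf("# Sweep plan: %d combinations -> %s\n", nrow(x$psets),
              paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = ", ")))
  invisible(x)
}

cache_path <- function(cache_dir, h) file.path(cache_dir, paste0(h, ".rds"))

cache_get <- function(cache_dir, h, key_repr) {
  f <- cache_path(cache_dir, h)
  if (!file.exists(f)) return(NULL)
  obj <- tryCatch(readRDS(f), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$key, key_repr)) {
    warn(paste0("cache entry ", h, " is corrupt or stale; recomputing"))
    return(NULL)
  }
  obj$value
}

cache_put <- function(cache_dir, h, key_repr, value) {
  saveRDS(list(key = key_repr, value = value), cache_path(cache_dir, h))
}

#' Execute a sweep plan with intermediate-result reuse
#'
#' Runs each node of the plan at most once, in topological order, caching
#' results on disk keyed by a content hash of the step key, the input data,
#' the shared options and the package version. Pairwise nodes run with the
#' grid's lenient dominator filters and persist all retained alignments;
#' each assembly node then re-filters molecules and alignments down to its
#' own stringent values before layout. Re-invoking with a warm cache
#' executes zero steps, and per-combination results are field-identical to
#' independent [assemble_one()] runs.
#'
#' @param ms An `om_molecules` table.
#' @param plan An `om_sweep_plan` from [plan_sweep()].
#' @param cache_dir Directory for cached intermediates (created if needed).
#' @param opts [sweep_options()].
#' @param seed Root seed for per-pair permutation streams.
#' @param reference Optional `om_contigs` reference map; when given, each
#'   assembly's quality report includes reference accuracy.
#' @return An `om_sweep_result`: list with `results` (tibble, one row per
#'   combination: the five parameters, an `assembly` list-column, and the
#'   [quality_report()] columns), `executed` (tibble of node_id, step_type,
#'   executed flag), `plan`, `cache_dir`.
#' @export
run_sweep <- function(ms, plan, cache_dir = tempfile("omsweep-cache-"),
                      opts = sweep_options(), seed = 1L, reference = NULL) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  input_hash <- rlang::hash(list(
    ms$molecule_id, ms$length_bp, ms$labels_bp, seed,
    unclass(opts), as.character(utils::packageVersion("omsweep"))))
  node_hash <- function(key) rlang::hash(list(step_key_id(key), input_hash))
  executed <- logical(nrow(plan$nodes))
  store <- new.env(parent = emptyenv())

  run_node <- function(i) {
    key <- plan$nodes$key[[i]]
    h <- node_hash(key)
    if (!is.null(store[[h]])) return(store[[h]])
    key_repr <- list(step_key_id(key), input_hash)
    val <- cache_get(cache_dir, h, key_repr)
    if (is.null(val)) {
      executed[i] <<- TRUE
      pre_i <- match(plan$nodes$precursor[i], plan$nodes$node_id)
      val <- switch(key$step_type,
        sort = {
          rp <- key$run_params
          sort_molecules(filter_molecules(ms, rp$min_length_kbp, rp$min_labels))
        },
        split = split_molecules(run_node(pre_i), opts$n_chunks),
        pairwise = {
          rp <- key$run_params
          ap <- align_params(pvalue_threshold = rp$pvalue_threshold,
                             fp_per_100kbp = rp$fp_per_100kbp,
                             fn_rate = rp$fn_rate,
                             sizing_sd_bp_per_kbp = opts$sizing_sd_bp_per_kbp,
                             site_density_per_100kbp = opts$site_density_per_100kbp,
                             max_skip = opts$max_skip, null_reps = opts$null_reps,
                             pvalue_method = opts$pvalue_method,
                             null_score_min = opts$null_score_min)
          all_pairs_overlaps(run_node(pre_i), ap, seed = seed)
        },
        assembly = {
          rp <- key$run_params
          filtered <- filter_molecules(ms, rp$min_length_kbp, rp$min_labels)
          ov <- run_node(pre_i)
          keep_ids <- filtered$molecule_id
          ov <- ov[ov$id_a %in% keep_ids & ov$id_b %in% keep_ids &
                     ov$pvalue <= rp$pvalue_threshold, , drop = FALSE]
          assemble_olc(filtered, ov, opts$placement_tolerance_bp,
                       opts$merge_radius_bp,
                       params = do.call(param_set, rp))
        })
      cache_put(cache_dir, h, key_repr, val)
    }
    store[[h]] <- val
    val
  }

  asm_nodes <- which(plan$nodes$step_type == "assembly")
  results <- vector("list", nrow(plan$psets))
  for (i in asm_nodes) {
    asm <- run_node(i)
    for (ps_row in plan$nodes$dependents[[i]]) {
      pset <- as.list(plan$psets[ps_row, ])
      filtered <- filter_molecules(ms, pset$min_length_kbp, pset$min_labels)
      qr <- quality_report(asm, filtered, reference = reference, opts = opts)
      results[[ps_row]] <- dplyr::bind_cols(
        as_tibble(pset), tibble(assembly = list(asm)), qr)
    }
  }
  # execute any non-assembly nodes not pulled in above (none in practice,
  # but keeps the contract: every planned node runs)
  for (i in seq_len(nrow(plan$nodes))) run_node(i)

  structure(list(results = dplyr::bind_rows(results),
                 executed = tibble(node_id = plan$nodes$node_id,
                                   step_type = plan$nodes$step_type,
                                   executed = executed),
                 plan = plan, cache_dir = cache_dir),
            class = "om_sweep_result")
}

#' @export
print.om_sweep_result <- function(x, ...) {
  cat(sprintf("# Sweep result: %d assemblies (%d of %d steps executed, cache %s)\n",
              nrow(x$results), sum(x$executed$executed), nrow(x$executed),
              x$cache_dir))
  invisible(x)
}

#' Reuse savings of a sweep
#'
#' Compares the steps actually planned/executed with the naive cost of
#' running every step once per parameter combination.
#'
#' @param swept An `om_sweep_result` (or an `om_sweep_plan`, in which case
#'   `executed` counts equal planned nodes).
#' @return A tibble with one row per step type plus a total row: planned
#'   distinct nodes, executed nodes, naive per-combination runs, and the
#'   savings ratio `naive / planned`.
#' @export
resource_report <- function(swept) {
  plan <- if (inherits(swept, "om_sweep_plan")) swept else swept$plan
  exec <- if (inherits(swept, "om_sweep_plan")) {
    tibble(step_type = plan$nodes$step_type, executed = TRUE)
  } else {
    swept$executed
  }
  n_psets <- nrow(plan$psets)
  steps <- c("sort", "split", "pairwise", "assembly")
  tb <- tibble(
    step_type = steps,
    planned = as.integer(plan$counts[steps]),
    executed = unname(vapply(steps, function(s) {
      sum(exec$executed[exec$step_type == s])
    }, integer(1))),
    naive = n_psets)
  total <- tibble(step_type = "total", planned = sum(tb$planned),
                  executed = sum(tb$executed), naive = 4L * n_psets)
  out <- dplyr::bind_rows(tb, total)
  out$savings_ratio <- out$naive / out$planned
  out
}
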