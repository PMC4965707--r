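test_that("step-key projection keeps only computation-affecting parameters", {
  grid <- default_sweep_grid()
  p1 <- param_set(1.11e-4, 0.5, 0.15, 100, 6L)
  p2 <- param_set(1.11e-12, 0.5, 0.15, 180, 10L)  # differs only in filters
  for (st in c("sort", "split", "pairwise")) {
    k1 <- project_step_key(st, p1, grid)
    k2 <- project_step_key(st, p2, grid)
    expect_identical(omsweep:::step_key_id(k1), omsweep:::step_key_id(k2))
  }
  ka1 <- project_step_key("assembly", p1, grid)
  ka2 <- project_step_key("assembly", p2, grid)
  expect_false(identical(omsweep:::step_key_id(ka1), omsweep:::step_key_id(ka2)))
  # pairwise keys distinguish error rates
  p3 <- param_set(1.11e-4, 1.5, 0.15, 100, 6L)
  expect_false(identical(
    omsweep:::step_key_id(project_step_key("pairwise", p1, grid)),
    omsweep:::step_key_id(project_step_key("pairwise", p3, grid))))
  expect_error(project_step_key("polish", p1, grid), "unknown step type")
})

test_that("the full five-parameter grid plans 405 assemblies from 11 precursor steps", {
  plan <- plan_sweep(default_sweep_grid())
  expect_equal(nrow(plan$psets), 405)
  expect_equal(unname(plan$counts["assembly"]), 405L)
  expect_equal(unname(plan$counts["pairwise"]), 9L)
  expect_equal(unname(plan$counts["sort"]), 1L)
  expect_equal(unname(plan$counts["split"]), 1L)
})

test_that("plan node counts equal brute-force deduplication of projections", {
  set.seed(61)
  for (case in 1:5) {
    grid <- param_grid(
      pvalue_threshold = sort(runif(sample(1:3, 1), 1e-8, 1e-2)),
      fp_per_100kbp = sample(c(0.5, 1.5, 2.5), sample(1:3, 1)),
      fn_rate = sample(c(0.1, 0.2, 0.3), sample(1:2, 1)),
      min_length_kbp = sample(c(100, 150), sample(1:2, 1)),
      min_labels = sample(6:10, sample(1:2, 1)))
    plan <- plan_sweep(grid)
    combos <- grid_combinations(grid)
    for (st in c("sort", "split", "pairwise", "assembly")) {
      ids <- vapply(seq_len(nrow(combos)), function(i) {
        omsweep:::step_key_id(project_step_key(st, as.list(combos[i, ]), grid))
      }, character(1))
      expect_equal(unname(plan$counts[st]), length(unique(ids)))
    }
    expect_equal(unname(plan$counts["assembly"]), nrow(combos))
  }
  # singleton grid: one node per step
  p1 <- plan_sweep(param_grid(1e-5, 1.5, 0.3, 150, 8L))
  expect_equal(unname(p1$counts), c(1L, 1L, 1L, 1L))
  expect_error(param_grid(numeric(0), 1, 0.1, 100, 6L), "at least one value")
})

test_that("memoized sweep equals naive per-combination execution", {
  sim <- toy_simulation(ref_len = 3e5, coverage = 10, seed = 63)
  ms <- sim$molecules
  grid <- param_grid(c(1e-3, 1e-5), c(0.5, 1.5), 0.1, 40, 3L)
  opts <- sweep_options(n_chunks = 3, null_reps = 50)
  cache <- withr::local_tempdir()
  sw <- run_sweep(ms, plan_sweep(grid), cache_dir = cache, opts = opts, seed = 9)
  expect_equal(nrow(sw$results), 4)
  for (i in seq_len(nrow(sw$results))) {
    pset <- do.call(param_set, as.list(sw$results[i, 1:5]))
    naive <- assemble_one(ms, pset, opts = opts, seed = 9)
    memo <- sw$results$assembly[[i]]
    expect_equal(memo$contigs, naive$contigs)
    expect_equal(memo$placements, naive$placements)
    expect_identical(memo$singletons, naive$singletons)
  }
})

test_that("a warm cache re-run executes zero steps and reproduces results", {
  sim <- toy_simulation(ref_len = 2e5, coverage = 8, seed = 64)
  ms <- sim$molecules
  grid <- param_grid(1e-3, c(0.5, 1.5), 0.1, 40, 3L)
  opts <- sweep_options(n_chunks = 2, null_reps = 30)
  cache <- withr::local_tempdir()
  sw1 <- run_sweep(ms, plan_sweep(grid), cache_dir = cache, opts = opts, seed = 2)
  expect_true(all(sw1$executed$executed))
  sw2 <- run_sweep(ms, plan_sweep(grid), cache_dir = cache, opts = opts, seed = 2)
  expect_false(any(sw2$executed$executed))
  expect_equal(tidy(sw1), tidy(sw2))
})

test_that("growing a cached grid reruns only the new pairwise nodes", {
  sim <- toy_simulation(ref_len = 2e5, coverage = 8, seed = 65)
  ms <- sim$molecules
  opts <- sweep_options(n_chunks = 2, null_reps = 30)
  cache <- withr::local_tempdir()
  g1 <- param_grid(1e-3, c(0.5, 1.5), 0.1, 40, 3L)
  run_sweep(ms, plan_sweep(g1), cache_dir = cache, opts = opts, seed = 2)
  g2 <- param_grid(1e-3, c(0.5, 1.5), c(0.1, 0.3), 40, 3L)
  sw <- run_sweep(ms, plan_sweep(g2), cache_dir = cache, opts = opts, seed = 2)
  ex <- sw$executed
  # exactly |FP| = 2 new pairwise nodes (for fn = 0.3); sort/split reused
  expect_equal(sum(ex$executed[ex$step_type == "pairwise"]), 2)
  expect_equal(sum(ex$executed[ex$step_type %in% c("sort", "split")]), 0)
})

test_that("corrupt cache entries are recomputed with a warning", {
  sim <- toy_simulation(ref_len = 2e5, coverage = 6, seed = 66)
  ms <- sim$molecules
  grid <- param_grid(1e-3, 1.5, 0.1, 40, 3L)
  opts <- sweep_options(n_chunks = 1, null_reps = 20)
  cache <- withr::local_tempdir()
  sw1 <- run_sweep(ms, plan_sweep(grid), cache_dir = cache, opts = opts, seed = 4)
  # clobber every cache entry's stored key
  for (f in list.files(cache, full.names = TRUE)) {
    obj <- readRDS(f); obj$key <- "tampered"; saveRDS(obj, f)
  }
  w <- capture_warnings(
    sw2 <- run_sweep(ms, plan_sweep(grid), cache_dir = cache, opts = opts, seed = 4))
  expect_true(all(grepl("corrupt or stale", w)))
  expect_gte(length(w), 1)
  expect_true(all(sw2$executed$executed))
  expect_equal(tidy(sw1), tidy(sw2))
})

test_that("resource report counts planned vs naive step runs", {
  plan <- plan_sweep(default_sweep_grid())
  rr <- resource_report(plan)
  expect_equal(rr$planned, c(1L, 1L, 9L, 405L, 416L))
  expect_equal(rr$naive, c(405L, 405L, 405L, 405L, 1620L))
  expect_equal(rr$savings_ratio[1], 405)
  singleton <- resource_report(plan_sweep(param_grid(1e-5, 1.5, 0.3, 150, 8L)))
  expect_true(all(singleton$savings_ratio[1:4] == 1))
  small <- resource_report(plan_sweep(param_grid(c(1e-3, 1e-5), c(0.5, 1.5), 0.1, 40, 3L)))
  expect_equal(small$planned, c(1L, 1L, 2L, 4L, 8L))
})

test_that("sweep config files are validated against the grid schema", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("grid:",
               "  pvalue_threshold: [1.0e-3, 1.0e-5]",
               "  fp_per_100kbp: [0.5, 1.5]",
               "  fn_rate: [0.1]",
               "  min_length_kbp: [40]",
               "  min_labels: [3]",
               "options:",
               "  n_chunks: 2",
               "  null_reps: 30"), f)
  cfg <- read_sweep_config(f)
  expect_s3_class(cfg$grid, "om_param_grid")
  expect_equal(cfg$options$n_chunks, 2L)
  writeLines(c("grid:", "  pvalue_threshold: [1.0e-3]", "  bogus_key: [1]"), f)
  expect_error(read_sweep_config(f), "unknown grid keys: bogus_key")
  writeLines("options: {n_chunks: 2}", f)
  expect_error(read_sweep_config(f), "missing 'grid'")
})
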