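test_that("molecule filters are inclusive and order-preserving", {
  ms <- molecules(1:3, c(90e3, 100e3, 150e3),
                  list(c(1e4), c(1e4, 2e4), c(1e4, 2e4, 3e4)))
  expect_equal(filter_molecules(ms, 0, 0)$molecule_id, 1:3)
  expect_equal(filter_molecules(ms, 100, 0)$molecule_id, 2:3)
  expect_equal(filter_molecules(ms, 100, 3)$molecule_id, 3L)
  # brute-force oracle on a random set
  set.seed(41)
  rms <- random_molecule_set(50)
  got <- filter_molecules(rms, 150, 8)$molecule_id
  want <- rms$molecule_id[rms$length_bp >= 150e3 &
                            vapply(rms$labels_bp, length, 1L) >= 8]
  expect_identical(got, want)
})

test_that("sorting is stable by descending length then id", {
  expect_equal(nrow(sort_molecules(molecules())), 0)
  ms <- molecules(c(5L, 2L, 9L), c(1e5, 2e5, 1e5), list(1e4, 1e4, 1e4))
  s <- sort_molecules(ms)
  expect_equal(s$molecule_id, c(2L, 5L, 9L))
  expect_equal(sort_molecules(s)$molecule_id, s$molecule_id)
  set.seed(42)
  rms <- random_molecule_set(30)
  expect_equal(sort_molecules(rms)$length_bp,
               sort(rms$length_bp, decreasing = TRUE))
})

test_that("round-robin split balances chunks and is invertible", {
  ms <- sort_molecules(random_molecule_set(10, seed = 43))
  expect_equal(split_molecules(ms, 1)[[1]]$molecule_id, ms$molecule_id)
  ch <- split_molecules(ms, 5)
  expect_true(all(vapply(ch, nrow, 1L) == 2))
  # round-robin interleave restores the sorted order
  back <- dplyr::bind_rows(ch)
  expect_setequal(back$molecule_id, ms$molecule_id)
  totals <- vapply(ch, function(x) sum(x$length_bp), numeric(1))
  expect_lte(max(totals) - min(totals), max(ms$length_bp))
})

test_that("all-pairs overlap detection is chunk-invariant", {
  sim <- toy_simulation(ref_len = 3e5, coverage = 10, seed = 45)
  ms <- sort_molecules(sim$molecules)[1:50, ]
  p <- align_params(pvalue_threshold = 1e-3, null_reps = 50)
  ov1 <- all_pairs_overlaps(ms, p, seed = 5)
  ov3 <- all_pairs_overlaps(split_molecules(ms, 3), p, seed = 5)
  ov7 <- all_pairs_overlaps(split_molecules(ms, 7), p, seed = 5)
  expect_equal(ov1, ov3)
  expect_equal(ov1, ov7)
  expect_gt(nrow(ov1), 0)
})

test_that("single molecules and empty overlap sets give all singletons", {
  ms <- random_molecule_set(5, seed = 46)
  p <- align_params()
  expect_equal(nrow(all_pairs_overlaps(ms[1, ], p)), 0)
  asm <- assemble_olc(ms, all_pairs_overlaps(ms[1, ], p))
  expect_equal(nrow(asm$contigs), 0)
  expect_equal(asm$singletons, sort(ms$molecule_id))
})

test_that("two noiseless overlapping molecules assemble into one contig", {
  # irregular reference sites; two 100 kbp molecules overlapping by 50 kbp
  # (5 shared sites in the overlap window)
  sites <- c(7000, 18000, 26000, 41000, 53000, 62000, 78000, 84000, 96000,
             105000, 118000, 131000, 144000)
  m1 <- sites[sites <= 100000]
  m2 <- sites[sites > 50000] - 50000
  ms <- molecules(1:2, c(100000, 100000), list(m1, m2))
  p <- align_params(pvalue_threshold = 0.05, null_reps = 100)
  set.seed(47)
  ov <- all_pairs_overlaps(ms, p, seed = 8)
  expect_equal(nrow(ov), 1)
  asm <- assemble_olc(ms, ov)
  expect_equal(nrow(asm$contigs), 1)
  expect_equal(asm$contigs$length_bp, 150000, tolerance = 1e-6)
  # consensus = union of true sites, occurrence 2 on the shared ones
  expect_equal(asm$contigs$labels_bp[[1]], sites, tolerance = 1e-6)
  shared <- sites > 50000 & sites <= 100000
  expect_equal(asm$contigs$occurrence[[1]][shared], rep(2L, sum(shared)))
  expect_equal(asm$contigs$occurrence[[1]][!shared], rep(1L, sum(!shared)))
  expect_equal(length(asm$singletons), 0)
})

test_that("overlaps referencing unknown molecules error", {
  ms <- random_molecule_set(3, seed = 48)
  fake <- tibble::tibble(id_a = 1L, id_b = 99L, orientation = "+",
                         offset_bp = 0, score = 10, n_matched = 3L,
                         unmatched_a = 0L, unmatched_b = 0L, pvalue = 1e-6,
                         matched_pairs = list(cbind(1:3, 1:3)))
  expect_error(assemble_olc(ms, fake), "unknown molecule id 99")
})

test_that("noiseless coverage reconstructs the reference map", {
  set.seed(49)
  ref <- random_reference(5e5, 11)
  sim <- simulate_molecules(ref, 20, length_model(70, 40),
                            error_profile(0, 0, 0, seed = 50))
  ms <- sim$molecules
  p <- align_params(pvalue_threshold = 1e-4, null_reps = 100)
  ov <- all_pairs_overlaps(ms, p, seed = 10)
  asm <- assemble_olc(ms, ov, merge_radius_bp = 500)
  tm <- assembly_truth_metrics(asm, sim$truth, ref)
  expect_equal(tm$false_joins, 0)
  expect_gt(tm$label_recall, 0.95)
  # consensus label positions of the longest contig match true site spacing
  validate_contigs(asm$contigs)
})

test_that("assembly conserves molecules and consensus invariants hold", {
  sim <- toy_simulation(ref_len = 4e5, coverage = 12, seed = 51)
  ms <- sim$molecules
  p <- align_params(pvalue_threshold = 1e-3, null_reps = 50)
  asm <- assemble_olc(ms, all_pairs_overlaps(ms, p, seed = 11))
  expect_equal(nrow(asm$placements) + length(asm$singletons), nrow(ms))
  expect_equal(sort(c(asm$placements$molecule_id, asm$singletons)),
               sort(ms$molecule_id))
  for (i in seq_len(nrow(asm$contigs))) {
    lab <- asm$contigs$labels_bp[[i]]
    expect_true(all(diff(lab) > 0))
    expect_true(all(asm$contigs$occurrence[[i]] <= asm$contigs$coverage[[i]]))
  }
  # every contig is supported by >= 2 molecules
  expect_true(all(table(asm$placements$contig_id) >= 2))
})

test_that("degraded data yields more singletons than clean data, no crash", {
  set.seed(52)
  ref <- random_reference(4e5, 11)
  run_one <- function(fn) {
    sim <- simulate_molecules(ref, 12, length_model(60, 30),
                              error_profile(1.5, fn, 30, seed = 53))
    ms <- sim$molecules
    p <- align_params(fn_rate = min(fn, 0.45), pvalue_threshold = 1e-3,
                      null_reps = 50)
    asm <- assemble_olc(ms, all_pairs_overlaps(ms, p, seed = 12))
    length(asm$singletons) / nrow(ms)
  }
  clean <- run_one(0.05)
  dirty <- run_one(0.45)
  expect_gte(dirty, clean)
})
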