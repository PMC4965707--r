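test_that("self-alignment recovers the full identity matching", {
  set.seed(21)
  p <- align_params()
  for (n in c(3, 6, 10)) {
    m <- molecules(1L, 1.2e5, list(random_map(n, 1e5)))
    al <- align_pair(m, m, p)
    expect_equal(al$n_matched, n)
    expect_equal(al$orientation, "+")
    expect_equal(al$offset_bp, 0, tolerance = 1e-9)
    mp <- al$matched_pairs[[1]]
    expect_equal(mp[, "idx_a"], seq_len(n), ignore_attr = TRUE)
    expect_equal(mp[, "idx_b"], seq_len(n), ignore_attr = TRUE)
  }
})

test_that("DP equals exhaustive enumeration over monotone matchings", {
  set.seed(22)
  p <- align_params(max_skip = 6)
  for (case in 1:60) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- random_map(na, 6e4, 1500)
    b <- random_map(nb, 6e4, 1500)
    al <- align_pair(list(length_bp = 7e4, labels_bp = a),
                     list(length_bp = 7e4, labels_bp = b), p)
    oracle <- oracle_best_score(a, b, 7e4, p)
    expect_equal(al$score, oracle, tolerance = 1e-8)
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(23)
  p <- align_params()
  for (case in 1:20) {
    a <- list(id = 1L, length_bp = 9e4, labels_bp = random_map(sample(3:8, 1), 8e4))
    b <- list(id = 2L, length_bp = 9e4, labels_bp = random_map(sample(3:8, 1), 8e4))
    ab <- align_pair(a, b, p)
    ba <- align_pair(b, a, p)
    expect_equal(is.null(ab), is.null(ba))
    if (!is.null(ab)) {
      expect_equal(ab$score, ba$score, tolerance = 1e-8)
      expect_equal(ab$n_matched, ba$n_matched)
    }
  }
})

test_that("reflecting b flips the reported orientation, score unchanged", {
  set.seed(24)
  p <- align_params()
  sim <- toy_simulation(coverage = 4, fp = 0.5, fn = 0.05, seed = 77)
  ms <- sim$molecules
  done <- 0
  for (i in 1:(nrow(ms) - 1)) {
    for (j in (i + 1):nrow(ms)) {
      al <- align_pair(ms[i, ], ms[j, ], p)
      if (is.null(al) || al$n_matched < 4) next
      b <- ms[j, ]
      refl <- molecules(b$molecule_id, b$length_bp,
                        list(rev(b$length_bp - b$labels_bp[[1]])))
      al2 <- align_pair(ms[i, ], refl, p)
      expect_equal(al2$score, al$score, tolerance = 1e-8)
      expect_false(al2$orientation == al$orientation)
      done <- done + 1
      if (done >= 5) break
    }
    if (done >= 5) break
  }
  expect_gte(done, 5)
})

test_that("score strictly decreases as a matched interval's discrepancy grows", {
  p <- align_params()
  a <- list(length_bp = 6e4, labels_bp = c(10000, 20000, 30000, 40000, 50000))
  scores <- vapply(c(0, 200, 400, 600), function(shift) {
    b <- list(length_bp = 6e4,
              labels_bp = c(10000, 20000, 30000 + shift, 40000 + shift, 50000 + shift))
    align_pair(a, b, p)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("matched pairs are strictly increasing and window counts consistent", {
  set.seed(25)
  p <- align_params()
  for (case in 1:25) {
    a <- list(length_bp = 1e5, labels_bp = random_map(sample(4:10, 1), 9e4))
    b <- list(length_bp = 1e5, labels_bp = random_map(sample(4:10, 1), 9e4))
    al <- align_pair(a, b, p)
    if (is.null(al)) next
    mp <- al$matched_pairs[[1]]
    expect_true(all(diff(mp[, 1]) > 0))
    expect_true(all(diff(mp[, 2]) > 0))
    expect_gte(al$n_matched, 2)
    expect_equal(al$unmatched_a,
                 diff(range(mp[, 1])) + 1 - al$n_matched, ignore_attr = TRUE)
  }
})

test_that("empirical p-values respect the smoothing floor and monotonicity", {
  set.seed(26)
  p <- align_params(pvalue_method = "empirical")
  a <- molecules(1L, 1e5, list(random_map(8, 9e4)))
  al <- align_pair(a, a, p)
  pv <- alignment_pvalue(al, a, a, p, null_reps = 49, seed = 99)
  expect_gte(pv, 1 / 50)
  expect_lte(pv, 1)
  # monotone in the observed score for a fixed null distribution
  nulls <- rnorm(200)
  scores <- seq(-2, 4, by = 0.5)
  pvs <- vapply(scores, omsweep:::pvalue_from_null, numeric(1),
                null_scores = nulls, method = "empirical")
  expect_true(all(diff(pvs) <= 0))
})

test_that("unrelated molecules of similar density are not significant", {
  set.seed(27)
  p <- align_params()
  n_sig <- 0; n_tested <- 0
  for (case in 1:40) {
    a <- molecules(1L, 1.6e5, list(random_map(12, 1.5e5, 5000)))
    b <- molecules(2L, 1.6e5, list(random_map(12, 1.5e5, 5000)))
    al <- align_pair(a, b, p)
    if (is.null(al)) next
    n_tested <- n_tested + 1
    pv <- alignment_pvalue(al, a, b, p, null_reps = 100, seed = case)
    if (pv <= 1.11e-4) n_sig <- n_sig + 1
  }
  expect_gte(n_tested, 30)
  expect_lte(n_sig / n_tested, 0.05)
})

test_that("molecules sharing many true sites are overwhelmingly significant", {
  sim <- toy_simulation(coverage = 8, fp = 0.5, fn = 0.05, seed = 31,
                        mean_kbp = 80, min_kbp = 50)
  p <- align_params()
  ms <- sim$molecules
  tr <- sim$truth
  pvs <- numeric(0)
  for (i in 1:(nrow(ms) - 1)) {
    for (j in (i + 1):nrow(ms)) {
      shared <- length(intersect(
        tr$provenance[[i]][!is.na(tr$provenance[[i]])],
        tr$provenance[[j]][!is.na(tr$provenance[[j]])]))
      if (shared < 6) next
      al <- align_pair(ms[i, ], ms[j, ], p)
      pvs <- c(pvs, if (is.null(al)) 1 else {
        alignment_pvalue(al, ms[i, ], ms[j, ], p, null_reps = 200, seed = 7)
      })
      if (length(pvs) >= 30) break
    }
    if (length(pvs) >= 30) break
  }
  expect_gte(length(pvs), 30)
  # most pairs with >= 6 shared sites are detected; a few are lost to
  # unlucky sizing-noise draws, as on real instruments
  expect_gte(mean(pvs < 0.05), 0.75)
  expect_lt(median(pvs), 0.01)
})

test_that("confidence is the negative base-10 log of the p-value", {
  expect_equal(confidence(1.0), 0)
  expect_equal(confidence(1e-6), 6)
  expect_equal(pvalue_from_confidence(0), 1)
  expect_equal(confidence(pvalue_from_confidence(13.7)), 13.7)
  expect_error(confidence(0), "0, 1")
  expect_error(confidence(-1), "0, 1")
  expect_error(pvalue_from_confidence(-2), ">= 0")
})
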