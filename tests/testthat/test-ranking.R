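test_that("the feature-count schedule shrinks by 10% (floored) down to 1", {
  expect_identical(head(k_schedule(44608), 3), c(44608L, 40147L, 36132L))
  expect_identical(k_schedule(1), 1L)
  expect_identical(k_schedule(10), 10:1)
  for (p in c(2, 7, 97, 5000)) {
    ks <- k_schedule(p)
    expect_equal(ks[1], p)
    expect_equal(ks[length(ks)], 1L)
    expect_true(all(diff(ks) < 0))
    expect_true(all(ks[-1] == pmax(1, floor(0.9 * ks[-length(ks)])) |
                      ks[-1] == ks[-length(ks)] - 1L))
  }
})

test_that("RFE keeps the single separating feature until the end", {
  # fc separates the classes perfectly; fa, fb are constant-ish noise
  x <- cbind(fa = c(.5, .5, .5, .5, .5, .5),
             fb = c(.4, .6, .5, .4, .6, .5),
             fc = c(1, 1, 1, 0, 0, 0))
  rownames(x) <- paste0("s", 1:6)
  y <- c(1, 1, 1, 0, 0, 0)
  for (fam in c("logistic_regression", "svm_linear")) {
    # suppressWarnings: glmnet cautions about tiny class sizes on this toy
    rk <- suppressWarnings(
      rfe_rank(x, y, classifier_spec(fam, seed = 1), step_fraction = 0.1))
    expect_identical(rk$feature_id[1], "fc")
  }
  expect_error(rfe_rank(x, y, classifier_spec("svm_rbf")), "linear")
})

test_that("RFE produces a complete deterministic permutation with lexicographic ties", {
  x <- toy_matrix(10, 4, seed = 3)
  y <- rep(c(1L, 0L), 5)
  rk <- suppressWarnings(
    rfe_rank(x, y, classifier_spec("logistic_regression"), step_fraction = 0.1))
  expect_setequal(rk$feature_id, colnames(x))
  expect_identical(rk$rank, 1:4)
  # duplicated column: tied weights resolve lexicographically (the earlier
  # ID survives longer), and reruns are identical
  x2 <- cbind(x, f01b = x[, "f01"])
  rk2 <- suppressWarnings(
    rfe_rank(x2, y, classifier_spec("logistic_regression"), 0.1))
  pos <- match(c("f01", "f01b"), rk2$feature_id)
  expect_lt(pos[1], pos[2])
  expect_identical(rk2, suppressWarnings(
    rfe_rank(x2, y, classifier_spec("logistic_regression"), 0.1)))
})

test_that("forest importance ranks planted signal above noise and is seeded", {
  ranks_signal <- ranks_null <- numeric(0)
  for (s in 1:5) {
    cfg <- synthetic_config(n_cases = 30, n_controls = 30, n_probes = 30,
                            n_taxa = 4, n_signal_probes = 5, n_signal_taxa = 0,
                            probe_effect = 2, missing_transcriptome = 0,
                            missing_microbiota = 0, seed = s)
    co <- generate_cohort(cfg)
    x <- min_max_normalize(as_feature_matrix(co$transcriptome))
    rk <- rfc_importance_rank(x, co$labels$label, n_trees = 100, seed = s)
    is_sig <- rk$feature_id %in% co$ground_truth$signal_probes
    ranks_signal <- c(ranks_signal, rk$rank[is_sig])
    ranks_null <- c(ranks_null, rk$rank[!is_sig])
  }
  expect_lt(mean(ranks_signal), mean(ranks_null))

  x <- toy_matrix(20, 8, seed = 2)
  y <- rep(c(1L, 0L), 10)
  expect_identical(rfc_importance_rank(x, y, 50, seed = 9),
                   rfc_importance_rank(x, y, 50, seed = 9))
  expect_error(rfc_importance_rank(x, y, 0), "n_trees")
})

test_that("pure-noise data shows no spuriously dominant feature", {
  set.seed(31)
  max_ratio <- sapply(1:20, function(s) {
    x <- toy_matrix(30, 10, seed = 100 + s)
    y <- rep(c(1L, 0L), 15)
    rk <- rfc_importance_rank(x, y, n_trees = 60, seed = s)
    max(rk$score) / mean(rk$score)
  })
  expect_true(all(max_ratio < 3))
})

test_that("importance-floor selection rescales by the maximum score", {
  rk <- structure(tibble::tibble(feature_id = c("a", "b", "c"),
                                 score = c(10, 9.5, 1), rank = 1:3),
                  method = "chi2",
                  class = c("feature_ranking", class(tibble::tibble())))
  expect_identical(threshold_select(rk, 0.95), c("a", "b"))
  expect_identical(threshold_select(rk, 0), c("a", "b", "c"))
  expect_identical(threshold_select(rk, 1), "a")
  rk0 <- structure(tibble::tibble(feature_id = "a", score = 0, rank = 1L),
                   method = "chi2",
                   class = c("feature_ranking", class(tibble::tibble())))
  expect_warning(out <- threshold_select(rk0, 0.5), "zero")
  expect_length(out, 0)
})
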