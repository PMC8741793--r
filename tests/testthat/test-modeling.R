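test_that("every family fits separable data perfectly and refits identically", {
  toy <- separable_toy(10, seed = 2)
  fams <- c("logistic_regression", "svm_linear", "svm_rbf",
            "random_forest", "gradient_boosted_trees")
  for (fam in fams) {
    spec <- classifier_spec(fam, seed = 5)
    fit <- fit_classifier(spec, toy$x, toy$y)
    p <- predict_proba(fit, toy$x)
    expect_true(all(p >= 0 & p <= 1))
    cm <- confusion(classify(p, 0.5), toy$y)
    expect_equal(classification_metrics(cm)$f1, 1.0,
                 info = paste("training F1 for", fam))
    # determinism: same spec + seed + data twice
    p2 <- predict_proba(fit_classifier(spec, toy$x, toy$y), toy$x)
    expect_identical(p, p2, info = fam)
  }
  expect_error(fit_classifier(classifier_spec("svm_rbf"), toy$x, rep(1, 20)),
               "single class")
})

test_that("probability prediction enforces the feature manifest and row order", {
  toy <- separable_toy(8, seed = 3)
  fit <- fit_classifier(classifier_spec("svm_rbf", seed = 1), toy$x, toy$y)
  swapped <- toy$x[, c("fb", "fa")]
  expect_error(predict_proba(fit, swapped), "fb")
  expect_error(predict_proba(fit, toy$x[, "fa", drop = FALSE]),
               "feature count")
  # row permutation permutes probabilities correspondingly
  p <- predict_proba(fit, toy$x)
  perm <- c(3, 1, 2, seq(4, nrow(toy$x)))
  expect_equal(predict_proba(fit, toy$x[perm, ]), p[perm])
})

test_that("label-permuted data yields chance-level cross-validated F1", {
  d <- generate_cohort(small_cohort_config(seed = 20, n_cases = 30,
                                           n_controls = 30,
                                           missing_transcriptome = 0,
                                           missing_microbiota = 0))
  x <- min_max_normalize(as_feature_matrix(d$transcriptome))
  set.seed(77)
  y_perm <- sample(d$labels$label)
  fold <- rep_len(1:5, length(y_perm))
  f1 <- sapply(1:5, function(f) {
    fit <- fit_classifier(classifier_spec("svm_rbf", seed = f),
                          x[fold != f, ], y_perm[fold != f])
    p <- predict_proba(fit, x[fold == f, ])
    classification_metrics(confusion(classify(p, 0.5), y_perm[fold == f]))$f1
  })
  expect_gt(mean(f1), 0.30)
  expect_lt(mean(f1), 0.70)
})

test_that("thresholding is strict and monotone", {
  expect_identical(classify(c(0.2, 0.31, 0.5), 0.3), c(0L, 1L, 1L))
  expect_identical(classify(0.5, 0.5), 0L)  # strict inequality at the boundary
  probs <- seq(0, 1, by = 0.05)
  n_pos <- sapply(c(0.7, 0.5, 0.3, 0.1), function(t) sum(classify(probs, t)))
  expect_true(all(diff(n_pos) >= 0))
  expect_error(classify(0.5, 1), "p_t")
})

test_that("threshold tuning maximises cross-validated F1 over the grid", {
  # imbalanced cohort with weak signal: a conservative model under-calls
  # cases, so F1 favours a threshold below the default 0.5
  cfg <- synthetic_config(n_cases = 30, n_controls = 14, n_probes = 20,
                          n_taxa = 4, n_signal_probes = 3, n_signal_taxa = 0,
                          probe_effect = 0.6, missing_transcriptome = 0,
                          missing_microbiota = 0, seed = 14)
  co <- generate_cohort(cfg)
  x <- min_max_normalize(as_feature_matrix(co$transcriptome))
  y <- co$labels$label
  tuned <- tune_threshold(classifier_spec("svm_rbf", seed = 2), x, y,
                          grid = seq(0.1, 0.9, 0.1), n_folds = 4, seed = 2)
  expect_equal(nrow(tuned$trace), 9)
  expect_lt(tuned$best_p_t, 0.5)
  # the chosen threshold attains the maximum of the trace
  expect_equal(tuned$trace$mean_f1[tuned$trace$p_t == tuned$best_p_t],
               max(tuned$trace$mean_f1))

  single <- tune_threshold(classifier_spec("svm_rbf", seed = 2), x, y,
                           grid = 0.5, n_folds = 4, seed = 2)
  expect_equal(single$best_p_t, 0.5)
  expect_error(tune_threshold(classifier_spec("svm_rbf"), x, y,
                              grid = numeric(0)), "empty")
})

test_that("cross-validated configurations do not grossly overfit planted data", {
  d <- generate_cohort(small_cohort_config(seed = 17, missing_transcriptome = 0,
                                           missing_microbiota = 0))
  x <- min_max_normalize(as_feature_matrix(d$transcriptome))
  y <- d$labels$label
  sel <- select_plan_b(x, y, schedule = c(10L, 5L),
                       model = classifier_spec("svm_rbf", seed = 3), seed = 3)
  xs <- x[, sel$selected_ids, drop = FALSE]
  fit <- fit_classifier(classifier_spec("svm_rbf", seed = 3), xs, y)
  train_f1 <- classification_metrics(
    confusion(classify(predict_proba(fit, xs), 0.5), y))$f1
  expect_gte(train_f1, max(sel$cv_trace$mean_f1) - 0.25)
})

test_that("model artifacts round-trip with their feature manifest", {
  toy <- separable_toy(6, seed = 5)
  fit <- fit_classifier(classifier_spec("random_forest", seed = 2),
                        toy$x, toy$y, threshold = 0.3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(fit, path)
  back <- load_classifier(path)
  expect_identical(back$feature_ids, colnames(toy$x))
  expect_equal(back$threshold, 0.3)
  expect_equal(predict_proba(back, toy$x), predict_proba(fit, toy$x))
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_classifier(junk), "artifact")
})
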