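make_planted_training <- function(seed, n_probes = 60, n_signal = 8,
                                  effect = 2) {
  cfg <- synthetic_config(n_cases = 28, n_controls = 22, n_probes = n_probes,
                          n_taxa = 4, n_signal_probes = n_signal,
                          n_signal_taxa = 0, probe_effect = effect,
                          missing_transcriptome = 0, missing_microbiota = 0,
                          seed = seed)
  co <- generate_cohort(cfg)
  list(x = min_max_normalize(as_feature_matrix(co$transcriptome)),
       y = co$labels$label, signal = co$ground_truth$signal_probes)
}

test_that("plan B finds a feature count near the planted signal and recovers it", {
  # 20 weak planted probes among 1,000 at cohort scale: the cross-validated
  # k-search should land within a factor of 3 of 20 and recover >= 90%
  for (s in 1:5) {
    cfg <- synthetic_config(n_cases = 88, n_controls = 72, n_probes = 1000,
                            n_taxa = 4, n_signal_probes = 20, n_signal_taxa = 0,
                            probe_effect = 1.0, missing_transcriptome = 0,
                            missing_microbiota = 0, seed = s)
    co <- generate_cohort(cfg)
    x <- min_max_normalize(as_feature_matrix(co$transcriptome))
    sel <- select_plan_b(x, co$labels$label, ranker = "chi2",
                         schedule = k_schedule(ncol(x)),
                         model = classifier_spec("svm_rbf", seed = s), seed = s)
    expect_gte(sel$chosen_k, 20 / 3)
    expect_lte(sel$chosen_k, 20 * 3)
    expect_gte(mean(co$ground_truth$signal_probes %in% sel$selected_ids), 0.9)
    expect_equal(nrow(sel$cv_trace), length(k_schedule(ncol(x))))
    # plan B contract: selected = top chosen_k of the full-training ranking
    expect_identical(sel$selected_ids,
                     sel$ranking$feature_id[seq_len(sel$chosen_k)])
  }
})

test_that("a single-value schedule degenerates gracefully", {
  d <- make_planted_training(4)
  sel_all <- select_plan_b(d$x, d$y, schedule = ncol(d$x),
                           model = classifier_spec("svm_rbf"), seed = 1)
  expect_setequal(sel_all$selected_ids, colnames(d$x))
  sel_k <- select_plan_b(d$x, d$y, schedule = 5L,
                         model = classifier_spec("svm_rbf"), seed = 1)
  expect_length(sel_k$selected_ids, 5)
  expect_equal(sel_k$chosen_k, 5L)
})

test_that("plan A intersects per-fold sets and retains them", {
  cfg <- synthetic_config(n_cases = 88, n_controls = 72, n_probes = 300,
                          n_taxa = 4, n_signal_probes = 20, n_signal_taxa = 0,
                          probe_effect = 1.5, missing_transcriptome = 0,
                          missing_microbiota = 0, seed = 6)
  co <- generate_cohort(cfg)
  x <- min_max_normalize(as_feature_matrix(co$transcriptome))
  sel <- select_plan_a(x, co$labels$label, ranker = "chi2",
                       schedule = c(60L, 40L, 30L, 25L, 20L),
                       model = classifier_spec("svm_rbf", seed = 2), seed = 2)
  expect_length(sel$per_fold_sets, 5)
  for (fs in sel$per_fold_sets) {
    expect_true(all(sel$selected_ids %in% fs))
  }
  expect_lte(length(sel$selected_ids),
             min(lengths(sel$per_fold_sets)))
  # strong planted signal lands in every fold's set, hence the intersection
  expect_gte(mean(co$ground_truth$signal_probes %in% sel$selected_ids), 0.9)
})

test_that("feature selection never reads rows outside its training partition", {
  d <- make_planted_training(9)
  train <- 1:40
  sel1 <- select_plan_b(d$x[train, ], d$y[train], schedule = c(10L, 5L),
                        model = classifier_spec("svm_rbf"), seed = 3)
  x_mut <- d$x
  x_mut[41:50, ] <- 0.123  # mutate held-out rows only
  sel2 <- select_plan_b(x_mut[train, ], d$y[train], schedule = c(10L, 5L),
                        model = classifier_spec("svm_rbf"), seed = 3)
  expect_identical(sel1$selected_ids, sel2$selected_ids)
  expect_identical(sel1$cv_trace, sel2$cv_trace)
})

test_that("integration strategies combine modalities as specified", {
  cfg <- small_cohort_config(seed = 13, n_probes = 40, n_taxa = 20,
                             n_signal_probes = 4, n_signal_taxa = 4,
                             probe_effect = 2, taxa_effect = 5,
                             missing_transcriptome = 0, missing_microbiota = 0)
  co <- generate_cohort(cfg)
  tm <- min_max_normalize(as_feature_matrix(co$transcriptome))
  mm <- min_max_normalize(as_feature_matrix(co$microbiota))
  y <- co$labels$label

  # late fusion with fixed per-modality targets: widths add up
  out4 <- integrate_modalities(tm, mm, y, "select_then_combine",
                               n_transcriptome = 5L, n_microbiota = 7L,
                               seed = 1)
  expect_equal(ncol(out4$features), 12)
  expect_equal(sum(out4$provenance$modality == "transcriptome"), 5)
  expect_equal(sum(out4$provenance$modality == "microbiota"), 7)

  # transcriptome-only reduces to a single-modality selection
  out2 <- integrate_modalities(tm, mm, y, "transcriptome_only",
                               n_transcriptome = 5L, seed = 1)
  sel_ref <- select_plan_b(tm, y, schedule = 5L,
                           model = classifier_spec("svm_rbf"), seed = 1)
  expect_identical(colnames(out2$features), sel_ref$selected_ids)
  expect_true(all(out2$provenance$modality == "transcriptome"))

  # early fusion on modalities that are informative in complementary ways
  out3 <- integrate_modalities(tm, mm, y, "combine_then_select",
                               n_combined = 10L, seed = 1)
  expect_setequal(unique(out3$provenance$modality),
                  c("transcriptome", "microbiota"))

  expect_error(integrate_modalities(tm, mm[-1, ], y, "microbiota_only"),
               "identical ordered sample")
})
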