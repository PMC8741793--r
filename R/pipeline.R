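#' Configure an end-to-end classification experiment
#'
#' Describes one complete run of the pipeline: data source, split,
#' normalization scope, feature selection, integration strategy, model,
#' jittering and thresholding. Every stochastic stage takes its seed from
#' the single master `seed` (split uses `seed`, selection `seed + 1`,
#' model `seed + 2`, jitter `seed + 3`), so a config reruns bit-identically.
#'
#' @param transcriptome,microbiota,labels File paths of the three
#'   tab-separated inputs, or `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_config()] to generate the cohort in
#'   memory instead of reading files. Exactly one of the two data sources
#'   must be provided.
#' @param label Short human-readable tag for comparison tables.
#' @param test_size Held-out test-set size (default 30).
#' @param normalization_scope `"joint"` normalizes training and test sets
#'   together (the classical workflow this pipeline mirrors);
#'   `"train_only"` fits min/max on the training set only, avoiding any
#'   influence of held-out rows.
#' @param strategy Integration strategy tag (see [integrate_modalities()]).
#' @param plan Feature-selection plan, `"B"` (single five-fold CV, default)
#'   or `"A"` (nested CV with intersection).
#' @param ranker Ranking method tag (see [rank_features()]).
#' @param n_transcriptome,n_microbiota,n_combined Per-selection feature
#'   targets: a fixed integer, `NULL` for a cross-validated k-search, `NA`
#'   to disable selection.
#' @param model_family,model_hyperparameters Classifier family and
#'   overrides (see [classifier_spec()]).
#' @param jitter_intensity Gaussian noise intensity I applied to the
#'   normalized training transcriptome block (0 disables; microbiota is
#'   never jittered).
#' @param variance_convention Jitter scale convention (see [add_jitter()]).
#' @param p_t Decision threshold, used as-is when `tune_threshold = FALSE`.
#' @param tune_threshold If `TRUE`, choose `p_t` from `threshold_grid` by
#'   cross-validation on the training set.
#' @param threshold_grid Candidate thresholds for tuning.
#' @param n_folds Folds for every cross-validated search (default 5).
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(transcriptome = NULL, microbiota = NULL,
                              labels = NULL, synthetic = NULL,
                              label = "experiment",
                              test_size = 30L,
                              normalization_scope = c("joint", "train_only"),
                              strategy = "select_then_combine",
                              plan = c("B", "A"), ranker = "chi2",
                              n_transcriptome = 35L, n_microbiota = 50L,
                              n_combined = NULL,
                              model_family = "svm_rbf",
                              model_hyperparameters = list(),
                              jitter_intensity = 0,
                              variance_convention = "variance_equals_I",
                              p_t = 0.5, tune_threshold = FALSE,
                              threshold_grid = seq(0.1, 0.9, by = 0.1),
                              n_folds = 5L, seed = 1L) {
  normalization_scope <- match.arg(normalization_scope)
  plan <- match.arg(plan)
  have_files <- !is.null(transcriptome) || !is.null(microbiota) || !is.null(labels)
  if (have_files && !is.null(synthetic)) {
    abort("give either input file paths or a synthetic config, not both")
  }
  if (have_files) {
    for (p in c(transcriptome, microbiota, labels)) {
      if (!file.exists(p)) abort(paste0("input file does not exist: ", p))
    }
  } else if (is.null(synthetic)) {
    abort("one of {input paths, synthetic config} is required")
  }
  structure(list(
    transcriptome = transcriptome, microbiota = microbiota, labels = labels,
    synthetic = synthetic, label = label,
    test_size = as.integer(test_size),
    normalization_scope = normalization_scope,
    strategy = strategy, plan = plan, ranker = ranker,
    n_transcriptome = n_transcriptome, n_microbiota = n_microbiota,
    n_combined = n_combined,
    model_family = model_family,
    model_hyperparameters = model_hyperparameters,
    jitter_intensity = jitter_intensity,
    variance_convention = variance_convention,
    p_t = p_t, tune_threshold = tune_threshold,
    threshold_grid = threshold_grid,
    n_folds = as.integer(n_folds), seed = as.integer(seed)
  ), class = "experiment_config")
}

# Load (files) or generate (synthetic) the raw tables.
load_experiment_data <- function(config) {
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    list(transcriptome = cohort$transcriptome,
         microbiota = cohort$microbiota,
         labels = cohort$labels)
  } else {
    list(transcriptome = read_feature_table(config$transcriptome, "transcriptome"),
         microbiota = read_feature_table(config$microbiota, "microbiota"),
         labels = read_labels(config$labels))
  }
}

# Plan dispatch used by run_experiment: reproduces integrate_modalities()
# but honours plan A where requested.
select_with_plan <- function(m, y, config, n_target, seed) {
  if (length(n_target) == 1 && is.na(n_target)) {
    return(list(ids = colnames(m), sel = NULL))
  }
  schedule <- if (is.null(n_target)) k_schedule(ncol(m)) else as.integer(n_target)
  model <- classifier_spec(config$model_family, config$model_hyperparameters,
                           seed = seed)
  sel <- if (config$plan == "A") {
    select_plan_a(m, y, ranker = config$ranker, n_outer = config$n_folds,
                  n_inner = config$n_folds, schedule = schedule,
                  model = model, seed = seed)
  } else {
    select_plan_b(m, y, ranker = config$ranker, n_folds = config$n_folds,
                  schedule = schedule, model = model, seed = seed)
  }
  list(ids = sel$selected_ids, sel = sel)
}

#' Run one end-to-end classification experiment
#'
#' Executes read/generate -> align -> mean-impute -> stratified split ->
#' min-max normalize -> jitter (training transcriptome only) -> feature
#' selection under the configured integration strategy -> fit -> threshold
#' -> evaluation on the held-out test set. Held-out rows influence nothing
#' before the final evaluation, except through joint min/max normalization
#' when that scope is configured.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the selection table,
#'   model artifact, report, ROC points and a YAML run log (sufficient to
#'   [replay_run()] the experiment bit-identically) are written there.
#' @return An `evaluation_report` whose `provenance` records the config,
#'   derived seeds, selection summary and feature provenance.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- list(split = config$seed, selection = config$seed + 1L,
                model = config$seed + 2L, jitter = config$seed + 3L)

  raw <- load_experiment_data(config)
  cohort <- align_modalities(raw$transcriptome, raw$microbiota, raw$labels)
  cohort$microbiota <- mean_impute(cohort$microbiota,
                                   cohort$imputed_microbiota_samples)

  split <- stratified_split(cohort$labels, config$test_size, seeds$split)
  tm <- as_feature_matrix(cohort$transcriptome)
  mm <- as_feature_matrix(cohort$microbiota)
  y <- setNames(cohort$labels$label, cohort$labels$sample_id)

  if (config$normalization_scope == "joint") {
    tm <- min_max_normalize(tm)
    mm <- min_max_normalize(mm)
  } else {
    rng_t <- fit_minmax(tm[split$train_ids, , drop = FALSE])
    rng_m <- fit_minmax(mm[split$train_ids, , drop = FALSE])
    tm <- apply_minmax(tm, rng_t)
    mm <- apply_minmax(mm, rng_m)
  }

  tm_train <- tm[split$train_ids, , drop = FALSE]
  mm_train <- mm[split$train_ids, , drop = FALSE]
  y_train <- y[split$train_ids]

  if (config$jitter_intensity > 0) {
    tm_train <- add_jitter(tm_train, config$jitter_intensity,
                           seed = seeds$jitter,
                           variance_convention = config$variance_convention)
    # chi-square scoring needs non-negative input; noise can dip below 0
    tm_train <- pmax(tm_train, 0)
  }

  sel_t <- sel_m <- sel_c <- NULL
  train_block <- switch(config$strategy,
    transcriptome_only = {
      b <- select_with_plan(tm_train, y_train, config, config$n_transcriptome,
                            seeds$selection)
      sel_t <- b$sel
      tm_train[, b$ids, drop = FALSE]
    },
    microbiota_only = {
      b <- select_with_plan(mm_train, y_train, config, config$n_microbiota,
                            seeds$selection)
      sel_m <- b$sel
      mm_train[, b$ids, drop = FALSE]
    },
    combine_then_select = {
      comb <- cbind(tm_train, mm_train)
      b <- select_with_plan(comb, y_train, config, config$n_combined,
                            seeds$selection)
      sel_c <- b$sel
      comb[, b$ids, drop = FALSE]
    },
    select_then_combine = {
      bt <- select_with_plan(tm_train, y_train, config, config$n_transcriptome,
                             seeds$selection)
      bm <- select_with_plan(mm_train, y_train, config, config$n_microbiota,
                             seeds$selection)
      sel_t <- bt$sel; sel_m <- bm$sel
      cbind(tm_train[, bt$ids, drop = FALSE], mm_train[, bm$ids, drop = FALSE])
    },
    abort(paste0("unknown strategy: ", config$strategy))
  )

  spec <- classifier_spec(config$model_family, config$model_hyperparameters,
                          seed = seeds$model)
  p_t <- config$p_t
  threshold_trace <- NULL
  if (isTRUE(config$tune_threshold)) {
    tuned <- tune_threshold(spec, train_block, y_train,
                            grid = config$threshold_grid,
                            n_folds = config$n_folds, seed = seeds$model)
    p_t <- tuned$best_p_t
    threshold_trace <- tuned$trace
  }
  model <- fit_classifier(spec, train_block, y_train, threshold = p_t)

  test_block <- cbind(tm, mm)[split$test_ids, colnames(train_block),
                              drop = FALSE]
  probs <- predict_proba(model, test_block)
  mod_of <- c(setNames(rep("transcriptome", ncol(tm)), colnames(tm)),
              setNames(rep("microbiota", ncol(mm)), colnames(mm)))
  provenance <- list(
    config = unclass(config), seeds = seeds,
    split = split,
    n_features = ncol(train_block),
    feature_provenance = tibble(feature_id = colnames(train_block),
                                modality = unname(mod_of[colnames(train_block)])),
    selection = list(transcriptome = sel_t, microbiota = sel_m,
                     combined = sel_c),
    threshold_trace = threshold_trace,
    imputed_microbiota_samples = cohort$imputed_microbiota_samples
  )
  report <- evaluate_predictions(probs, y[split$test_ids], p_t = p_t,
                                 provenance = provenance)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(report, out_dir)
    for (nm in names(provenance$selection)) {
      sel <- provenance$selection[[nm]]
      if (!is.null(sel)) {
        write_selection(sel, file.path(out_dir, paste0("selection_", nm, ".tsv")),
                        modality_of = mod_of)
      }
    }
    save_classifier(model, file.path(out_dir, "model.rds"))
    write_run_log(config, seeds, file.path(out_dir, "run_log.yaml"))
  }
  report
}

# The run log holds everything needed to re-execute the run bit-identically.
write_run_log <- function(config, seeds, path) {
  log <- list(
    adclassify_run_log = 1L,
    config = serialize_config(config),
    derived_seeds = seeds
  )
  yaml::write_yaml(log, path)
  invisible(path)
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) out$synthetic <- unclass(out$synthetic)
  # NULLs vanish in YAML; encode the selection-disabling NA explicitly
  for (k in c("n_transcriptome", "n_microbiota", "n_combined")) {
    if (!is.null(out[[k]]) && length(out[[k]]) == 1 && is.na(out[[k]])) {
      out[[k]] <- "disabled"
    }
  }
  out
}

deserialize_config <- function(lst) {
  for (k in c("n_transcriptome", "n_microbiota", "n_combined")) {
    if (identical(lst[[k]], "disabled")) lst[[k]] <- NA
  }
  if (!is.null(lst$synthetic)) {
    lst$synthetic <- do.call(synthetic_config, lst$synthetic)
  }
  do.call(experiment_config, lst)
}

#' Re-execute an experiment from its run log
#'
#' @param log_path Path to a `run_log.yaml` written by [run_experiment()].
#' @param out_dir Optional output directory for the replayed run.
#' @return The replayed `evaluation_report` (bit-identical to the original
#'   run's report).
#' @export
replay_run <- function(log_path, out_dir = NULL) {
  log <- yaml::read_yaml(log_path)
  if (!identical(log$adclassify_run_log, 1L)) {
    abort("not an adclassify run log")
  }
  run_experiment(deserialize_config(log$config), out_dir = out_dir)
}

#' Run and tabulate several experiment configurations side by side
#'
#' All configs must share the master seed and test size so their held-out
#' test sets coincide and rows are comparable.
#'
#' @param configs List of [experiment_config()] objects.
#' @return A tibble with one row per config: `label`, `n_features`, `p_t`,
#'   `f1`, `accuracy`, `precision`, `recall`, `auc`.
#' @export
run_comparison <- function(configs) {
  if (length(configs) < 2) abort("run_comparison needs >= 2 configs")
  seeds <- vapply(configs, function(cf) cf$seed, integer(1))
  sizes <- vapply(configs, function(cf) cf$test_size, integer(1))
  if (length(unique(seeds)) != 1 || length(unique(sizes)) != 1) {
    abort("configs must share the master seed and test size to be comparable")
  }
  purrr::map_dfr(configs, function(cf) {
    r <- run_experiment(cf)
    m <- r$metrics
    tibble(label = cf$label,
           n_features = r$provenance$n_features,
           p_t = r$p_t,
           f1 = m$f1, accuracy = m$accuracy,
           precision = m$precision, recall = m$recall,
           auc = r$auc)
  })
}

#' @export
print.experiment_config <- function(x, ...) {
  src <- if (!is.null(x$synthetic)) "synthetic cohort" else "files"
  cat(sprintf(paste0(
    "# experiment_config '%s'\n",
    "#   data: %s | test size %d | normalization: %s\n",
    "#   strategy: %s | plan %s | ranker %s | model %s\n",
    "#   jitter I = %g | p_t = %s | seed %d\n"),
    x$label, src, x$test_size, x$normalization_scope,
    x$strategy, x$plan, x$ranker, x$model_family,
    x$jitter_intensity,
    if (isTRUE(x$tune_threshold)) "tuned" else format(x$p_t), x$seed))
  invisible(x)
}
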