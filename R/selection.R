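# Cross-validated feature-count search shared by both selection plans.
# For each fold: rank on the fold-training block once (rankings do not
# depend on k), then for each candidate k fit the model on the top-k
# features and score F1 on the fold-validation block.
cv_k_search <- function(m, y, ranker, n_folds, schedule, model, seed,
                        step_fraction = 0.1, n_trees = 100L) {
  fold <- stratified_folds(y, n_folds, seed)
  f1 <- matrix(NA_real_, nrow = n_folds, ncol = length(schedule))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    rk <- rank_features(m[tr, , drop = FALSE], y[tr], method = ranker,
                        seed = seed, step_fraction = step_fraction,
                        n_trees = n_trees)
    for (j in seq_along(schedule)) {
      ids <- rk$feature_id[seq_len(schedule[j])]
      fit <- fit_classifier(model, m[tr, ids, drop = FALSE], y[tr])
      p <- predict_proba(fit, m[!tr, ids, drop = FALSE])
      cm <- confusion(classify(p, 0.5), y[!tr])
      f1[f, j] <- classification_metrics(cm)$f1
    }
  }
  mean_f1 <- colMeans(f1)
  # best mean F1; ties resolved toward the smaller feature count
  best <- which(mean_f1 == max(mean_f1))
  chosen_k <- min(schedule[best])
  list(chosen_k = chosen_k,
       cv_trace = tibble(k = schedule, mean_f1 = mean_f1))
}

new_selection_result <- function(selected_ids, plan, chosen_k, cv_trace,
                                 per_fold_sets = NULL, ranking = NULL,
                                 fallback = FALSE) {
  structure(list(selected_ids = selected_ids, plan = plan,
                 chosen_k = chosen_k, cv_trace = cv_trace,
                 per_fold_sets = per_fold_sets, ranking = ranking,
                 fallback = fallback),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("# selection_result [plan %s]: %d features (chosen k = %d)%s\n",
              x$plan, length(x$selected_ids), x$chosen_k,
              if (isTRUE(x$fallback)) " [majority-of-folds fallback]" else ""))
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  if (!is.null(x$ranking)) {
    out <- as_tibble(x$ranking)
    out$selected <- out$feature_id %in% x$selected_ids
    return(out)
  }
  tibble(feature_id = x$selected_ids, selected = TRUE)
}

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(plan = x$plan, n_selected = length(x$selected_ids),
         chosen_k = x$chosen_k, best_cv_f1 = max(x$cv_trace$mean_f1),
         fallback = isTRUE(x$fallback))
}

#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot(object$cv_trace, aes(x = .data$k, y = .data$mean_f1)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    labs(x = "candidate feature count k (log scale)",
         y = "mean validation F1",
         title = sprintf("Plan %s feature-count search (chosen k = %d)",
                         object$plan, object$chosen_k)) +
    theme_minimal()
}

#' Plan B feature selection: single cross-validated feature-count search
#'
#' One stratified five-fold cross-validation over the training set: for
#' every candidate feature count k in the schedule, features are ranked on
#' each fold's training block, the top k are kept, and the model's F1 on
#' the fold's validation block is recorded. The chosen k maximises mean
#' validation F1 (ties toward smaller k); the final set is the top-k of
#' the ranking computed on the full training set.
#'
#' @param x Training feature matrix / table (normalized).
#' @param y Binary labels.
#' @param ranker Ranking method tag (see [rank_features()]).
#' @param n_folds Number of folds (default 5).
#' @param schedule Candidate k values, e.g. [k_schedule()]; defaults to the
#'   full schedule over all features.
#' @param model A [classifier_spec()] used to score candidate subsets (the
#'   same family later used for classification).
#' @param seed Fold/ranker seed.
#' @return A `selection_result` with `selected_ids`, `chosen_k`,
#'   `cv_trace`, and the full-training `ranking`.
#' @export
select_plan_b <- function(x, y, ranker = "chi2", n_folds = 5L,
                          schedule = NULL,
                          model = classifier_spec("svm_rbf"), seed = 1L) {
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  if (n_folds < 2) abort("n_folds must be >= 2")
  if (is.null(schedule)) schedule <- k_schedule(ncol(m))
  if (any(schedule < 1 | schedule > ncol(m))) {
    abort("schedule values must lie in [1, n_features]")
  }
  search <- cv_k_search(m, y, ranker, n_folds, schedule, model, seed)
  full_rank <- rank_features(m, y, method = ranker, seed = seed)
  selected <- full_rank$feature_id[seq_len(search$chosen_k)]
  new_selection_result(selected, "B", search$chosen_k, search$cv_trace,
                       ranking = full_rank)
}

#' Plan A feature selection: nested cross-validation with intersection
#'
#' A 5-by-5 nested cross-validation. For each outer training split, an
#' inner cross-validated feature-count search (as in [select_plan_b()])
#' picks the optimal k; the features are then ranked on the whole outer
#' training split and its top k form that fold's set. The final set is the
#' intersection of the per-outer-fold sets. If the intersection is empty, a
#' flagged fallback keeps features present in at least `n_outer - 1` sets.
#'
#' @param x,y Training data.
#' @param ranker Ranking method tag.
#' @param n_outer,n_inner Outer and inner fold counts (default 5 each).
#' @param schedule Candidate k values (defaults to the full schedule).
#' @param model A [classifier_spec()] used to score candidate subsets.
#' @param seed Base seed; outer folds use `seed`, the inner search of outer
#'   fold f uses `seed + f`.
#' @return A `selection_result` with `per_fold_sets` retained; `chosen_k`
#'   reports the size of the final set.
#' @export
select_plan_a <- function(x, y, ranker = "chi2", n_outer = 5L, n_inner = 5L,
                          schedule = NULL,
                          model = classifier_spec("svm_rbf"), seed = 1L) {
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  if (n_outer < 2 || n_inner < 2) abort("fold counts must be >= 2")
  if (is.null(schedule)) schedule <- k_schedule(ncol(m))
  outer_fold <- stratified_folds(y, n_outer, seed)
  per_fold_sets <- vector("list", n_outer)
  traces <- vector("list", n_outer)
  for (f in seq_len(n_outer)) {
    tr <- outer_fold != f
    inner_schedule <- schedule[schedule <= sum(tr)]
    search <- cv_k_search(m[tr, , drop = FALSE], y[tr], ranker, n_inner,
                          inner_schedule, model, seed + f)
    rk <- rank_features(m[tr, , drop = FALSE], y[tr], method = ranker,
                        seed = seed + f)
    per_fold_sets[[f]] <- rk$feature_id[seq_len(search$chosen_k)]
    traces[[f]] <- dplyr::mutate(search$cv_trace, outer_fold = f)
  }
  final <- Reduce(intersect, per_fold_sets)
  fallback <- FALSE
  if (length(final) == 0) {
    warn("empty intersection across outer folds; falling back to features present in >= n_outer - 1 sets")
    fallback <- TRUE
    tally <- table(unlist(lapply(per_fold_sets, unique)))
    final <- names(tally)[tally >= n_outer - 1]
  }
  trace <- dplyr::bind_rows(traces) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_f1 = mean(.data$mean_f1), .groups = "drop")
  new_selection_result(final, "A", length(final), trace,
                       per_fold_sets = per_fold_sets, fallback = fallback)
}

#' Serialize a selection result to TSV
#'
#' Columns: `feature_id`, `score` (when a ranking is available),
#' `modality` (when provided), `in_final_set`.
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @param modality_of Optional named character vector mapping feature IDs
#'   to modalities.
#' @export
write_selection <- function(result, path, modality_of = NULL) {
  t <- tidy(result)
  names(t)[names(t) == "selected"] <- "in_final_set"
  if (!is.null(modality_of)) t$modality <- unname(modality_of[t$feature_id])
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
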