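#' Rank features by a selection method
#'
#' Dispatches to the chi-square filter, recursive feature elimination (RFE)
#' with a linear model's weights, or random-forest impurity importance.
#'
#' @param x Feature matrix / `omics_tbl` (non-negative, normalized for
#'   `chi2`).
#' @param y Binary labels (vector or label tibble).
#' @param method One of `"chi2"`, `"rfe_lr"`, `"rfe_svm"`, `"rfe_rfc"`,
#'   `"rfc_importance"`.
#' @param seed Seed for the stochastic rankers (forests).
#' @param step_fraction Fraction of remaining features removed per RFE
#'   round.
#' @param n_trees Forest size for `rfc_importance` and `rfe_rfc`.
#' @return A `feature_ranking` tibble: `feature_id`, `score`, `rank`,
#'   best first; attribute `method`. Score ties are broken by feature-ID
#'   lexicographic order so rankings are deterministic.
#' @export
rank_features <- function(x, y,
                          method = c("chi2", "rfe_lr", "rfe_svm", "rfe_rfc",
                                     "rfc_importance"),
                          seed = 1L, step_fraction = 0.1, n_trees = 100L) {
  method <- match.arg(method)
  if (is.data.frame(y)) y <- y$label
  switch(method,
    chi2 = new_feature_ranking(chi2_scores(x, y), "chi2"),
    rfc_importance = rfc_importance_rank(x, y, n_trees = n_trees, seed = seed),
    rfe_lr = rfe_rank(x, y, classifier_spec("logistic_regression", seed = seed),
                      step_fraction),
    rfe_svm = rfe_rank(x, y, classifier_spec("svm_linear", seed = seed),
                       step_fraction),
    rfe_rfc = rfe_rank(x, y, classifier_spec("random_forest", seed = seed,
                                             hyperparameters = list(n_trees = n_trees)),
                       step_fraction)
  )
}

# Order scores best-first with lexicographic feature-ID tie-break.
new_feature_ranking <- function(scores, method) {
  ord <- order(-scores, names(scores), method = "radix")
  structure(
    tibble(feature_id = names(scores)[ord],
           score = unname(scores[ord]),
           rank = seq_along(scores)),
    method = method,
    class = c("feature_ranking", class(tibble()))
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("# feature_ranking [%s]: %d features\n",
              attr(x, "method"), nrow(x)))
  NextMethod()
}

#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, top_n = 30, ...) {
  d <- head(object, top_n)
  ggplot(d, aes(x = .data$score,
                y = stats::reorder(.data$feature_id, .data$score))) +
    geom_col() +
    labs(x = "importance score", y = NULL,
         title = sprintf("Top %d features (%s)", nrow(d), attr(object, "method"))) +
    theme_minimal()
}

#' Recursive feature elimination ranking
#'
#' Repeatedly fits `base_model`, reads its per-feature weights (absolute
#' linear coefficients, or forest importances), and removes the
#' lowest-weight `step_fraction` of the remaining features (at least one)
#' until a single feature is left. The ranking is the reverse of the
#' elimination order: the survivor ranks first. Scores are the elimination
#' round survived (higher = retained longer).
#'
#' @param x Feature matrix / table.
#' @param y Binary labels.
#' @param base_model A [classifier_spec()] exposing feature weights
#'   (`logistic_regression`, `svm_linear`, `random_forest`,
#'   `gradient_boosted_trees`); an rbf SVM has no per-feature weights and
#'   is rejected.
#' @param step_fraction Fraction of remaining features dropped per round.
#' @return A `feature_ranking` tibble.
#' @export
rfe_rank <- function(x, y, base_model, step_fraction = 0.1) {
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  if (base_model$family == "svm_rbf") {
    abort("rbf SVM exposes no per-feature weights; use svm_linear for RFE")
  }
  remaining <- colnames(m)
  round <- 0L
  elim_round <- setNames(numeric(ncol(m)), colnames(m))
  while (length(remaining) > 1) {
    round <- round + 1L
    fitted <- fit_classifier(base_model, m[, remaining, drop = FALSE], y)
    w <- feature_weights(fitted)
    # drop the weakest slice this round; among tied weights the
    # lexicographically later ID is dropped first, so earlier IDs rank better
    n_drop <- max(1L, floor(step_fraction * length(remaining)))
    by_name_desc <- order(names(w), decreasing = TRUE, method = "radix")
    ord <- by_name_desc[order(w[by_name_desc], method = "radix")]  # stable
    drop <- names(w)[ord][seq_len(n_drop)]
    elim_round[drop] <- round
    remaining <- setdiff(remaining, drop)
  }
  elim_round[remaining] <- round + 1L
  new_feature_ranking(elim_round, paste0("rfe_", sub("_.*", "", base_model$family)))
}

#' Random-forest impurity importance ranking
#'
#' @param x Feature matrix / table.
#' @param y Binary labels.
#' @param n_trees Number of trees (>= 1).
#' @param seed Seed; rankings are reproducible under a fixed seed.
#' @return A `feature_ranking` tibble.
#' @export
rfc_importance_rank <- function(x, y, n_trees = 100L, seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  restore <- local_seed(as.integer(seed))
  on.exit(restore(), add = TRUE)
  fit <- randomForest::randomForest(m, factor(y, levels = c(0, 1)),
                                    ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  new_feature_ranking(setNames(as.numeric(imp), rownames(fit$importance)),
                      "rfc_importance")
}

#' Candidate feature-count schedule
#'
#' The search grid for the number of features to keep: starts at all
#' features and shrinks by 10% (floor, with a floor of 1) each step until
#' it reaches 1. Strictly decreasing, duplicate-free.
#'
#' @param p_total Total number of features (>= 1).
#' @param shrink Per-step multiplier (default 0.9, i.e. a 10% reduction).
#' @return Integer vector `p_total, floor(0.9 p_total), ..., 1`.
#' @export
k_schedule <- function(p_total, shrink = 0.9) {
  stopifnot(p_total >= 1)
  ks <- integer(0)
  k <- as.integer(p_total)
  while (TRUE) {
    ks <- c(ks, k)
    if (k == 1L) break
    nxt <- max(1L, as.integer(floor(shrink * k)))
    if (nxt >= k) nxt <- k - 1L
    k <- nxt
  }
  ks
}

#' Select features whose rescaled importance clears a floor
#'
#' Scores are rescaled to `[0, 1]` by dividing by the maximum score; the
#' features with rescaled importance >= `importance_floor` are returned
#' (e.g. a floor of 0.95 picks the handful of near-top features).
#'
#' @param ranking A `feature_ranking`.
#' @param importance_floor Threshold on the rescaled score, in `[0, 1]`.
#' @return Character vector of selected feature IDs (best first).
#' @export
threshold_select <- function(ranking, importance_floor) {
  if (max(ranking$score) <= 0) {
    warn("all scores are zero; nothing selected")
    return(character(0))
  }
  rescaled <- ranking$score / max(ranking$score)
  ranking$feature_id[rescaled >= importance_floor]
}
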