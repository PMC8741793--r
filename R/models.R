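#' Specify a classifier family
#'
#' Uniform handle over the model families used in the pipeline: logistic
#' regression (ridge-penalised, mirroring the common library default),
#' SVM with linear or rbf kernel (with probability outputs), random
#' forest, and gradient-boosted trees.
#'
#' @param family One of `"logistic_regression"`, `"svm_linear"`,
#'   `"svm_rbf"`, `"random_forest"`, `"gradient_boosted_trees"`.
#' @param hyperparameters Named list of overrides. Recognised keys:
#'   `cost` (SVMs, default 1), `gamma` (rbf, default 1/p), `n_trees`
#'   (forest, default 100), `nrounds`, `max_depth`, `eta` (boosting,
#'   defaults 100 / 6 / 0.3), `lambda` (ridge logistic, default 1/n).
#' @param seed Integer seed used by the stochastic families (and by SVM
#'   probability calibration) so fits are reproducible.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("logistic_regression", "svm_linear",
                                       "svm_rbf", "random_forest",
                                       "gradient_boosted_trees"),
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Training feature matrix / table, normalized to `[0, 1]`
#'   upstream.
#' @param y Binary labels (0/1 vector or label tibble), both classes
#'   present.
#' @param threshold Probability cutoff stored with the model (see
#'   [classify()]); default 0.5.
#' @return A `trained_classifier`: `spec`, opaque `fit`, the exact ordered
#'   `feature_ids` it was trained on, and `threshold`.
#' @export
fit_classifier <- function(spec, x, y, threshold = 0.5) {
  stopifnot(inherits(spec, "classifier_spec"))
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")

  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  yf <- factor(y, levels = c(0, 1))

  fit <- switch(spec$family,
    logistic_regression = {
      lam <- hp(spec, "lambda", 1 / nrow(m))
      xx <- if (ncol(m) == 1L) cbind(m, `.__pad` = 0) else m
      glmnet::glmnet(xx, yf, family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    },
    svm_linear = e1071::svm(m, yf, kernel = "linear",
                            cost = hp(spec, "cost", 1),
                            probability = TRUE, scale = FALSE),
    svm_rbf = e1071::svm(m, yf, kernel = "radial",
                         cost = hp(spec, "cost", 1),
                         gamma = hp(spec, "gamma", 1 / ncol(m)),
                         probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(m, yf,
                                               ntree = hp(spec, "n_trees", 100L)),
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(m, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp(spec, "max_depth", 6L),
                      eta = hp(spec, "eta", 0.3),
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp(spec, "nrounds", 100L), verbose = 0)
    },
    abort(paste0("unknown model family: ", spec$family))
  )
  structure(list(spec = spec, fit = fit,
                 feature_ids = colnames(m), threshold = threshold),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("# trained_classifier [%s]: %d features, threshold %.2f\n",
              x$spec$family, length(x$feature_ids), x$threshold))
  invisible(x)
}

#' @method glance trained_classifier
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble(family = x$spec$family, n_features = length(x$feature_ids),
         threshold = x$threshold, seed = x$spec$seed)
}

#' Predicted case probabilities
#'
#' @param model A `trained_classifier`.
#' @param x Feature matrix / table whose columns match the model's
#'   `feature_ids` exactly (same order).
#' @return Numeric vector of class-1 (case) probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, x) {
  m <- as_feature_matrix(x)
  if (!identical(colnames(m), model$feature_ids)) {
    mism <- which(colnames(m) != model$feature_ids |
                    is.na(colnames(m)) | is.na(model$feature_ids))
    first <- if (length(colnames(m)) != length(model$feature_ids)) {
      "feature count differs"
    } else {
      sprintf("first mismatch at position %d: got '%s', expected '%s'",
              mism[1], colnames(m)[mism[1]], model$feature_ids[mism[1]])
    }
    abort(paste0("feature columns do not match the trained model; ", first))
  }
  p <- switch(model$spec$family,
    logistic_regression = {
      xx <- if (ncol(m) == 1L) cbind(m, `.__pad` = 0) else m
      as.numeric(predict(model$fit, xx, type = "response"))
    },
    svm_linear = ,
    svm_rbf = {
      pr <- predict(model$fit, m, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    random_forest = as.numeric(predict(model$fit, m, type = "prob")[, "1"]),
    gradient_boosted_trees =
      as.numeric(predict(model$fit, xgboost::xgb.DMatrix(m, nthread = 1)))
  )
  pmin(pmax(p, 0), 1)
}

# Per-feature weights for RFE: absolute linear coefficients or tree
# importances, named by feature.
feature_weights <- function(model) {
  ids <- model$feature_ids
  w <- switch(model$spec$family,
    logistic_regression = {
      cf <- as.numeric(glmnet::coef.glmnet(model$fit))[-1]  # drop intercept
      abs(cf)[seq_along(ids)]
    },
    svm_linear = {
      wv <- crossprod(model$fit$coefs, model$fit$SV)
      abs(as.numeric(wv))
    },
    random_forest = as.numeric(model$fit$importance[ids, "MeanDecreaseGini"]),
    gradient_boosted_trees = {
      imp <- xgboost::xgb.importance(model = model$fit)
      out <- setNames(rep(0, length(ids)), ids)
      out[imp$Feature] <- imp$Gain
      as.numeric(out)
    },
    abort(paste0("no per-feature weights for family: ", model$spec$family))
  )
  setNames(w, ids)
}

#' Threshold predicted probabilities into class labels
#'
#' A sample is called a case (1) iff its predicted probability is strictly
#' greater than the cutoff `p_t`.
#'
#' @param probabilities Numeric vector of case probabilities.
#' @param p_t Probability threshold in (0, 1); default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities, p_t = 0.5) {
  if (p_t <= 0 || p_t >= 1) abort("p_t must be in (0, 1)")
  as.integer(probabilities > p_t)
}

#' Tune the probability threshold by cross-validation
#'
#' For each candidate cutoff, fits the model on each training fold and
#' scores F1 on the corresponding validation fold; the chosen cutoff
#' maximises the mean validation F1 (ties resolved toward 0.5, then toward
#' the smaller value).
#'
#' @param spec A [classifier_spec()].
#' @param x,y Training data (matrix/table and binary labels).
#' @param grid Candidate thresholds in (0, 1); default `seq(0.1, 0.9, 0.1)`.
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `best_p_t` and `trace`, a tibble (`p_t`, `mean_f1`).
#' @export
tune_threshold <- function(spec, x, y, grid = seq(0.1, 0.9, by = 0.1),
                           n_folds = 5L, seed = 1L) {
  if (length(grid) == 0) abort("threshold grid is empty")
  if (any(grid <= 0 | grid >= 1)) abort("grid values must lie in (0, 1)")
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  fold <- stratified_folds(y, n_folds, seed)
  f1s <- matrix(NA_real_, nrow = n_folds, ncol = length(grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- fit_classifier(spec, m[tr, , drop = FALSE], y[tr])
    p <- predict_proba(fit, m[!tr, , drop = FALSE])
    for (j in seq_along(grid)) {
      cm <- confusion(classify(p, grid[j]), y[!tr])
      f1s[f, j] <- classification_metrics(cm)$f1
    }
  }
  mean_f1 <- colMeans(f1s)
  best <- which(mean_f1 == max(mean_f1))
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1]
  list(best_p_t = grid[best],
       trace = tibble(p_t = grid, mean_f1 = mean_f1))
}

#' Save or load a trained classifier
#'
#' The artifact embeds a format version and the ordered feature manifest;
#' [predict_proba()] refuses prediction when columns do not match it.
#'
#' @param model A `trained_classifier`.
#' @param path File path for the artifact.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the `trained_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  saveRDS(list(format = "adclassify_model_v1", model = model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adclassify_model_v1")) {
    abort("not an adclassify model artifact")
  }
  obj$model
}
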