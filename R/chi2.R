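#' Chi-square feature scores for a binary classification task
#'
#' Filter-type feature importance computed from its matrix definition.
#' The binary label vector y is expanded to a one-hot (n, 2) indicator Y
#' (first column = class 1, second = class 0). Then, with X the
#' non-negative (n, p) data matrix:
#'
#' * observed class mass per feature:  f_obs = t(Y) %*% X              (2, p)
#' * feature_count = column sums of X                                  (1, p)
#' * class_prob    = column means of Y                                 (1, 2)
#' * expected mass: f_exp = t(class_prob) %*% feature_count            (2, p)
#' * score_j = sum over the two classes of (f_obs - f_exp)^2 / f_exp
#'
#' Higher scores mean the feature's mass is distributed more unevenly
#' between cases and controls, i.e. higher importance. A feature with zero
#' total mass scores 0 by convention. Input must be non-negative — run
#' [min_max_normalize()] upstream — because the statistic treats values as
#' counts/mass.
#'
#' @param x Non-negative numeric matrix, `omics_tbl`, or data frame with
#'   `sample_id` (samples in rows).
#' @param y Binary label vector (0/1), or a label tibble with a `label`
#'   column, length = number of rows of `x`.
#' @return Named numeric vector of non-negative scores, one per feature, in
#'   the input feature order.
#' @export
chi2_scores <- function(x, y) {
  m <- as_feature_matrix(x)
  if (is.data.frame(y)) y <- y$label
  y <- as.integer(y)
  if (length(y) != nrow(m)) abort("y length must equal the number of samples")
  if (length(unique(y)) < 2) abort("chi-square scores need both classes present")
  if (any(m < 0)) abort("chi-square scores are undefined for negative values")

  Y <- cbind(case = as.numeric(y == 1L), control = as.numeric(y == 0L))
  f_obs <- crossprod(Y, m)                       # (2, p)
  feature_count <- colSums(m)                    # (p)
  class_prob <- colMeans(Y)                      # (2)
  f_exp <- outer(class_prob, feature_count)      # (2, p)
  dev <- (f_obs - f_exp)^2
  ratio <- ifelse(f_exp > 0, dev / f_exp, 0)     # zero-mass features score 0
  scores <- colSums(ratio)
  names(scores) <- colnames(m)
  scores
}
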