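#' Stratified train/test split
#'
#' Splits a labelled cohort so the case:control balance of the test set
#' matches the whole cohort: each class contributes its largest-remainder
#' share of `test_size` (round `test_size * class_count / n`, adjusted by
#' one where needed so the test set size is hit exactly). Sampling within
#' class is uniform and fully determined by `seed`.
#'
#' @param labels Label tibble (`sample_id`, `label`) from [label_vector()].
#' @param test_size Number of test samples, `0 < test_size < n`.
#' @param seed Integer seed.
#' @return A `split_indices` list: `train_ids`, `test_ids`, `seed`.
#' @export
stratified_split <- function(labels, test_size, seed = 1L) {
  y <- labels$label
  n <- length(y)
  if (test_size <= 0 || test_size >= n) abort("test_size must be in (0, n)")
  if (length(unique(y)) < 2) abort("both classes must be present")

  counts <- c(`1` = sum(y == 1L), `0` = sum(y == 0L))
  exact <- test_size * counts / n
  take <- floor(exact)
  rem <- exact - take
  short <- test_size - sum(take)
  if (short > 0) {
    take[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      take[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  for (cls in names(take)) {
    if (take[cls] == 0) {
      warn(sprintf("class %s would get 0 test samples; forcing 1", cls))
      take[cls] <- 1
      other <- setdiff(names(take), cls)
      take[other] <- take[other] - 1
    }
  }

  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  test_ids <- character(0)
  for (cls in c("1", "0")) {
    ids_cls <- labels$sample_id[y == as.integer(cls)]
    test_ids <- c(test_ids, sample(ids_cls, take[[cls]]))
  }
  test_ids <- labels$sample_id[labels$sample_id %in% test_ids]
  train_ids <- setdiff(labels$sample_id, test_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("# split_indices: %d train / %d test (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' @method tidy split_indices
#' @export
tidy.split_indices <- function(x, ...) {
  tibble(sample_id = c(x$train_ids, x$test_ids),
         partition = rep(c("train", "test"),
                         c(length(x$train_ids), length(x$test_ids))))
}

#' Serialize split indices to a two-column TSV
#' @param split A `split_indices` object.
#' @param path Output path.
#' @export
write_split <- function(split, path) {
  utils::write.table(as.data.frame(tidy(split)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Stratified k-fold assignment: per class, shuffle then deal round-robin.
# Returns an integer fold id per sample, deterministic under seed.
stratified_folds <- function(y, k, seed) {
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Min-max normalization to the unit interval
#'
#' Per feature (column), x' = (x - min(x)) / (max(x) - min(x)), so that the
#' column minimum maps to 0 and the maximum to 1. The scaled data stay
#' non-negative, which the chi-square scorer requires. Constant columns
#' (max = min) map to 0 everywhere by convention.
#'
#' @param x Numeric matrix, `omics_tbl`, or data frame with `sample_id`.
#' @return Same shape as the input (matrix in, matrix out; table in,
#'   table out).
#' @export
min_max_normalize <- function(x) {
  if (!is.matrix(x)) {
    mod <- attr(x, "modality")
    m <- min_max_normalize(as_feature_matrix(x))
    out <- dplyr::bind_cols(tibble(sample_id = rownames(m)),
                            as_tibble(m, .name_repair = "minimal"))
    if (!is.null(mod)) return(omics_table(out, mod))
    return(out)
  }
  if (!all(is.finite(x))) abort("min_max_normalize requires finite input")
  rng <- fit_minmax(x)
  apply_minmax(x, rng)
}

# Fitted min/max per column, reusable on held-out data (train-only scope).
fit_minmax <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

apply_minmax <- function(x, rng) {
  span <- rng$max - rng$min
  out <- sweep(x, 2, rng$min, `-`)
  out <- sweep(out, 2, ifelse(span == 0, 1, span), `/`)
  out[, span == 0] <- 0
  out
}

#' Mean imputation of flagged samples
#'
#' Replaces each flagged sample's row by the per-feature mean over the
#' non-flagged rows — the standard treatment when values are assumed
#' missing completely at random (MCAR). Used to fill the microbiota
#' placeholder rows created by [align_modalities()].
#'
#' @param table An `omics_tbl`.
#' @param missing_samples Character vector of flagged sample IDs (subset of
#'   the table's samples).
#' @return The table with flagged rows replaced.
#' @export
mean_impute <- function(table, missing_samples) {
  m <- as_feature_matrix(table)
  if (!all(missing_samples %in% rownames(m))) {
    abort("missing_samples must be a subset of the table's sample IDs")
  }
  if (length(missing_samples) == 0) return(table)
  keep <- setdiff(rownames(m), missing_samples)
  if (length(keep) == 0) abort("cannot impute: every sample is flagged")
  mu <- colMeans(m[keep, , drop = FALSE])
  m[missing_samples, ] <- matrix(mu, nrow = length(missing_samples),
                                 ncol = ncol(m), byrow = TRUE)
  matrix_to_omics(m, modality(table))
}

#' Add Gaussian jitter to a training matrix
#'
#' Adds i.i.d. zero-mean Gaussian noise s ~ N(0, sigma^2 I) with sigma^2 = 1,
#' where `intensity` (I) sets the noise scale. Jittering is a regulariser
#' against overfitting; in this pipeline it is applied only to the training
#' transcriptome block, never to the zero-heavy microbiota data.
#'
#' The notation N(0, sigma^2 I) is read as variance = I (so sd = sqrt(I))
#' under the default `variance_equals_I` convention; `sd_equals_I` selects
#' the alternative reading.
#'
#' @param x Numeric matrix (normalized training transcriptome block).
#' @param intensity Noise intensity I >= 0; 0 returns the input unchanged.
#' @param seed Integer seed; fixed seed gives identical noise.
#' @param variance_convention `"variance_equals_I"` (default) or
#'   `"sd_equals_I"`.
#' @return Matrix of the same shape.
#' @export
add_jitter <- function(x, intensity, seed = 21L,
                       variance_convention = c("variance_equals_I", "sd_equals_I")) {
  variance_convention <- match.arg(variance_convention)
  if (intensity < 0) abort("jitter intensity must be >= 0")
  if (intensity == 0) return(x)
  sd <- if (variance_convention == "variance_equals_I") sqrt(intensity) else intensity
  restore <- local_seed(as.integer(seed))
  on.exit(restore(), add = TRUE)
  x + matrix(rnorm(length(x), sd = sd), nrow = nrow(x))
}
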