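# Shared fixture builders. Everything is generated in code at test time;
# no data files ship with the tests.

# Small labelled matrix with named dimensions.
toy_matrix <- function(n, p, seed = 1, prefix = "f") {
  set.seed(seed)
  matrix(runif(n * p), n, p,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         sprintf("%s%02d", prefix, seq_len(p))))
}

# Linearly separable two-feature toy: class 1 sits in the upper-right corner.
separable_toy <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  x1 <- cbind(runif(n_per_class, 0.7, 1), runif(n_per_class, 0.7, 1))
  x0 <- cbind(runif(n_per_class, 0, 0.3), runif(n_per_class, 0, 0.3))
  x <- rbind(x1, x0)
  dimnames(x) <- list(sprintf("s%02d", seq_len(2 * n_per_class)), c("fa", "fb"))
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}

# Small synthetic cohort for pipeline tests.
small_cohort_config <- function(seed = 7, ...) {
  args <- modifyList(list(
    n_cases = 22, n_controls = 18, n_probes = 60, n_taxa = 15,
    n_signal_probes = 5, n_signal_taxa = 4, probe_effect = 1.5,
    taxa_effect = 4, zero_inflation = 0.5,
    missing_transcriptome = 1, missing_microbiota = 1, seed = seed
  ), list(...))
  do.call(synthetic_config, args)
}

# Independent brute-force oracle for the chi-square scores: per feature, a
# two-cell goodness-of-fit statistic on the (class x feature-mass) table.
chi2_oracle <- function(x, y) {
  vapply(seq_len(ncol(x)), function(j) {
    obs <- c(sum(x[y == 1, j]), sum(x[y == 0, j]))
    if (sum(obs) == 0) return(0)
    suppressWarnings(
      unname(stats::chisq.test(obs, p = c(mean(y == 1), mean(y == 0)))$statistic)
    )
  }, numeric(1))
}

# Independent AUC oracle: probability a random case outranks a random
# control, ties counted one half.
auc_oracle <- function(probs, truth) {
  ca <- probs[truth == 1]
  co <- probs[truth == 0]
  mean(outer(ca, co, ">") + 0.5 * outer(ca, co, "=="))
}
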