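#' Configuration for the synthetic paired-omics cohort generator
#'
#' Defaults emulate the study cohort this pipeline targets: 161 children
#' (88 atopic-dermatitis cases, 73 controls) profiled on 44,608 expression
#' probes and 366 phylum/genus taxa, with one sample missing each modality.
#' Signal sizes default to the 35 predictive probes and 50 predictive taxa
#' the classification workflow selects.
#'
#' @param n_cases,n_controls Class sizes of the labelled cohort.
#' @param n_probes,n_taxa Feature counts per modality.
#' @param n_signal_probes,n_signal_taxa Numbers of planted differential
#'   features.
#' @param probe_effect Standardised mean shift (Cohen's d, log-intensity
#'   scale) of signal probes between cases and controls.
#' @param taxa_effect Multiplicative case/control fold-change in mean
#'   relative abundance of signal taxa.
#' @param zero_inflation Probability that a taxon cell is structurally zero
#'   (in `[0, 1)`).
#' @param missing_transcriptome Number of extra microbiota-only samples
#'   (they carry labels but no transcriptome row, and are dropped at
#'   alignment).
#' @param missing_microbiota Number of labelled samples whose microbiota row
#'   is withheld (flagged for mean imputation at alignment).
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 88, n_controls = 73,
                             n_probes = 44608, n_taxa = 366,
                             n_signal_probes = 35, n_signal_taxa = 50,
                             probe_effect = 1.0, taxa_effect = 3.0,
                             zero_inflation = 0.7,
                             missing_transcriptome = 1,
                             missing_microbiota = 1,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_probes = as.integer(n_probes), n_taxa = as.integer(n_taxa),
              n_signal_probes = as.integer(n_signal_probes),
              n_signal_taxa = as.integer(n_signal_taxa),
              probe_effect = probe_effect, taxa_effect = taxa_effect,
              zero_inflation = zero_inflation,
              missing_transcriptome = as.integer(missing_transcriptome),
              missing_microbiota = as.integer(missing_microbiota),
              seed = as.integer(seed))
  counts <- cfg[c("n_cases", "n_controls", "n_probes", "n_taxa",
                  "n_signal_probes", "n_signal_taxa",
                  "missing_transcriptome", "missing_microbiota")]
  if (any(unlist(counts) < 0)) abort("counts must be >= 0")
  if (cfg$n_signal_probes > cfg$n_probes) {
    abort("n_signal_probes exceeds n_probes")
  }
  if (cfg$n_signal_taxa > cfg$n_taxa) abort("n_signal_taxa exceeds n_taxa")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1) {
    abort("zero_inflation must be in [0, 1)")
  }
  if (cfg$probe_effect < 0) abort("probe_effect must be >= 0")
  if (cfg$missing_microbiota > cfg$n_cases + cfg$n_controls) {
    abort("missing_microbiota exceeds cohort size")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic paired transcriptome/microbiota cohort
#'
#' Transcriptome intensities are per-probe Gaussian on the log scale and
#' exponentiated, so downstream min-max normalization sees skewed positive
#' data; planted probes differ between classes by `probe_effect` standard
#' deviations of the log intensity. Microbiota rows are Dirichlet-style
#' relative abundances (per-taxon gamma draws normalised to sum to one per
#' sample) with an independent Bernoulli zero mask applied afterwards;
#' planted taxa have a case/control concentration ratio of `taxa_effect`.
#'
#' The ground-truth signal feature IDs are returned so tests can measure
#' recovery; the classification pipeline itself never reads them.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list: `transcriptome`, `microbiota`
#'   (`omics_tbl`), `labels` (tibble), and `ground_truth` (list with
#'   `signal_probes`, `signal_taxa`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_lab <- cfg$n_cases + cfg$n_controls
  n_all <- n_lab + cfg$missing_transcriptome
  old <- local_seed(cfg$seed)
  on.exit(old(), add = TRUE)

  ids <- sprintf("S%03d", seq_len(n_all))
  y_all <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  # microbiota-only extras alternate classes so they carry plausible labels
  y_extra <- rep_len(c(1L, 0L), cfg$missing_transcriptome)
  labels_all <- c(y_all, if (cfg$missing_transcriptome > 0) y_extra)

  probe_ids <- sprintf("probe_%05d", seq_len(cfg$n_probes))
  taxon_ids <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  signal_probes <- probe_ids[seq_len(cfg$n_signal_probes)]
  signal_taxa <- taxon_ids[seq_len(cfg$n_signal_taxa)]

  ## transcriptome: labelled samples only (extras are microbiota-only)
  mu <- rnorm(cfg$n_probes, mean = 6, sd = 1)        # log-scale probe means
  sigma <- runif(cfg$n_probes, 0.3, 0.8)             # log-scale probe sds
  logx <- matrix(rnorm(n_lab * cfg$n_probes), nrow = n_lab)
  logx <- sweep(logx, 2, sigma, `*`)
  logx <- sweep(logx, 2, mu, `+`)
  if (cfg$n_signal_probes > 0) {
    shift <- matrix(0, n_lab, cfg$n_signal_probes)
    shift[y_all == 1L, ] <- 1
    shift <- sweep(shift, 2, cfg$probe_effect * sigma[seq_len(cfg$n_signal_probes)], `*`)
    logx[, seq_len(cfg$n_signal_probes)] <- logx[, seq_len(cfg$n_signal_probes)] + shift
  }
  tmat <- exp(logx)
  dimnames(tmat) <- list(ids[seq_len(n_lab)], probe_ids)

  ## microbiota: all samples except `missing_microbiota` labelled ones
  alpha <- rlnorm(cfg$n_taxa, meanlog = -1, sdlog = 1)
  g <- matrix(rgamma(n_all * cfg$n_taxa,
                     shape = rep(alpha, each = n_all), rate = 1),
              nrow = n_all)
  if (cfg$n_signal_taxa > 0 && cfg$taxa_effect != 1) {
    case_rows <- labels_all == 1L
    g[case_rows, seq_len(cfg$n_signal_taxa)] <-
      g[case_rows, seq_len(cfg$n_signal_taxa)] * cfg$taxa_effect
  }
  rs <- rowSums(g)
  rs[rs == 0] <- 1
  mmat <- g / rs
  if (cfg$zero_inflation > 0) {
    mask <- matrix(runif(n_all * cfg$n_taxa) < cfg$zero_inflation, nrow = n_all)
    mmat[mask] <- 0
  }
  dimnames(mmat) <- list(ids, taxon_ids)
  if (cfg$missing_microbiota > 0) {
    # withhold the last labelled samples' microbiota rows
    drop_ids <- ids[seq.int(n_lab - cfg$missing_microbiota + 1L, n_lab)]
    mmat <- mmat[setdiff(ids, drop_ids), , drop = FALSE]
  }

  structure(
    list(
      transcriptome = omics_table(tmat, "transcriptome"),
      microbiota = omics_table(mmat, "microbiota"),
      labels = label_vector(ids, labels_all),
      ground_truth = list(signal_probes = signal_probes,
                          signal_taxa = signal_taxa)
    ),
    config = cfg,
    class = "synthetic_cohort"
  )
}

# Seed the RNG locally and return a restorer, so generation never disturbs
# the caller's random stream.
local_seed <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits the three tab-separated tables read by [read_feature_table()] /
#' [read_labels()] plus a ground-truth ID list (one feature ID per line).
#' Round-trips exactly and is byte-identical across calls for a fixed
#' config + seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    transcriptome = file.path(dir, "transcriptome.tsv"),
    microbiota = file.path(dir, "microbiota.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ground_truth = file.path(dir, "ground_truth.txt")
  )
  write_feature_table(cohort$transcriptome, paths[["transcriptome"]])
  write_feature_table(cohort$microbiota, paths[["microbiota"]])
  write_labels(cohort$labels, paths[["labels"]])
  writeLines(c(cohort$ground_truth$signal_probes,
               cohort$ground_truth$signal_taxa),
             paths[["ground_truth"]])
  paths
}
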