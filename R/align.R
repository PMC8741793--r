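#' Align transcriptome and microbiota tables into one cohort
#'
#' Applies the keep/impute/drop rules used to reconcile partially
#' overlapping modalities:
#' * a sample with transcriptome data and a label is kept;
#' * a kept sample lacking a microbiota row receives a placeholder row
#'   (all zero) and is recorded in `imputed_microbiota_samples`, to be filled
#'   by [mean_impute()];
#' * a sample with only microbiota data is dropped (imputing tens of
#'   thousands of probes from nothing is not meaningful).
#'
#' Output sample order follows the transcriptome table restricted to kept
#' samples; all three components share that order.
#'
#' @param transcriptome,microbiota `omics_tbl` objects.
#' @param labels Label tibble from [label_vector()] / [read_labels()];
#'   must cover every kept sample.
#' @return A `multiomics_cohort`: list with elements `transcriptome`,
#'   `microbiota`, `labels`, `imputed_microbiota_samples`.
#' @export
align_modalities <- function(transcriptome, microbiota, labels) {
  t_ids <- sample_ids(transcriptome)
  m_ids <- sample_ids(microbiota)
  shared_feats <- intersect(feature_ids(transcriptome), feature_ids(microbiota))
  if (length(shared_feats) > 0) {
    abort(paste0("feature IDs must be unique across modalities; shared: ",
                 paste(head(shared_feats, 3), collapse = ", ")))
  }
  keep <- t_ids[t_ids %in% labels$sample_id]
  if (length(keep) == 0) {
    abort("no transcriptome sample has a label; nothing to align")
  }
  missing_lab <- setdiff(t_ids, labels$sample_id)
  # transcriptome samples without a label cannot be used in supervised
  # training and are dropped alongside microbiota-only samples
  tm <- as_feature_matrix(transcriptome)[keep, , drop = FALSE]

  mm_full <- as_feature_matrix(microbiota)
  imputed <- setdiff(keep, m_ids)
  mm <- matrix(0, nrow = length(keep), ncol = ncol(mm_full),
               dimnames = list(keep, colnames(mm_full)))
  present <- intersect(keep, m_ids)
  mm[present, ] <- mm_full[present, , drop = FALSE]

  lab <- labels[match(keep, labels$sample_id), ]

  structure(
    list(
      transcriptome = omics_table(tm, "transcriptome"),
      microbiota = omics_table(mm, "microbiota"),
      labels = label_vector(lab$sample_id, lab$label),
      imputed_microbiota_samples = imputed
    ),
    dropped_microbiota_only = setdiff(m_ids, keep),
    dropped_unlabelled = missing_lab,
    class = "multiomics_cohort"
  )
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "# multiomics_cohort: %d samples (%d cases / %d controls)\n",
    "#   transcriptome: %d features; microbiota: %d features\n",
    "#   imputed microbiota rows: %d\n"),
    nrow(x$labels), sum(x$labels$label == 1L), sum(x$labels$label == 0L),
    length(feature_ids(x$transcriptome)), length(feature_ids(x$microbiota)),
    length(x$imputed_microbiota_samples)))
  invisible(x)
}

#' @method glance multiomics_cohort
#' @export
glance.multiomics_cohort <- function(x, ...) {
  tibble(
    n_samples = nrow(x$labels),
    n_cases = sum(x$labels$label == 1L),
    n_controls = sum(x$labels$label == 0L),
    n_probes = length(feature_ids(x$transcriptome)),
    n_taxa = length(feature_ids(x$microbiota)),
    n_imputed_microbiota = length(x$imputed_microbiota_samples)
  )
}
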