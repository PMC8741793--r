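#' Combine transcriptome and microbiota features under one of four
#' integration strategies
#'
#' The strategies correspond to the four ways of using the two modalities:
#'
#' 1. `microbiota_only` — select (optionally) and use microbiota features
#'    alone;
#' 2. `transcriptome_only` — likewise for the transcriptome;
#' 3. `combine_then_select` — concatenate both modalities' columns first,
#'    then run a single feature selection on the combined matrix;
#' 4. `select_then_combine` — run feature selection per modality, then
#'    concatenate the selected columns (late fusion).
#'
#' Selection within a strategy is Plan B ([select_plan_b()]) with the given
#' ranker; passing a fixed `n_features` restricts the candidate schedule to
#' that single value (i.e. take the top n of the training ranking), and
#' `NULL` searches the full schedule. `n_features = NA` disables selection
#' for that modality (all features pass through).
#'
#' @param transcriptome,microbiota Normalized training blocks (matrix or
#'   `omics_tbl`) with identical sample order.
#' @param y Binary training labels.
#' @param strategy One of the four tags above.
#' @param ranker Ranking method tag (default `"chi2"`).
#' @param n_transcriptome,n_microbiota,n_combined Feature-count targets per
#'   selection (fixed integer, `NULL` for a full cross-validated search, or
#'   `NA` to disable selection).
#' @param model [classifier_spec()] scoring candidate subsets during the
#'   search.
#' @param n_folds,seed Cross-validation parameters.
#' @return List: `features` (selected training matrix, transcriptome
#'   columns first), `provenance` (tibble `feature_id`, `modality`),
#'   `selection` (the `selection_result`(s) behind the choice, or `NULL`
#'   where selection was disabled).
#' @export
integrate_modalities <- function(transcriptome, microbiota, y,
                                 strategy = c("select_then_combine",
                                              "combine_then_select",
                                              "transcriptome_only",
                                              "microbiota_only"),
                                 ranker = "chi2",
                                 n_transcriptome = 35L, n_microbiota = 50L,
                                 n_combined = NULL,
                                 model = classifier_spec("svm_rbf"),
                                 n_folds = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  tm <- as_feature_matrix(transcriptome)
  mm <- as_feature_matrix(microbiota)
  if (!identical(rownames(tm), rownames(mm))) {
    abort("modalities must share an identical ordered sample set; align first")
  }
  if (is.data.frame(y)) y <- y$label
  mod_of <- c(setNames(rep("transcriptome", ncol(tm)), colnames(tm)),
              setNames(rep("microbiota", ncol(mm)), colnames(mm)))

  select_block <- function(m, n_target) {
    if (length(n_target) == 1 && is.na(n_target)) {
      return(list(ids = colnames(m), sel = NULL))
    }
    schedule <- if (is.null(n_target)) k_schedule(ncol(m)) else as.integer(n_target)
    sel <- select_plan_b(m, y, ranker = ranker, n_folds = n_folds,
                         schedule = schedule, model = model, seed = seed)
    list(ids = sel$selected_ids, sel = sel)
  }

  out <- switch(strategy,
    transcriptome_only = {
      b <- select_block(tm, n_transcriptome)
      list(features = tm[, b$ids, drop = FALSE], selection = b$sel)
    },
    microbiota_only = {
      b <- select_block(mm, n_microbiota)
      list(features = mm[, b$ids, drop = FALSE], selection = b$sel)
    },
    combine_then_select = {
      comb <- cbind(tm, mm)
      b <- select_block(comb, n_combined)
      list(features = comb[, b$ids, drop = FALSE], selection = b$sel)
    },
    select_then_combine = {
      bt <- select_block(tm, n_transcriptome)
      bm <- select_block(mm, n_microbiota)
      list(features = cbind(tm[, bt$ids, drop = FALSE],
                            mm[, bm$ids, drop = FALSE]),
           selection = list(transcriptome = bt$sel, microbiota = bm$sel))
    }
  )
  out$provenance <- tibble(feature_id = colnames(out$features),
                           modality = unname(mod_of[colnames(out$features)]))
  out
}
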