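#' Construct an omics feature table
#'
#' An omics table is a tibble holding one modality's sample-by-feature matrix:
#' a `sample_id` character column followed by one numeric column per feature.
#' Transcriptome values are arbitrary (positive) probe intensities; microbiota
#' values are non-negative relative abundances at phylum/genus level.
#'
#' @param x A data frame whose first column is `sample_id` (or that has
#'   a `sample_id` column) and whose remaining columns are numeric features,
#'   or a numeric matrix with sample rownames and feature colnames.
#' @param modality Either `"transcriptome"` or `"microbiota"`.
#' @return A tibble of class `omics_tbl` with attribute `modality`.
#' @export
omics_table <- function(x, modality = c("transcriptome", "microbiota")) {
  modality <- match.arg(modality)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input requires sample rownames and feature colnames")
    }
    if (anyDuplicated(colnames(x))) {
      abort(paste0("duplicate feature IDs: ",
                   paste(unique(colnames(x)[duplicated(colnames(x))]),
                         collapse = ", ")))
    }
    x <- dplyr::bind_cols(tibble(sample_id = rownames(x)),
                          as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("omics table needs a 'sample_id' column")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  feats <- setdiff(names(x), "sample_id")
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicate sample IDs: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  if (anyDuplicated(feats)) {
    abort(paste0("duplicate feature IDs: ",
                 paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  }
  for (f in feats) {
    if (!is.numeric(x[[f]])) abort(paste0("feature '", f, "' is not numeric"))
  }
  if (modality == "microbiota") {
    vals <- as.matrix(x[feats])
    if (any(vals < 0, na.rm = TRUE)) {
      abort("microbiota abundances must be non-negative")
    }
  }
  structure(x, modality = modality,
            class = c("omics_tbl", class(as_tibble(x))))
}

#' @export
print.omics_tbl <- function(x, ...) {
  cat(sprintf("# omics_tbl [%s]: %d samples x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Sample and feature identifiers of an omics table
#' @param x An `omics_tbl`.
#' @return Character vector of IDs, in table order.
#' @export
sample_ids <- function(x) x[["sample_id"]]

#' @rdname sample_ids
#' @export
feature_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname sample_ids
#' @export
modality <- function(x) attr(x, "modality")

#' Extract the numeric matrix from a feature table
#'
#' @param x An `omics_tbl`, a data frame with a `sample_id` column, or a
#'   numeric matrix (returned as is, coerced to have dimnames).
#' @return Numeric matrix, samples in rows (rownames = sample IDs),
#'   features in columns.
#' @export
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    return(x)
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) abort("expected a 'sample_id' column")
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- as.character(x$sample_id)
  m
}

# Rebuild an omics_tbl from a matrix, keeping the modality tag.
matrix_to_omics <- function(m, modality) {
  omics_table(m, modality = modality)
}

#' Read a tab-separated feature table
#'
#' Expects UTF-8 tab-separated text with a numeric body and a '.' decimal
#' mark. By default samples are rows: the header row holds feature IDs and
#' the first column holds sample IDs. Set `features_as_rows = TRUE` for the
#' transposed layout.
#'
#' @param path File path.
#' @param modality `"transcriptome"` or `"microbiota"`.
#' @param features_as_rows Logical; transpose on read if `TRUE`.
#' @return An [omics_table()].
#' @export
read_feature_table <- function(path, modality = c("transcriptome", "microbiota"),
                               features_as_rows = FALSE) {
  modality <- match.arg(modality)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) abort("feature table needs an ID column plus >= 1 feature")
  ids <- raw[[1]]
  body <- raw[-1]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body)))
  )
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(body)))
  if (nrow(raw) > 0 && anyNA(num)) {
    na_src <- which(is.na(num), arr.ind = TRUE)
    cell <- na_src[1, ]
    abort(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                  as.matrix(body)[cell[1], cell[2]], ids[cell[1]],
                  names(body)[cell[2]], path))
  }
  m <- num
  rownames(m) <- ids
  colnames(m) <- names(body)
  if (features_as_rows) m <- t(m)
  omics_table(m, modality = modality)
}

#' Write a feature table as tab-separated text
#'
#' Inverse of [read_feature_table()]: UTF-8, tab-delimited, '.' decimal,
#' samples as rows.
#'
#' @param table An `omics_tbl` (or data frame with `sample_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  m <- as_feature_matrix(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a case/control label table
#'
#' Two-column tab-separated text: `sample_id` and `label`. Labels may be
#' 0/1 integers or the strings "case"/"control" (mapped to 1/0);
#' 1 marks a case (atopic dermatitis), 0 a control.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id` (character) and `label`
#'   (integer 0/1).
#' @export
read_labels <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) < 2) abort("label table needs columns sample_id and label")
  lab <- tolower(trimws(raw[[2]]))
  lab[lab == "case"] <- "1"
  lab[lab == "control"] <- "0"
  val <- suppressWarnings(as.integer(lab))
  if (anyNA(val) || !all(val %in% c(0L, 1L))) {
    abort("labels must be 0/1 or 'case'/'control'")
  }
  label_vector(as.character(raw[[1]]), val)
}

#' @rdname read_labels
#' @param labels A label tibble as returned by [label_vector()].
#' @export
write_labels <- function(labels, path) {
  utils::write.table(as.data.frame(labels[c("sample_id", "label")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a label vector
#'
#' @param sample_ids Character vector of unique sample IDs.
#' @param labels Integer/numeric vector of 0 (control) / 1 (case), same length.
#' @return A tibble `sample_id`, `label`.
#' @export
label_vector <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels)) {
    abort("sample_ids and labels differ in length")
  }
  if (anyDuplicated(sample_ids)) abort("duplicate sample IDs in labels")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0 or 1")
  tibble(sample_id = sample_ids, label = labels)
}
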