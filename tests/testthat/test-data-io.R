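test_that("feature tables round-trip through TSV with IDs and values intact", {
  m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3,
              dimnames = list(c("sA", "sB", "sC"), c("g1", "g2")))
  tab <- omics_table(m, "transcriptome")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path, "transcriptome")
  expect_equal(dim(as_feature_matrix(back)), c(3L, 2L))
  expect_identical(sample_ids(back), c("sA", "sB", "sC"))
  expect_identical(feature_ids(back), c("g1", "g2"))
  expect_equal(as_feature_matrix(back), m)

  # transposed layout reads back to the same table
  tm <- t(m)
  df <- data.frame(feature_id = rownames(tm), tm, check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_feature_table(path2, "transcriptome", features_as_rows = TRUE)
  expect_equal(as_feature_matrix(back2), m)
})

test_that("malformed tables are rejected with a located parse error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "sA\t1.0\t2.0", "sB\tNA\t4.0"), path)
  expect_error(read_feature_table(path, "transcriptome"), "sB")
  expect_error(read_feature_table(path, "transcriptome"), "g1")

  expect_error(omics_table(tibble::tibble(sample_id = c("a", "a"), g1 = 1:2),
                           "transcriptome"), "duplicate sample")
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("g", "g")))
  expect_error(omics_table(m, "transcriptome"), "duplicate feature")
  expect_error(omics_table(matrix(-1, 1, 1, dimnames = list("a", "t1")),
                           "microbiota"), "non-negative")
})

test_that("label files accept 0/1 and case/control encodings", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel", "sA\tcase", "sB\tcontrol", "sC\t1"), path)
  lab <- read_labels(path)
  expect_identical(lab$label, c(1L, 0L, 1L))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, path2)
  expect_identical(read_labels(path2), lab)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel", "sA\tmaybe"), bad)
  expect_error(read_labels(bad), "0/1")
})

test_that("alignment keeps labelled transcriptome samples, flags missing microbiota, drops microbiota-only", {
  # cohort-shaped case: both tables n samples, n-1 shared
  n <- 21
  ids_t <- sprintf("P%02d", 1:n)                   # P01..P21 have transcriptome
  ids_m <- c(sprintf("P%02d", 1:(n - 1)), "EXTRA") # EXTRA is microbiota-only
  tm <- matrix(rnorm(n * 3), n, dimnames = list(ids_t, c("g1", "g2", "g3")))
  mm <- matrix(abs(rnorm(n * 2)), n, dimnames = list(ids_m, c("t1", "t2")))
  labs <- label_vector(c(ids_t, "EXTRA"), rep_len(c(1, 0), n + 1))

  co <- align_modalities(omics_table(tm, "transcriptome"),
                         omics_table(mm, "microbiota"), labs)
  expect_identical(sample_ids(co$transcriptome), ids_t)
  expect_identical(sample_ids(co$microbiota), ids_t)
  expect_identical(co$labels$sample_id, ids_t)
  expect_identical(co$imputed_microbiota_samples, sprintf("P%02d", n))
  expect_false("EXTRA" %in% sample_ids(co$microbiota))

  # identical sample sets: nothing imputed, nothing dropped
  co_same <- align_modalities(
    omics_table(tm[1:(n - 1), , drop = FALSE], "transcriptome"),
    omics_table(mm[1:(n - 1), , drop = FALSE], "microbiota"), labs)
  expect_length(co_same$imputed_microbiota_samples, 0)

  # transcriptome strictly inside microbiota: cohort = transcriptome set
  co3 <- align_modalities(
    omics_table(tm[1:5, , drop = FALSE], "transcriptome"),
    omics_table(mm, "microbiota"), labs)
  expect_identical(sample_ids(co3$transcriptome), ids_t[1:5])
  expect_length(co3$imputed_microbiota_samples, 0)
  expect_equal(nrow(co3$labels), 5L)
})

test_that("alignment is idempotent and errors on unusable inputs", {
  cfg <- small_cohort_config()
  raw <- generate_cohort(cfg)
  co <- align_modalities(raw$transcriptome, raw$microbiota, raw$labels)
  co$microbiota <- mean_impute(co$microbiota, co$imputed_microbiota_samples)
  again <- align_modalities(co$transcriptome, co$microbiota, co$labels)
  expect_equal(as_feature_matrix(again$transcriptome),
               as_feature_matrix(co$transcriptome))
  expect_equal(as_feature_matrix(again$microbiota),
               as_feature_matrix(co$microbiota))
  expect_identical(again$labels, co$labels)
  expect_length(again$imputed_microbiota_samples, 0)

  labs_none <- label_vector("ZZZ", 1)
  expect_error(align_modalities(raw$transcriptome, raw$microbiota, labs_none),
               "no transcriptome sample has a label")
})
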