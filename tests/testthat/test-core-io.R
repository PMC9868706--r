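test_that("a toy CSV with an empty cell parses to a table with one missing value", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,role,injection_order,collection_id,replicate_id,platform,F1,F2",
    "S1,biological,1,C1,R1,gcms,10,20",
    "S2,biological,2,C1,R2,gcms,,30",
    "S3,qc,3,QC,Q1,gcms,12,25"), tf)
  ft <- read_feature_table(tf)
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(sum(is.na(ft$intensities)), 1)
  expect_true(is.na(ft$intensities["S2", "F1"]))
})

test_that("write then read round-trips both table types, including missingness", {
  d <- generate_dataset(small_config(seed = 2))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(d$table, tf)
  rt <- read_feature_table(tf)
  expect_identical(is.na(rt$intensities), is.na(d$table$intensities))
  expect_equal(rt$intensities, d$table$intensities, tolerance = 1e-12)
  expect_equal(as.data.frame(rt$sample_meta), as.data.frame(d$table$sample_meta))

  tt <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(d$traits, tt, dialect = "tsv")
  expect_equal(as.data.frame(read_trait_table(tt, dialect = "tsv")),
               as.data.frame(d$traits), tolerance = 1e-12)
})

test_that("validation rejects duplicate ids, negatives and missing metadata", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,role,injection_order,collection_id,replicate_id,platform,F1",
    "S1,biological,1,C1,R1,gcms,10",
    "S1,biological,2,C1,R2,gcms,11"), tf)
  expect_error(read_feature_table(tf), "S1")

  m <- matrix(c(1, -2), 1, 2, dimnames = list("S1", c("F1", "F2")))
  sm <- tibble::tibble(sample_id = "S1", role = "biological",
                       injection_order = 1L, collection_id = "C1",
                       replicate_id = "R1", platform = "gcms")
  expect_error(feature_table(m, sm), "negative")
  expect_error(feature_table(matrix(1, 1, 1, dimnames = list("S1", "F1")),
                             sm[, -2]), "role")
})

test_that("platform merge unions disjoint names and keeps the low-RSD duplicate", {
  d <- generate_dataset(small_config(seed = 3,
                                     missing_rate = 0))
  t1 <- subset_feature_table(d$table, features = 1:2)
  t2 <- subset_feature_table(d$table, features = 3)
  t1$sample_meta$platform <- "gcms"
  t2$sample_meta$platform <- "lcms_pos"
  t1$feature_meta$name <- c("A", "B"); t2$feature_meta$name <- "C"
  merged <- merge_platform_tables(list(t1, t2))
  expect_equal(n_features(merged), 3L)

  # duplicate annotation: the 0.12-RSD copy is retained
  t2b <- subset_feature_table(d$table, features = 3:4)
  t2b$sample_meta$platform <- "lcms_pos"
  t2b$feature_meta$name <- c("rutin", "D")
  t1b <- t1; t1b$feature_meta$name <- c("rutin", "B")
  rsds <- c(0.12, 0.5, 0.30, 0.4)
  names(rsds) <- c(t1b$feature_meta$feature_id, t2b$feature_meta$feature_id)
  merged2 <- merge_platform_tables(list(t1b, t2b), qc_rsd = rsds)
  expect_equal(n_features(merged2), 3L)  # total 4 minus 1 duplicated name
  kept <- merged2$feature_meta[merged2$feature_meta$name == "rutin", ]
  expect_equal(kept$source_platform, "gcms")
  expect_equal(kept$feature_id, t1b$feature_meta$feature_id[1])

  expect_error(merge_platform_tables(list()), "empty")
})

test_that("trait loader enforces the 13-trait vocabulary and completeness", {
  tf <- withr::local_tempfile(fileext = ".csv")
  d <- generate_dataset(small_config(seed = 4))
  write_trait_table(d$traits[1:5, ], tf)
  tr <- read_trait_table(tf)
  expect_equal(dim(tr), c(5L, 14L))  # collection_id + 13 traits

  bad <- d$traits[1:5, ]; names(bad)[2] <- "XYZ"
  tf2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, tf2)
  expect_error(read_trait_table(tf2), "XYZ")

  holey <- d$traits[1:5, ]; holey$LL[2] <- NA
  tf3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(holey, tf3)
  expect_error(read_trait_table(tf3), "missing")
})
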