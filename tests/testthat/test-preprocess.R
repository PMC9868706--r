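make_mini_table <- function(m, roles = NULL, orders = NULL) {
  n <- nrow(m)
  if (is.null(roles)) roles <- rep("biological", n)
  if (is.null(orders)) orders <- seq_len(n)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  feature_table(m, tibble::tibble(
    sample_id = ids,
    role = roles, injection_order = orders,
    collection_id = paste0("C", seq_len(n)), replicate_id = "R1",
    platform = "lcms_pos"))
}

test_that("the detection filter uses an inclusive boundary and ignores QC samples", {
  m <- matrix(1, 12, 3, dimnames = list(paste0("S", 1:12), c("A", "B", "C")))
  m[1:8, "A"] <- NA     # 8/10 biological missing -> removed (0.80 inclusive)
  m[1:7, "B"] <- NA     # 7/10 -> kept
  m[11:12, "C"] <- NA   # missing only in QC -> kept
  ft <- make_mini_table(m, roles = c(rep("biological", 10), "qc", "qc"))
  kept <- filter_features(ft)
  expect_identical(colnames(kept$intensities), c("B", "C"))
})

test_that("KNN imputation leaves complete data alone and copies the nearest duplicate", {
  m <- matrix(runif(20, 1, 2), 4, 5,
              dimnames = list(paste0("S", 1:4), paste0("F", 1:5)))
  ft <- make_mini_table(m)
  expect_identical(impute_knn(ft), ft)

  m2 <- rbind(m[1, , drop = FALSE], m[1, , drop = FALSE], m[3:4, ])
  rownames(m2) <- paste0("S", 1:4)
  m2[2, 3] <- NA                       # S2 duplicates S1 except missing F3
  ft2 <- make_mini_table(m2)
  imp <- impute_knn(ft2, k = 1)
  expect_equal(imp$intensities[2, 3], m2[1, 3])
  imp_cells <- is.na(m2)
  expect_identical(imp$intensities[!imp_cells], m2[!imp_cells])
})

test_that("KNN imputation beats column-mean imputation on MCAR-masked data", {
  for (s in 1:2) {
    d <- generate_dataset(small_config(seed = s, missing_rate = 0))
    masked <- mask_missing(d$table, rate = 0.1, seed = s + 100)
    holes <- is.na(masked$intensities)
    knn <- impute_knn(masked, k = 10)$intensities
    cm <- masked$intensities
    mu <- colMeans(cm, na.rm = TRUE)
    cm[holes] <- matrix(mu, nrow(cm), ncol(cm), byrow = TRUE)[holes]
    truth <- d$table$intensities
    rmse <- function(est) sqrt(mean((est[holes] - truth[holes])^2))
    expect_lt(rmse(knn), rmse(cm))
  }
})

test_that("rsd matches its closed form and is scale invariant", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 0.5)       # sd 1 (n-1), mean 2
  v <- runif(20, 1, 5)
  expect_equal(rsd(v * 7.3), rsd(v))
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_error(rsd(3), "at least 2")
})

test_that("drift correction is exact for LOESS and strong for RF on smooth noise-free drift", {
  d <- generate_dataset(synth_config(
    n_collections = 80, chemotype_sizes = c(40, 40), n_features = 40,
    n_modules = 2, module_size = 10, markers_per_chemotype = 5,
    noise_sd = 0, qc_noise_sd = 0, drift_amplitude = 0, missing_rate = 0,
    seed = 3))
  ft <- d$table
  ord <- ft$sample_meta$injection_order
  g <- 1 + 0.3 * ((ord / max(ord) - 0.5)^2 * 4 - 1 / 3)  # smooth quadratic
  ft$intensities <- ft$intensities * g

  cl <- correct_drift(ft, "loess", seed = 1)
  expect_lt(median(cl$report$rsd_after), 1e-6)
  cr <- correct_drift(ft, "rf", seed = 1)
  expect_gte(1 - median(cr$report$rsd_after) / median(cr$report$rsd_before),
             0.80)

  # constant QC intensities -> table unchanged
  flat <- d$table
  cf <- correct_drift(flat, "loess", seed = 1)
  expect_equal(cf$table$intensities, flat$intensities, tolerance = 1e-9)
})

test_that("feature-independent drift leaves biological group ratios intact", {
  d <- generate_dataset(small_config(seed = 5, noise_sd = 0.1, qc_noise_sd = 0,
                                     drift_amplitude = 0, missing_rate = 0))
  ft <- d$table
  ord <- ft$sample_meta$injection_order
  g <- 1 + 0.25 * sin(2 * pi * ord / max(ord))
  drifted <- ft
  drifted$intensities <- ft$intensities * g
  corr <- correct_drift(drifted, "loess", seed = 1)$table
  sm <- ft$sample_meta
  bio <- sm$role == "biological"
  grp <- d$truth$chemotype_of[sm$collection_id[bio]] == 1
  ratio <- function(m) colMeans(m[bio, ][grp, ]) / colMeans(m[bio, ][!grp, ])
  expect_equal(ratio(corr$intensities), ratio(ft$intensities),
               tolerance = 0.01)
})

test_that("method selection prefers RF on ties and barely perturbs zero-drift tables", {
  d <- generate_dataset(small_config(seed = 4, noise_sd = 0.25,
                                     qc_noise_sd = 0.02, drift_amplitude = 0,
                                     missing_rate = 0))
  sel <- select_correction(d$table, seed = 2)
  expect_equal(nrow(sel$summary), 3L)
  expect_equal(sum(sel$summary$selected), 1L)
  # all methods reach reserved fraction 1 on this clean table: tie -> rf
  expect_true(all(sel$summary$reserved_fraction == 1))
  expect_identical(sel$selected, "rf")
  rel <- abs(sel$table$intensities / d$table$intensities - 1)
  expect_lt(max(rel), 0.05)
})

test_that("replicate-outlier removal drops the displaced replicate and guards small collections", {
  d <- generate_dataset(synth_config(
    n_collections = 8, n_replicates = 6, chemotype_sizes = c(4, 4),
    n_features = 30, n_modules = 2, module_size = 10,
    markers_per_chemotype = 3, missing_rate = 0, noise_sd = 0.05, seed = 4))
  ft <- d$table
  sm <- ft$sample_meta
  victim <- which(sm$collection_id == "C001" & sm$role == "biological")[1]
  ft$intensities[victim, ] <- ft$intensities[victim, ] * 25
  out <- remove_replicate_outliers(ft, n_remove = 3)
  expect_false(sm$sample_id[victim] %in% out$sample_meta$sample_id)
  counts <- base::table(out$sample_meta$collection_id[
    out$sample_meta$role == "biological"])
  expect_true(all(counts == 3))

  few <- generate_dataset(small_config(seed = 6, missing_rate = 0))
  expect_warning(kept <- remove_replicate_outliers(few$table, n_remove = 3),
                 "kept intact")
  expect_equal(n_samples(kept), n_samples(few$table))
})

test_that("log standardization centres features and averages replicates correctly", {
  d <- generate_dataset(small_config(seed = 7, missing_rate = 0))
  x <- log_standardize_and_average(d$table)
  # single replicate per collection -> averaging is identity
  one <- generate_dataset(small_config(seed = 7, n_replicates = 1,
                                       missing_rate = 0))
  x1 <- log_standardize_and_average(one$table)
  m1 <- as.matrix(x1[, -1])
  expect_lt(max(abs(colMeans(m1))), 1e-9)
  expect_equal(unname(apply(m1, 2, sd)), rep(1, ncol(m1)), tolerance = 1e-9)

  # two collections whose replicates are scaled copies (x2): closed form
  m <- matrix(rep(c(10, 20), each = 4), 4, 2,
              dimnames = list(paste0("S", 1:4), c("A", "B")))
  m[3:4, ] <- m[3:4, ] * 0          # reset
  m <- rbind(matrix(c(10, 40), 2, 2, byrow = TRUE),
             matrix(c(20, 80), 2, 2, byrow = TRUE))
  dimnames(m) <- list(paste0("S", 1:4), c("A", "B"))
  ft <- feature_table(m, tibble::tibble(
    sample_id = paste0("S", 1:4), role = "biological",
    injection_order = 1:4, collection_id = rep(c("C1", "C2"), each = 2),
    replicate_id = rep(c("R1", "R2"), 2), platform = "gcms"))
  z <- as.matrix(log_standardize_and_average(ft)[, -1])
  # each feature takes values +/- c with c = sqrt((2r-1)/(2r)), r = 2
  expect_equal(abs(unname(z)), matrix(sqrt(3 / 4), 2, 2), tolerance = 1e-9)

  neg <- d$table
  bio_row <- which(neg$sample_meta$role == "biological")[1]
  neg$intensities[bio_row, 1] <- 0
  expect_error(log_standardize_and_average(neg), "positive")
})
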