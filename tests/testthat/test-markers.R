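test_that("fold change matches its definition and inverts under group swap", {
  m <- matrix(c(4, 4, 2, 2,
                3, 3, 3, 3), 4, 2,
              dimnames = list(paste0("C", 1:4), c("A", "B")))
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  fc <- fold_change(m, mask)
  expect_equal(fc$fc, c(2, 1))
  expect_equal(fc$log2fc, c(1, 0))
  sw <- fold_change(m, !mask)
  expect_equal(sw$fc, 1 / fc$fc)
  expect_error(fold_change(m, rep(TRUE, 4)), "non-empty")
})

test_that("the pooled t-test matches closed form and degrades gracefully", {
  # means 0 vs 3 at sd ~1, n = 30/30: p astronomically small
  set.seed(8)
  x <- matrix(rnorm(60), 60, 1, dimnames = list(sprintf("C%02d", 1:60), "F1"))
  mask <- rep(c(TRUE, FALSE), each = 30)
  x[mask, 1] <- x[mask, 1] + 3
  tt <- feature_t_test(x, mask)
  expect_lt(tt$p_value, 1e-10)
  # cross-check against stats::t.test with pooled variance
  ref <- t.test(x[mask, 1], x[!mask, 1], var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)

  # identical constant groups: degenerate convention p = 1 with flag
  z <- matrix(5, 10, 1, dimnames = list(paste0("C", 1:10), "F1"))
  td <- feature_t_test(z, rep(c(TRUE, FALSE), each = 5))
  expect_equal(td$p_value, 1)
  expect_true(td$zero_variance)

  # under the null p is approximately uniform
  set.seed(9)
  xn <- matrix(rnorm(60 * 300), 60,
               dimnames = list(sprintf("C%02d", 1:60), paste0("F", 1:300)))
  pn <- feature_t_test(xn, mask)$p_value
  expect_gt(mean(pn), 0.42)
  expect_lt(mean(pn), 0.58)
  expect_gt(mean(pn < 0.05), 0.01)
  expect_lt(mean(pn < 0.05), 0.11)
})

test_that("MDA ranks a label-copy feature first and stays near zero for noise", {
  set.seed(4)
  n <- 80
  x <- matrix(rnorm(n * 30), n,
              dimnames = list(sprintf("C%02d", 1:n), paste0("F", 1:30)))
  mask <- rep(c(TRUE, FALSE), each = n / 2)
  x[, 7] <- ifelse(mask, 1, 0)
  md <- rf_mda(x, mask, n_trees = 500, seed = 2)
  expect_equal(nrow(md), 30L)
  expect_equal(md$feature_id[which.max(md$mda)], "F7")
  noise_mda <- md$mda[-7]
  expect_lt(mean(noise_mda >= 2), 0.15)
  expect_lt(abs(median(noise_mda)), 1)
})

test_that("the joint screen applies inclusive/exclusive boundaries as specified", {
  base_tbl <- function(vip, p, l2fc, mda) {
    list(vip = tibble::tibble(feature_id = "F1", vip = vip),
         p = tibble::tibble(feature_id = "F1", p_value = p),
         fc = tibble::tibble(feature_id = "F1", fc = 2^l2fc, log2fc = l2fc),
         mda = tibble::tibble(feature_id = "F1", mda = mda))
  }
  all_pass <- base_tbl(3, 0.001, 1.2, 4)
  rec <- screen_markers(all_pass$vip, all_pass$p, all_pass$fc, all_pass$mda,
                        chemotype = 1)
  expect_true(rec$marker)
  expect_equal(rec$direction, "up")

  # VIP 1.9 fails; VIP exactly 2.0 passes (inclusive)
  v19 <- base_tbl(1.9, 0.001, 1.2, 4)
  expect_false(screen_markers(v19$vip, v19$p, v19$fc, v19$mda)$marker)
  v20 <- base_tbl(2.0, 0.001, 1.2, 4)
  expect_true(screen_markers(v20$vip, v20$p, v20$fc, v20$mda)$marker)
})

test_that("the screen equals the brute-force intersection and is threshold-monotone", {
  set.seed(3)
  n_feat <- 120
  ids <- paste0("F", seq_len(n_feat))
  vip <- tibble::tibble(feature_id = ids, vip = runif(n_feat, 0, 4))
  p <- tibble::tibble(feature_id = ids, p_value = runif(n_feat))
  l2 <- runif(n_feat, -2, 2)
  fc <- tibble::tibble(feature_id = ids, fc = 2^l2, log2fc = l2)
  mda <- tibble::tibble(feature_id = ids, mda = runif(n_feat, -1, 5))
  rec <- screen_markers(vip, p, fc, mda)
  brute <- Reduce(intersect, list(ids[vip$vip >= 2], ids[p$p_value < 0.05],
                                  ids[abs(l2) > 0.5], ids[mda$mda >= 2]))
  expect_setequal(rec$feature_id[rec$marker], brute)

  # monotone: raising any threshold never adds markers
  for (th in list(list(vip = 3), list(p = 0.01), list(log2fc = 1),
                  list(mda = 3))) {
    tighter <- screen_markers(vip, p, fc, mda, thresholds = th)
    expect_true(all(tighter$feature_id[tighter$marker] %in%
                      rec$feature_id[rec$marker]))
  }
})

test_that("exclusivity partitions marker sets correctly", {
  disjoint <- list(`1` = c("A", "B"), `2` = c("C"))
  vd <- exclusive_markers(disjoint)
  expect_true(all(vd$exclusive))
  identical_sets <- list(`1` = c("A", "B"), `2` = c("A", "B"))
  vi <- exclusive_markers(identical_sets)
  expect_false(any(vi$exclusive))
  expect_equal(vi$n_chemotypes, c(2L, 2L))
})

test_that("volcano export is row-complete and internally consistent", {
  set.seed(2)
  n_feat <- 40
  ids <- paste0("F", seq_len(n_feat))
  l2 <- rnorm(n_feat)
  rec <- screen_markers(
    tibble::tibble(feature_id = ids, vip = runif(n_feat, 0, 4)),
    tibble::tibble(feature_id = ids, p_value = runif(n_feat)),
    tibble::tibble(feature_id = ids, fc = 2^l2, log2fc = l2),
    tibble::tibble(feature_id = ids, mda = runif(n_feat, 0, 4)))
  rec$p_value[1] <- 1
  vt <- volcano_table(rec)
  expect_equal(nrow(vt), n_feat)
  expect_equal(vt$neg_log10_p[1], 0)
  expect_true(all(vt$marker == rec$marker))

  expect_error(marker_validation(matrix(1, 2, 2), character(0), 1:2),
               "empty")
})
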