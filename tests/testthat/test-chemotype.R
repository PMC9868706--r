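test_that("gap statistic picks the planted k on blobs and k = 1 on a single blob", {
  for (s in 1:3) {
    b <- make_blobs(s, k = 4)
    g <- gap_statistic(b$x, k_range = 1:6, seed = s)
    expect_equal(g$k_hat, 4L)
    expect_equal(nrow(g$curve), 6L)
    expect_true(all(g$curve$s_k > 0))
    expect_equal(g$curve$gap,
                 g$curve$expected_log_wk - g$curve$log_wk)
  }
  set.seed(11)
  x1 <- matrix(rnorm(160 * 2), 160,
               dimnames = list(sprintf("C%03d", 1:160), c("V1", "V2")))
  expect_equal(gap_statistic(x1, k_range = 1:6, seed = 3)$k_hat, 1L)
  expect_error(gap_statistic(matrix(1, 20, 2,
                                    dimnames = list(paste0("C", 1:20), NULL))),
               "degenerate")
})

test_that("gap dispersion curve agrees with the clusGap oracle on separated blobs", {
  skip_if_not_installed("cluster")
  b <- make_blobs(5, k = 3, n = 90)
  g <- gap_statistic(b$x, k_range = 1:5, B = 20, seed = 5)
  set.seed(5)
  oracle <- cluster::clusGap(b$x, FUNcluster = function(x, k) {
    list(cluster = stats::kmeans(x, k, nstart = 10)$cluster)
  }, K.max = 5, B = 20, d.power = 2, spaceH0 = "original", verbose = FALSE)
  # same dispersion up to the pair-counting convention (clusGap sums
  # unordered pairs, i.e. W/2; the constant cancels inside the gap), for
  # k <= true k where k-means reaches the same optimum
  expect_equal(g$curve$log_wk[1:3] - log(2), unname(oracle$Tab[1:3, "logW"]),
               tolerance = 1e-6)
  expect_equal(
    cluster::maxSE(oracle$Tab[, "gap"], oracle$Tab[, "SE.sim"],
                   method = "Tibs2001SEmax"),
    g$k_hat)
})

test_that("k-means assignment is deterministic, size-ordered and exact on blobs", {
  b <- make_blobs(2, k = 2, n = 80, sep = 8)
  a1 <- kmeans_classify(b$x, 2, seed = 9)
  a2 <- kmeans_classify(b$x, 2, seed = 9)
  expect_identical(a1$chemotype, a2$chemotype)
  expect_equal(adjusted_rand_index(a1$chemotype, b$labels), 1)
  sizes <- as.vector(base::table(a1$chemotype))
  expect_true(all(diff(sizes) <= 0))
  # duplicate rows stay co-clustered
  xd <- rbind(b$x, b$x[1, , drop = FALSE])
  rownames(xd)[81] <- "C081dup"
  ad <- kmeans_classify(xd, 2, seed = 9)
  expect_equal(ad$chemotype[81], ad$chemotype[1])
  expect_error(kmeans_classify(b$x, 1), "k must be")
})

test_that("SOM collapses onto repeated points and tracks errors per epoch", {
  set.seed(3)
  proto <- matrix(rnorm(4 * 6, sd = 4), 4)
  x <- proto[rep(1:4, each = 10), ]
  rownames(x) <- sprintf("C%02d", 1:40)
  colnames(x) <- paste0("F", 1:6)
  som <- train_som(x, rows = 2, cols = 2, n_epochs = 60, seed = 2)
  expect_lt(som$qe, 1e-6)
  expect_true(all(som$trace$te >= 0 & som$trace$te <= 1))
  expect_lte(som$qe + som$te, som$trace$qe[1] + som$trace$te[1])
  expect_equal(nrow(som$trace), 60L)
})

test_that("SOM assignment equals brute-force nearest-codebook classification", {
  b <- make_blobs(4, k = 3, n = 60, d = 5)
  som <- train_som(b$x, rows = 4, cols = 4, n_epochs = 30, seed = 1)
  bmu <- som_bmu(som, b$x)
  brute <- apply(b$x, 1, function(v) {
    which.min(colSums((t(som$codebook) - v)^2))
  })
  expect_equal(bmu, unname(brute))

  som <- cluster_codebook(som, 3)
  a <- assign_chemotypes(som, b$x)
  expect_equal(sum(base::table(a$chemotype)), 60)
  expect_equal(adjusted_rand_index(a$chemotype, b$labels), 1)
  # a sample equal to a codebook vector maps to exactly that node, and
  # inherits the same chemotype as any data point sharing that BMU
  probe <- som$codebook[7, , drop = FALSE]
  rownames(probe) <- "probe"
  expect_equal(som_bmu(som, probe), 7L)
  joint <- assign_chemotypes(som, rbind(b$x, probe))
  mates <- which(som_bmu(som, b$x) == 7)
  if (length(mates) > 0) {
    expect_equal(joint$chemotype[joint$collection_id == "probe"],
                 joint$chemotype[mates[1]])
  }
})

test_that("codebook clustering with k = n_nodes labels each node alone", {
  b <- make_blobs(6, k = 2, n = 40, d = 3)
  som <- train_som(b$x, rows = 2, cols = 3, n_epochs = 20, seed = 1)
  som <- cluster_codebook(som, 6)
  expect_equal(sort(unique(som$node_cluster)), 1:6)
  expect_equal(length(unique(som$node_cluster)), 6L)
  expect_error(cluster_codebook(som, 7), "exceeds")
})
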