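make_block_matrix <- function(seed, n = 120, blocks = 3, block_size = 15,
                              n_noise = 20, rho = 0.7) {
  set.seed(seed)
  p <- blocks * block_size + n_noise
  g <- matrix(rnorm(n * blocks), n)
  m <- matrix(rnorm(n * p), n)
  truth <- rep(0L, p)
  for (b in seq_len(blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    m[, idx] <- sqrt(rho) * g[, b] + sqrt(1 - rho) * m[, idx]
    truth[idx] <- b
  }
  m <- scale(m)
  dimnames(m) <- list(sprintf("C%03d", seq_len(n)), sprintf("F%03d", seq_len(p)))
  list(x = m, truth = truth, factors = g)
}

test_that("adjacency powers behave as pointwise squares and shrink for noise", {
  bm <- make_block_matrix(1)
  a <- abs(cor(bm$x))
  expect_equal(a^6, (a^3)^2)
  noise_pairs <- a[bm$truth == 0, bm$truth == 0]
  off <- noise_pairs[upper.tri(noise_pairs)]
  expect_lt(max(off^8), 1e-4)
})

test_that("soft-threshold selection keeps the network connected on block data", {
  bm <- make_block_matrix(2)
  st <- pick_soft_threshold(bm$x)
  expect_gte(st$fits$mean_connectivity[st$fits$power == st$beta], 1)
  expect_equal(nrow(st$fits), 20L)
})

test_that("TOM is a proper similarity and planted blocks are recovered", {
  bm <- make_block_matrix(3)
  st <- pick_soft_threshold(bm$x)
  mods <- detect_modules(bm$x, beta = st$beta)
  tom <- mods$tom
  expect_equal(unname(diag(tom)), rep(1, ncol(bm$x)))
  expect_equal(tom, t(tom), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  in_block <- bm$truth > 0
  found <- mods$modules$module[in_block]
  expect_gte(adjusted_rand_index(bm$truth[in_block], found), 0.80)
  # one color per module id
  map <- unique(mods$modules[mods$modules$module > 0, c("module", "color")])
  expect_equal(nrow(map), length(unique(map$module)))
})

test_that("independent features yield no modules and module detection ignores column order", {
  set.seed(4)
  x <- scale(matrix(rnorm(100 * 60), 100))
  dimnames(x) <- list(sprintf("C%03d", 1:100), sprintf("F%03d", 1:60))
  mods <- detect_modules(x, beta = 6)
  expect_true(all(mods$modules$module == 0))

  bm <- make_block_matrix(5, n_noise = 10)
  mods1 <- detect_modules(bm$x, beta = 5)
  perm <- sample(ncol(bm$x))
  mods2 <- detect_modules(bm$x[, perm], beta = 5)
  lab1 <- mods1$modules$module[match(colnames(bm$x), mods1$modules$feature_id)]
  lab2 <- mods2$modules$module[match(colnames(bm$x), mods2$modules$feature_id)]
  expect_equal(adjusted_rand_index(lab1, lab2), 1)
})

test_that("the eigenmetabolite is the leading PC, unit variance, positively oriented", {
  bm <- make_block_matrix(6)
  mods <- detect_modules(bm$x, beta = 5)
  expect_false(is.null(mods$eigenmetabolites))
  me <- as.matrix(mods$eigenmetabolites[, -1])
  expect_equal(unname(apply(me, 2, sd)), rep(1, ncol(me)), tolerance = 1e-9)
  # explains the largest variance fraction of its module's submatrix
  first_mod <- mods$modules$feature_id[mods$modules$module == 1]
  sub <- scale(bm$x[, first_mod])
  pc <- prcomp(sub, center = FALSE)
  expect_gt(abs(cor(me[, 1], pc$x[, 1])), 1 - 1e-9)
})

test_that("module-trait correlation flags a planted coupling and a trait copy", {
  bm <- make_block_matrix(7)
  mods <- detect_modules(bm$x, beta = 5)
  traits <- tibble::tibble(
    collection_id = rownames(bm$x),
    LL = as.vector(mods$eigenmetabolites[[2]]),          # exact copy
    LT = rnorm(nrow(bm$x)))
  mt <- module_trait_correlation(mods, traits)
  expect_equal(nrow(mt), 2 * (ncol(mods$eigenmetabolites) - 1))
  copy_row <- mt[mt$module == names(mods$eigenmetabolites)[2] &
                   mt$trait == "LL", ]
  expect_equal(abs(copy_row$r), 1, tolerance = 1e-9)
  expect_lt(copy_row$p_value, 1e-12)
})

test_that("chemotypes with no up-markers yield an empty morphological link", {
  bm <- make_block_matrix(8)
  mods <- detect_modules(bm$x, beta = 5)
  traits <- tibble::tibble(collection_id = rownames(bm$x),
                           LL = bm$factors[, 1] * 0.75 + rnorm(nrow(bm$x)))
  mt <- module_trait_correlation(mods, traits)
  fake_markers <- tibble::tibble(
    feature_id = character(0), chemotype = integer(0), marker = logical(0),
    direction = character(0))
  fake_markers <- dplyr::bind_rows(
    fake_markers,
    tibble::tibble(feature_id = "F001", chemotype = 1L, marker = TRUE,
                   direction = "down"))
  res <- select_morph_markers(fake_markers, mods, mt)
  expect_equal(nrow(res), 1L)
  expect_true(is.na(res$trait))
})

test_that("RF regression importance singles out the generating feature", {
  set.seed(9)
  x <- matrix(rnorm(100 * 15), 100,
              dimnames = list(sprintf("C%03d", 1:100), paste0("F", 1:15)))
  y <- x[, 4] + rnorm(100, sd = 0.2)
  imp <- rf_regression_importance(x, y, n_trees = 500, seed = 1)
  expect_equal(nrow(imp), 15L)
  expect_equal(imp$feature_id[which.max(imp$inc_mse)], "F4")
})

test_that("LASSO predictability is exact for a copied trait and rejects constants", {
  set.seed(10)
  x <- matrix(rnorm(120 * 30), 120,
              dimnames = list(sprintf("C%03d", 1:120), paste0("F", 1:30)))
  fit <- lasso_predictability(x, x[, 5], folds = 5, seed = 2)
  expect_gte(fit$predictability, 0.99)
  expect_true("F5" %in% fit$coefficients$term)
  expect_error(lasso_predictability(x, rep(1, 120)), "zero-variance")
})

test_that("trait ANOVA covers 13 traits and detects a shifted group", {
  d <- generate_dataset(small_config(seed = 11))
  asg <- truth_assignment(d$truth)
  traits <- d$traits
  traits$LW <- rnorm(nrow(traits))
  traits$LW[asg$chemotype[match(traits$collection_id,
                                asg$collection_id)] == 2] <- 5 +
    rnorm(sum(asg$chemotype == 2))
  res <- anova_traits(traits, asg)
  expect_equal(nrow(res$anova), 13L)
  expect_lt(res$anova$p_value[res$anova$trait == "LW"], 1e-6)
  mw <- res$means[res$means$trait == "LW", ]
  expect_equal(mw$chemotype[which.max(mw$mean)], "2")
})
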