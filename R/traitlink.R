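#' Pick the soft-thresholding power for the co-expression network
#'
#' For each candidate power the unsigned adjacency |cor|^beta is formed and
#' the scale-free topology fit is measured as the (sign-corrected) R^2 of
#' the log10 p(k) vs log10 k regression over 10 connectivity bins. The
#' chosen beta is the smallest power reaching `rsq_min` (default 0.80), or
#' the power maximizing the fit when none does — considering only powers
#' whose mean connectivity stays at or above `min_connectivity` (average
#' degree >= 1 by default). The connectivity floor matters on
#' block-structured metabolite data, which is not scale-free at low
#' powers: chasing the fit alone drives the power so high that the
#' network disconnects and no modules can survive.
#'
#' @param x Collection matrix (collections x features).
#' @param powers Candidate powers (default 1:20).
#' @param rsq_min Fit threshold (default 0.80).
#' @param min_connectivity Minimum mean connectivity for a power to be
#'   eligible (default 1); ignored if no power satisfies it.
#' @return A list: `beta`, `scale_free_fit`, and the per-power tibble `fits`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, rsq_min = 0.80,
                                min_connectivity = 1) {
  m <- as_collection_matrix(x)
  a0 <- abs(cor(m))
  diag(a0) <- 0
  fits <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(a0^b)
    tibble::tibble(power = b, fit = scale_free_fit(k),
                   mean_connectivity = mean(k))
  })
  eligible <- fits$mean_connectivity >= min_connectivity
  if (!any(eligible)) eligible <- rep(TRUE, nrow(fits))
  ok <- which(eligible & fits$fit >= rsq_min)
  beta <- if (length(ok) > 0) fits$power[ok[1]] else
    fits$power[which(eligible)[which.max(fits$fit[eligible])]]
  list(beta = beta, scale_free_fit = fits$fit[fits$power == beta], fits = fits)
}

# signed scale-free fit: R^2 of log10 p(k) ~ log10 k over 10 bins,
# positive only when the slope is negative (degree distribution decaying)
scale_free_fit <- function(k) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 10) return(0)
  bins <- cut(k, breaks = 10)
  dk <- tapply(k, bins, mean)
  pk <- as.vector(base::table(bins)) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Detect metabolite co-expression modules
#'
#' Unsigned weighted network: adjacency |cor|^beta, topological overlap
#' matrix (TOM) similarity, average-linkage clustering on 1 - TOM, static
#' tree cut at `cut_height`; clusters below `min_module_size` fall into
#' module 0 ("grey", unassigned). Modules are renamed by descending size
#' using the conventional colour sequence, and each module's
#' eigenmetabolite (first principal component of its standardized
#' submatrix, unit variance, sign oriented to positive mean loading) is
#' returned.
#'
#' @param x Collection matrix.
#' @param beta Soft power from [pick_soft_threshold()].
#' @param min_module_size Minimum features per module (default 10).
#' @param cut_height Static cut height on the 1 - TOM dendrogram
#'   (default 0.99).
#' @return A `module_result`: `modules` tibble (feature_id, module id,
#'   color), `eigenmetabolites` (collection x module tibble), `beta`,
#'   `tom` (the TOM matrix).
#' @export
detect_modules <- function(x, beta, min_module_size = 10, cut_height = 0.99) {
  m <- as_collection_matrix(x)
  p <- ncol(m)
  if (p < min_module_size) {
    modules <- tibble::tibble(feature_id = colnames(m), module = 0L,
                              color = "grey")
    return(structure(list(modules = modules, eigenmetabolites = NULL,
                          beta = beta, tom = NULL), class = "module_result"))
  }
  a <- abs(cor(m))^beta
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- base::table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- ifelse(as.character(raw) %in% keep, as.character(raw), "0")
  # renumber by descending size; 0 stays unassigned
  kept_sizes <- sort(base::table(module[module != "0"]), decreasing = TRUE)
  id_map <- setNames(seq_along(kept_sizes), names(kept_sizes))
  module_id <- ifelse(module == "0", 0L, unname(id_map[module]))
  color <- rep("grey", length(module_id))
  assigned <- module_id > 0
  color[assigned] <- MODULE_COLORS[pmin(module_id[assigned],
                                        length(MODULE_COLORS))]
  modules <- tibble::tibble(feature_id = colnames(m), module = module_id,
                            color = color)

  eig <- purrr::map(sort(unique(module_id[module_id > 0])), function(mm) {
    sub <- scale(m[, module_id == mm, drop = FALSE])
    pc <- prcomp(sub, center = FALSE, rank. = 1)
    e <- pc$x[, 1]
    if (mean(pc$rotation[, 1]) < 0) e <- -e
    e / sd(e)
  })
  eig_tbl <- NULL
  if (length(eig) > 0) {
    eig_m <- do.call(cbind, eig)
    colnames(eig_m) <- paste0("ME", MODULE_COLORS[seq_along(eig)])
    eig_tbl <- dplyr::bind_cols(tibble::tibble(collection_id = rownames(m)),
                                tibble::as_tibble(eig_m))
  }
  structure(list(modules = modules, eigenmetabolites = eig_tbl,
                 beta = beta, tom = tom),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  n_mod <- sum(unique(x$modules$module) > 0)
  cat(sprintf("<module_result> beta = %s: %d module(s), %d/%d features assigned\n",
              format(x$beta), n_mod, sum(x$modules$module > 0),
              nrow(x$modules)))
  if (n_mod > 0) {
    print(x$modules |> dplyr::filter(.data$module > 0) |>
            dplyr::count(.data$module, .data$color))
  }
  invisible(x)
}

#' @rdname detect_modules
#' @param x A `module_result`.
#' @param ... Unused.
#' @export
tidy.module_result <- function(x, ...) x$modules

#' Module-trait correlation table
#'
#' Pearson correlation (with two-sided p) between every module
#' eigenmetabolite and every trait, over the collections present in both
#' tables.
#'
#' @param modules A `module_result` from [detect_modules()].
#' @param traits Trait tibble (`collection_id` + trait columns).
#' @return A tibble: module (ME color), trait, r, p_value, n.
#' @export
module_trait_correlation <- function(modules, traits) {
  eig <- modules$eigenmetabolites
  if (is.null(eig)) abort("no modules detected; nothing to correlate.")
  shared <- intersect(eig$collection_id, traits$collection_id)
  if (length(shared) < 3) abort("too few shared collections.")
  e <- eig[match(shared, eig$collection_id), ]
  t_ <- traits[match(shared, traits$collection_id), ]
  me_cols <- setdiff(names(e), "collection_id")
  tr_cols <- setdiff(names(t_), "collection_id")
  tidyr::expand_grid(module = me_cols, trait = tr_cols) |>
    dplyr::mutate(purrr::map2_dfr(.data$module, .data$trait, function(mm, tr) {
      ct <- cor.test(e[[mm]], t_[[tr]])
      tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                     n = length(shared))
    }))
}

#' Heat-map style plot of module-trait correlations
#'
#' @param mt_cor Output of [module_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(mt_cor) {
  ggplot2::ggplot(mt_cor, ggplot2::aes(x = .data$trait, y = .data$module,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r,
                      ifelse(.data$p_value < 0.05, "*", ""))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Morphological marker of each chemotype
#'
#' For each chemotype, the module containing the largest number of that
#' chemotype's up-regulated chemomarkers is found, and the chemotype's
#' morphological marker is that module's most strongly correlated trait
#' (max |r| among correlations with p < 0.05). Chemotypes whose best
#' module has no significant trait get `NA` with a warning.
#'
#' @param markers Marker-record tibble from [screen_chemomarkers()].
#' @param modules A `module_result`.
#' @param mt_cor Output of [module_trait_correlation()].
#' @return A tibble: chemotype, module, n_markers_in_module, trait, r,
#'   p_value.
#' @export
select_morph_markers <- function(markers, modules, mt_cor) {
  mod_tbl <- modules$modules
  chemos <- sort(unique(markers$chemotype))
  purrr::map_dfr(chemos, function(cc) {
    up <- markers |>
      dplyr::filter(.data$chemotype == cc, .data$marker,
                    .data$direction == "up")
    if (nrow(up) == 0) {
      return(tibble::tibble(chemotype = cc, module = NA_character_,
                            n_markers_in_module = 0L, trait = NA_character_,
                            r = NA_real_, p_value = NA_real_))
    }
    counts <- mod_tbl |>
      dplyr::filter(.data$feature_id %in% up$feature_id, .data$module > 0) |>
      dplyr::count(.data$module, .data$color, sort = TRUE)
    if (nrow(counts) == 0) {
      warn(sprintf("chemotype %s: no up-markers fall in any module.", cc))
      return(tibble::tibble(chemotype = cc, module = NA_character_,
                            n_markers_in_module = 0L, trait = NA_character_,
                            r = NA_real_, p_value = NA_real_))
    }
    me <- paste0("ME", counts$color[1])
    cand <- mt_cor |>
      dplyr::filter(.data$module == me, .data$p_value < 0.05) |>
      dplyr::arrange(dplyr::desc(abs(.data$r)))
    if (nrow(cand) == 0) {
      warn(sprintf("chemotype %s: module %s has no significant trait.", cc, me))
      return(tibble::tibble(chemotype = cc, module = me,
                            n_markers_in_module = counts$n[1],
                            trait = NA_character_, r = NA_real_,
                            p_value = NA_real_))
    }
    tibble::tibble(chemotype = cc, module = me,
                   n_markers_in_module = counts$n[1],
                   trait = cand$trait[1], r = cand$r[1],
                   p_value = cand$p_value[1])
  })
}

#' Random-forest regression importance of module members for a trait
#'
#' Random-forest regression of the trait on a module's features; %IncMSE
#' is the percent increase of out-of-bag MSE upon per-feature permutation.
#'
#' @param x_module Collection matrix restricted to one module's features.
#' @param trait Numeric trait vector in row order (or a trait tibble plus
#'   `trait_name`).
#' @param trait_name Trait column when `trait` is a tibble.
#' @param n_trees Trees (default 1000).
#' @param seed Integer seed.
#' @return A tibble: feature_id, inc_mse (percent).
#' @export
rf_regression_importance <- function(x_module, trait, trait_name = NULL,
                                     n_trees = 1000, seed = 1) {
  m <- as_collection_matrix(x_module)
  y <- if (is.data.frame(trait)) {
    trait[[trait_name]][match(rownames(m), trait$collection_id)]
  } else trait
  stopifnot(length(y) == nrow(m))
  set.seed(seed)
  fit <- randomForest::randomForest(x = m, y = y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)
  tibble::tibble(feature_id = colnames(m), inc_mse = unname(imp[, 1]))
}

#' Out-of-fold LASSO predictability of a trait
#'
#' Nested cross-validation: in each outer fold the penalty is chosen by
#' inner cross-validation (1-SE rule) and the held-out collections are
#' predicted; predictability is the determination coefficient
#' R^2 = 1 - SSE/SST between the pooled out-of-fold predictions and the
#' observed trait (can be negative; never clamped). Nonzero coefficients
#' from a final full-data fit are also reported.
#'
#' @param x Collection matrix of metabolite abundances.
#' @param trait Numeric trait vector in row order (or trait tibble plus
#'   `trait_name`).
#' @param trait_name Trait column when `trait` is a tibble.
#' @param folds Outer folds (default 10).
#' @param seed Integer seed.
#' @return A `trait_prediction` list: `predictability`, `predictions`
#'   tibble, `coefficients` tibble of selected features.
#' @export
lasso_predictability <- function(x, trait, trait_name = NULL, folds = 10,
                                 seed = 1) {
  m <- as_collection_matrix(x)
  y <- if (is.data.frame(trait)) {
    trait[[trait_name]][match(rownames(m), trait$collection_id)]
  } else trait
  stopifnot(length(y) == nrow(m))
  if (sd(y) == 0) abort("zero-variance trait.")
  set.seed(stage_seed(seed, "lasso_folds"))
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(m)))
  pred <- rep(NA_real_, nrow(m))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    set.seed(stage_seed(seed, paste0("lasso_inner_", f)))
    cvfit <- glmnet::cv.glmnet(m[tr, , drop = FALSE], y[tr], alpha = 1,
                               nfolds = max(3, min(10, floor(sum(tr) / 3))))
    pred[!tr] <- as.vector(predict(cvfit, m[!tr, , drop = FALSE],
                                   s = "lambda.1se"))
  }
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  set.seed(stage_seed(seed, "lasso_full"))
  full <- glmnet::cv.glmnet(m, y, alpha = 1,
                            nfolds = max(3, min(10, floor(nrow(m) / 3))))
  cf <- coef(full, s = "lambda.1se")
  nz <- which(as.vector(cf) != 0)
  coefs <- tibble::tibble(term = rownames(cf)[nz],
                          estimate = as.vector(cf)[nz])
  structure(
    list(predictability = r2,
         predictions = tibble::tibble(collection_id = rownames(m),
                                      observed = y, predicted = pred,
                                      fold = fold_id),
         coefficients = coefs,
         trait = trait_name %||% "trait", folds = folds),
    class = "trait_prediction"
  )
}

#' @export
print.trait_prediction <- function(x, ...) {
  cat(sprintf(
    "<trait_prediction> %s: out-of-fold R^2 = %.4f (%d folds, %d features selected)\n",
    x$trait, x$predictability, x$folds, max(0, nrow(x$coefficients) - 1)))
  invisible(x)
}

#' @rdname lasso_predictability
#' @param x A `trait_prediction`.
#' @param ... Unused.
#' @export
tidy.trait_prediction <- function(x, ...) x$coefficients

#' @rdname lasso_predictability
#' @export
glance.trait_prediction <- function(x, ...) {
  tibble::tibble(trait = x$trait, predictability = x$predictability,
                 folds = x$folds,
                 n_selected = max(0, nrow(x$coefficients) - 1))
}

#' One-way ANOVA of morphology traits across chemotypes
#'
#' Per trait: one-way ANOVA across chemotype groups with Tukey HSD
#' pairwise comparisons and per-chemotype means.
#'
#' @param traits Trait tibble (`collection_id` + trait columns).
#' @param assignment A `chemotype_assignment` covering the collections.
#' @return A list: `anova` tibble (trait, F, p_value), `means`
#'   (trait x chemotype means), `tukey` (pairwise comparisons).
#' @export
anova_traits <- function(traits, assignment) {
  labels <- factor(extract_labels(assignment, traits$collection_id))
  tr_cols <- setdiff(names(traits), "collection_id")
  res <- purrr::map_dfr(tr_cols, function(tr) {
    fit <- aov(traits[[tr]] ~ labels)
    s <- summary(fit)[[1]]
    tibble::tibble(trait = tr, f_statistic = s$`F value`[1],
                   p_value = s$`Pr(>F)`[1])
  })
  means <- purrr::map_dfr(tr_cols, function(tr) {
    tibble::tibble(trait = tr,
                   chemotype = levels(labels),
                   mean = as.vector(tapply(traits[[tr]], labels, mean)))
  })
  tukey <- purrr::map_dfr(tr_cols, function(tr) {
    tk <- TukeyHSD(aov(traits[[tr]] ~ labels))$labels
    tibble::tibble(trait = tr, comparison = rownames(tk),
                   diff = tk[, "diff"], p_adj = tk[, "p adj"])
  })
  list(anova = res, means = means, tukey = tukey)
}
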