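#' One-vs-rest OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis with a
#' single predictive component: variation in X uncorrelated with the class
#' variable is iteratively removed as orthogonal components, then one
#' predictive PLS component is fitted on the filtered matrix. With
#' `n_orth = 0` the model reduces exactly to single-component PLS1.
#'
#' Reported quantities follow the usual (O)PLS conventions:
#' R2Y(cum) is the fraction of class-variable variance explained by the
#' fitted model; Q2(cum) = 1 - PRESS/TSS over stratified `cv_folds`-fold
#' cross-validation; VIP follows the classical definition (squared
#' component weights weighted by the class variance each component
#' explains, normalized so that sum(VIP^2) equals the number of features).
#' Orthogonal components explain zero class variance, so they influence
#' VIP only through the orthogonal filtering of the predictive weights.
#'
#' @param x Collection matrix (tibble with `collection_id` or matrix).
#' @param y Binary class: numeric +/-1, logical, or a 2-level factor
#'   (first level mapped to -1).
#' @param n_orth Number of orthogonal components (default 1).
#' @param cv_folds Cross-validation folds for Q2 (default 7, stratified).
#' @param seed Integer seed (controls fold allocation).
#' @return An `opls_model`: scores/weights/loadings of the predictive and
#'   orthogonal components, `r2y_cum`, `q2_cum`, `vip`.
#' @export
opls_fit <- function(x, y, n_orth = 1, cv_folds = 7, seed = 1) {
  m <- as_collection_matrix(x)
  yv <- encode_pm1(y)
  if (length(yv) != nrow(m)) abort("y length must match rows of x.")
  if (length(unique(yv)) < 2) abort("y must have exactly 2 classes.")
  if (min(base::table(yv)) < cv_folds) {
    abort("both classes must have at least cv_folds members.")
  }
  if (n_orth >= min(nrow(m) - 1, ncol(m))) {
    abort("n_orth must be below the rank of x.")
  }

  x_mean <- colMeans(m)
  y_mean <- mean(yv)
  xc <- sweep(m, 2, x_mean)
  yc <- yv - y_mean

  core <- opls_core(xc, yc, n_orth)
  fitted <- core$t_pred * core$q
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)

  # stratified CV for Q2
  set.seed(stage_seed(seed, "opls_cv"))
  folds <- integer(length(yv))
  for (cl in unique(yv)) {
    rows <- which(yv == cl)
    folds[rows] <- sample(rep(seq_len(cv_folds), length.out = length(rows)))
  }
  press <- tss <- 0
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    mu_x <- colMeans(m[tr, , drop = FALSE])
    mu_y <- mean(yv[tr])
    fit_f <- opls_core(sweep(m[tr, , drop = FALSE], 2, mu_x), yv[tr] - mu_y,
                       n_orth)
    yhat <- opls_predict_core(fit_f, sweep(m[!tr, , drop = FALSE], 2, mu_x)) + mu_y
    press <- press + sum((yv[!tr] - yhat)^2)
    tss <- tss + sum((yv[!tr] - mu_y)^2)
  }
  q2 <- 1 - press / tss

  # classical VIP: component weights squared, weighted by the class
  # variance each component explains, scaled so sum(vip^2) = p. The
  # orthogonal components explain zero class variance by construction, so
  # they enter only through the orthogonally filtered weight vector w.
  p <- ncol(m)
  vip <- sqrt(p) * abs(core$w)
  names(vip) <- colnames(m)

  structure(
    list(w = core$w, q = core$q, p_load = core$p_load,
         t_pred = core$t_pred, t_orth = core$t_orth,
         w_orth = core$w_orth, p_orth = core$p_orth,
         n_orth = length(core$t_orth),
         r2y_cum = r2y, q2_cum = q2, vip = vip,
         x_mean = x_mean, y_mean = y_mean, cv_folds = cv_folds),
    class = "opls_model"
  )
}

encode_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y)))
    if (length(lv) != 2) abort("y must have exactly 2 classes.")
    return(ifelse(as.character(y) == lv[2], 1, -1))
  }
  if (!all(y %in% c(-1, 1))) abort("numeric y must be +/-1.")
  as.numeric(y)
}

# OPLS workhorse on centered data; w is the PLS1 weight of the filtered X
opls_core <- function(xc, yc, n_orth) {
  w <- drop(crossprod(xc, yc))
  w <- w / sqrt(sum(w^2))
  t_orth <- w_orth <- p_orth <- list()
  xf <- xc
  if (n_orth > 0) {
    for (o in seq_len(n_orth)) {
      t_ <- drop(xf %*% w)
      p_ <- drop(crossprod(xf, t_)) / sum(t_^2)
      wo <- p_ - drop(crossprod(w, p_)) * w
      nw <- sqrt(sum(wo^2))
      if (nw < 1e-12) break                 # no orthogonal variation left
      wo <- wo / nw
      to <- drop(xf %*% wo)
      po <- drop(crossprod(xf, to)) / sum(to^2)
      xf <- xf - tcrossprod(to, po)
      t_orth[[o]] <- to; w_orth[[o]] <- wo; p_orth[[o]] <- po
    }
  }
  t_pred <- drop(xf %*% w)
  p_load <- drop(crossprod(xf, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  list(w = w, q = q, p_load = p_load, t_pred = t_pred,
       t_orth = t_orth, w_orth = w_orth, p_orth = p_orth)
}

opls_predict_core <- function(core, x_new_centered) {
  xf <- x_new_centered
  for (o in seq_along(core$w_orth)) {
    to <- drop(xf %*% core$w_orth[[o]])
    xf <- xf - tcrossprod(to, core$p_orth[[o]])
  }
  drop(xf %*% core$w) * core$q
}

#' Predict class scores from an OPLS-DA model
#'
#' @param object An `opls_model`.
#' @param newdata Collection matrix with the model's features.
#' @param ... Unused.
#' @return Numeric predictions on the +/-1 scale.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  m <- as_collection_matrix(newdata)
  opls_predict_core(object, sweep(m, 2, object$x_mean)) + object$y_mean
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s)\n  R2Y(cum) %.3f  Q2(cum) %.3f  (%d-fold CV)\n",
    x$n_orth, x$r2y_cum, x$q2_cum, x$cv_folds))
  invisible(x)
}

#' @rdname opls_fit
#' @param x,object An `opls_model`.
#' @param ... Unused.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature_id = names(x$vip), vip = unname(x$vip),
                 weight = unname(x$w), loading = unname(x$p_load))
}

#' @rdname opls_fit
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(r2y_cum = x$r2y_cum, q2_cum = x$q2_cum,
                 n_orth = x$n_orth, cv_folds = x$cv_folds)
}

#' Permutation validation of an OPLS-DA model
#'
#' The class variable is permuted `n_perm` times and the model refitted
#' each time; empirical p-values are (1 + #\{permuted >= observed\}) /
#' (n_perm + 1) for both R2Y and Q2. A valid model shows permuted values
#' clearly below the observed ones.
#'
#' @param x Collection matrix.
#' @param y Binary class as in [opls_fit()].
#' @param n_perm Number of permutations (default 200, must be > 0).
#' @param n_orth,cv_folds Passed to [opls_fit()].
#' @param seed Integer seed.
#' @return A `permutation_result`: observed r2y/q2, tibble of permuted
#'   values, empirical p-values.
#' @export
opls_permutation <- function(x, y, n_perm = 200, n_orth = 1, cv_folds = 7,
                             seed = 1) {
  if (n_perm <= 0) abort("n_perm must be positive.")
  m <- as_collection_matrix(x)
  obs <- opls_fit(m, y, n_orth = n_orth, cv_folds = cv_folds, seed = seed)
  yv <- encode_pm1(y)
  perm <- purrr::map_dfr(seq_len(n_perm), function(b) {
    set.seed(stage_seed(seed, paste0("perm_", b)))
    yp <- sample(yv)
    fit <- opls_fit(m, yp, n_orth = n_orth, cv_folds = cv_folds,
                    seed = stage_seed(seed, paste0("perm_cv_", b)))
    tibble::tibble(perm = b, r2y = fit$r2y_cum, q2 = fit$q2_cum)
  })
  structure(
    list(observed = tibble::tibble(r2y = obs$r2y_cum, q2 = obs$q2_cum),
         permuted = perm,
         p_r2y = (1 + sum(perm$r2y >= obs$r2y_cum)) / (n_perm + 1),
         p_q2 = (1 + sum(perm$q2 >= obs$q2_cum)) / (n_perm + 1),
         n_perm = n_perm),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d permutations\n  observed R2Y %.3f (p = %.4f)  observed Q2 %.3f (p = %.4f)\n",
    x$n_perm, x$observed$r2y, x$p_r2y, x$observed$q2, x$p_q2))
  invisible(x)
}

#' @rdname opls_permutation
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @export
autoplot.permutation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$permuted, c("r2y", "q2"),
                              names_to = "metric", values_to = "value")
  obs <- tidyr::pivot_longer(object$observed, c("r2y", "q2"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "permuted value", y = "count",
                  title = "OPLS-DA permutation validation") +
    ggplot2::theme_minimal()
}
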