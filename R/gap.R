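#' Gap statistic for choosing the number of chemotypes
#'
#' For each candidate k the within-cluster dispersion W_k of the best of 10
#' seeded K-means restarts is compared with its expectation under B uniform
#' reference datasets drawn over the data's bounding box:
#' gap(k) = mean_b log(W_kb) - log(W_k), with simulation error
#' s_k = sd_b(log W_kb) * sqrt(1 + 1/B). The selected k is the smallest k
#' with gap(k) >= gap(k+1) - s_(k+1) (ties resolved toward smaller k); if
#' no k satisfies the rule the gap maximum is taken.
#'
#' @param x Collection matrix: tibble with `collection_id` plus feature
#'   columns, or a numeric matrix with rownames.
#' @param k_range Candidate cluster counts (default 1:10).
#' @param B Number of uniform reference datasets (default 50).
#' @param nstart K-means restarts per fit (default 10).
#' @param seed Integer seed.
#' @return A `gap_result`: tibble with columns k, log_wk, expected_log_wk,
#'   gap, s_k; attribute/field `k_hat` is the selected k.
#' @export
gap_statistic <- function(x, k_range = 1:10, B = 50, nstart = 10, seed = 1) {
  m <- as_collection_matrix(x)
  if (nrow(m) < max(k_range) + 1) abort("too few rows for the requested k range.")
  rng <- apply(m, 2, range)
  if (all(rng[1, ] == rng[2, ])) abort("degenerate input: zero variance.")

  wk <- function(mm, k, seed_k) {
    if (k == 1) return(sum(scale(mm, scale = FALSE)^2))
    set.seed(seed_k)
    kmeans(mm, centers = k, nstart = nstart, iter.max = 50)$tot.withinss
  }

  log_wk <- vapply(k_range, function(k) {
    log(wk(m, k, stage_seed(seed, paste0("data_k", k))))
  }, numeric(1))

  set.seed(stage_seed(seed, "reference"))
  ref_seeds <- matrix(sample.int(2^31 - 1, B * length(k_range)), B)
  log_wk_ref <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    set.seed(stage_seed(seed, paste0("ref_draw", b)))
    ref <- sapply(seq_len(ncol(m)), function(j) runif(nrow(m), rng[1, j], rng[2, j]))
    for (ki in seq_along(k_range)) {
      log_wk_ref[b, ki] <- log(wk(ref, k_range[ki], ref_seeds[b, ki]))
    }
  }

  expected <- colMeans(log_wk_ref)
  gap <- expected - log_wk
  s_k <- apply(log_wk_ref, 2, sd) * sqrt(1 + 1 / B)

  k_hat <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1)) {
    if (gap[i] >= gap[i + 1] - s_k[i + 1]) {
      k_hat <- k_range[i]
      break
    }
  }
  res <- tibble::tibble(k = k_range, log_wk = log_wk,
                        expected_log_wk = expected, gap = gap, s_k = s_k)
  structure(list(curve = res, k_hat = k_hat, B = B), class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> selected k = %d (B = %d references)\n",
              x$k_hat, x$B))
  print(x$curve)
  invisible(x)
}

#' @rdname gap_statistic
#' @param x A `gap_result`.
#' @param ... Unused.
#' @export
tidy.gap_result <- function(x, ...) x$curve

#' @rdname gap_statistic
#' @export
glance.gap_result <- function(x, ...) {
  tibble::tibble(k_hat = x$k_hat, B = x$B,
                 max_gap = max(x$curve$gap))
}

#' @rdname gap_statistic
#' @param object A `gap_result`.
#' @export
autoplot.gap_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$s_k,
                                          ymax = .data$gap + .data$s_k)) +
    ggplot2::geom_vline(xintercept = object$k_hat, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic",
                  title = sprintf("Gap statistic (selected k = %d)", object$k_hat)) +
    ggplot2::theme_minimal()
}

#' K-means chemotype assignment
#'
#' Best of `nstart` seeded restarts by within-cluster dispersion; cluster
#' labels are renumbered by descending cluster size (ties by first
#' occurrence), matching the chemotype numbering convention.
#'
#' @param x Collection matrix (tibble with `collection_id` or matrix).
#' @param k Number of chemotypes (>= 2).
#' @param nstart Restarts (default 10).
#' @param seed Integer seed.
#' @return A `chemotype_assignment` tibble: `collection_id`, `chemotype`
#'   (integer 1..k); attributes `method = "kmeans"` and `k`.
#' @export
kmeans_classify <- function(x, k, nstart = 10, seed = 1) {
  m <- as_collection_matrix(x)
  if (k < 2) abort("k must be >= 2.")
  if (k > nrow(m)) abort("k exceeds the number of collections.")
  set.seed(seed)
  fit <- kmeans(m, centers = k, nstart = nstart, iter.max = 50)
  new_chemotype_assignment(rownames(m), fit$cluster, method = "kmeans", k = k)
}

# renumber labels by descending group size and build the assignment tibble
new_chemotype_assignment <- function(collection_id, raw_labels, method, k,
                                     extra = NULL) {
  sizes <- base::table(raw_labels)
  order_map <- names(sizes)[order(-as.vector(sizes),
                                  match(names(sizes), unique(as.character(raw_labels))))]
  chem <- match(as.character(raw_labels), order_map)
  out <- tibble::tibble(collection_id = collection_id, chemotype = chem)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, method = method, k = k,
            class = c("chemotype_assignment", class(out)))
}

#' @export
print.chemotype_assignment <- function(x, ...) {
  cat(sprintf("<chemotype_assignment> method = %s, k = %d\n",
              attr(x, "method"), attr(x, "k")))
  print(base::table(chemotype = x$chemotype))
  NextMethod()
}
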