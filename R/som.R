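#' Train a self-organizing map on a collection matrix
#'
#' A rectangular SOM (default 7 x 7) trained for a fixed number of epochs
#' of sequential best-matching-unit (BMU) updates with a Gaussian
#' neighbourhood truncated at the current radius. The radius decays
#' linearly from `max(rows, cols)/2` to 0.5 and the learning rate from
#' 0.5 to 0.01 over the epochs; once the radius drops below the grid
#' spacing the updates are winner-only, letting the codebook converge.
#' The codebook is initialized deterministically on the top-2
#' principal-component plane of the data; sample presentation order is
#' reshuffled each epoch from the seed.
#'
#' After every epoch the quantization error (mean sample-to-BMU distance)
#' and topographic error (fraction of samples whose best and second-best
#' nodes are not 4-adjacent on the grid) are recorded; the returned
#' codebook is the epoch snapshot minimizing `qe_weight*qe + te_weight*te`,
#' the fixed-iteration reading of "minimum quantization and topology error"
#' as the training termination criterion.
#'
#' @param x Collection matrix (tibble with `collection_id` or matrix),
#'   already standardized.
#' @param rows,cols Grid dimensions (default 7 x 7).
#' @param n_epochs Training epochs (default 100).
#' @param qe_weight,te_weight Weights of the snapshot criterion (default 1, 1).
#' @param init "pca" (deterministic, default) or "sample" (seeded random
#'   rows of the data).
#' @param seed Integer seed.
#' @return A `som_model`: codebook (node x feature), grid layout, `qe`,
#'   `te`, per-epoch `trace`, and (after [cluster_codebook()]) a
#'   `node_cluster` labeling.
#' @export
train_som <- function(x, rows = 7, cols = 7, n_epochs = 100,
                      qe_weight = 1, te_weight = 1,
                      init = c("pca", "sample"), seed = 1) {
  m <- as_collection_matrix(x)
  if (any(!is.finite(m))) abort("input matrix must be finite.")
  init <- match.arg(init)
  n_nodes <- rows * cols
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]

  codebook <- if (init == "pca") {
    pc <- prcomp(m, center = TRUE, rank. = 2)
    sdev <- pc$sdev[1:2]
    u1 <- seq(-2, 2, length.out = rows) * sdev[1]
    u2 <- seq(-2, 2, length.out = cols) * sdev[2]
    rot <- pc$rotation
    if (ncol(rot) < 2) rot <- cbind(rot, 0)
    matrix(colMeans(m), n_nodes, ncol(m), byrow = TRUE) +
      u1[grid$row] %o% rot[, 1] + u2[grid$col] %o% rot[, 2]
  } else {
    set.seed(seed)
    m[sample(nrow(m), n_nodes, replace = nrow(m) < n_nodes), , drop = FALSE]
  }

  sigma0 <- max(rows, cols) / 2
  sigma_seq <- seq(sigma0, 0.5, length.out = n_epochs)
  alpha_seq <- seq(0.5, 0.01, length.out = n_epochs)
  # pairwise squared grid distances between nodes
  gd2 <- outer(grid$row, grid$row, "-")^2 + outer(grid$col, grid$col, "-")^2

  node_sq <- rowSums(codebook^2)
  bmu_errors <- function(cb) {
    d2 <- matrix(rowSums(cb^2), nrow(m), n_nodes, byrow = TRUE) -
      2 * m %*% t(cb) + rowSums(m^2)
    d2[d2 < 0] <- 0
    bmu <- max.col(-d2, ties.method = "first")
    d2_b <- d2
    d2_b[cbind(seq_len(nrow(m)), bmu)] <- Inf
    bmu2 <- max.col(-d2_b, ties.method = "first")
    qe <- mean(sqrt(d2[cbind(seq_len(nrow(m)), bmu)]))
    adj <- abs(grid$row[bmu] - grid$row[bmu2]) +
      abs(grid$col[bmu] - grid$col[bmu2]) == 1
    list(bmu = bmu, qe = qe, te = mean(!adj))
  }

  trace <- tibble::tibble(epoch = integer(0), qe = numeric(0), te = numeric(0))
  best <- list(score = Inf, codebook = codebook, qe = NA_real_, te = NA_real_)
  set.seed(stage_seed(seed, "som_order"))
  for (e in seq_len(n_epochs)) {
    sigma2 <- 2 * sigma_seq[e]^2
    alpha <- alpha_seq[e]
    # Gaussian kernel truncated at grid radius sigma: once sigma drops
    # below 1 the map fine-tunes winner-only and can converge exactly
    h_all <- exp(-gd2 / sigma2) * (gd2 <= sigma_seq[e]^2 + 1e-12)
    diag(h_all) <- 1
    for (i in sample(nrow(m))) {
      xi <- m[i, ]
      d2 <- rowSums(codebook^2) - 2 * drop(codebook %*% xi) + sum(xi^2)
      bmu <- which.min(d2)
      h <- h_all[bmu, ]
      active <- h > 1e-4
      codebook[active, ] <- codebook[active, , drop = FALSE] +
        (alpha * h[active]) *
        (matrix(xi, sum(active), ncol(m), byrow = TRUE) -
           codebook[active, , drop = FALSE])
    }
    err <- bmu_errors(codebook)
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(epoch = e, qe = err$qe, te = err$te))
    score <- qe_weight * err$qe + te_weight * err$te
    if (score < best$score) {
      best <- list(score = score, codebook = codebook, qe = err$qe, te = err$te)
    }
  }

  structure(
    list(codebook = best$codebook, grid = tibble::as_tibble(grid),
         rows = rows, cols = cols, qe = best$qe, te = best$te,
         trace = trace, node_cluster = NULL,
         feature_names = colnames(m)),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d rectangular grid, %d features\n",
              x$rows, x$cols, ncol(x$codebook)))
  cat(sprintf("  quantization error %.4f, topographic error %.4f\n", x$qe, x$te))
  if (!is.null(x$node_cluster)) {
    cat(sprintf("  codebook clustered into %d chemotypes\n",
                length(unique(x$node_cluster))))
  }
  invisible(x)
}

#' Best-matching unit of each row of a matrix
#'
#' @param model A `som_model`.
#' @param x Collection matrix.
#' @return Integer vector of node indices (row-major over the grid).
#' @export
som_bmu <- function(model, x) {
  m <- as_collection_matrix(x)
  cb <- model$codebook
  d2 <- matrix(rowSums(cb^2), nrow(m), nrow(cb), byrow = TRUE) -
    2 * m %*% t(cb) + rowSums(m^2)
  max.col(-d2, ties.method = "first")
}

#' Cluster SOM codebook vectors into chemotype groups
#'
#' Average-linkage hierarchical clustering of the node codebook vectors
#' (Euclidean distance), cut at k groups — the standard two-stage SOM
#' practice for turning the node lattice into a small number of classes.
#'
#' @param model A trained `som_model`.
#' @param k Number of chemotype groups.
#' @return The model with `node_cluster` set (one label per node).
#' @export
cluster_codebook <- function(model, k) {
  n_nodes <- nrow(model$codebook)
  if (k > n_nodes) abort("k exceeds the number of nodes.")
  hc <- hclust(dist(model$codebook), method = "average")
  model$node_cluster <- cutree(hc, k = k)
  model$k <- k
  model
}

#' Assign collections to chemotypes through a clustered SOM
#'
#' Each collection is mapped to its best-matching node and inherits that
#' node's codebook cluster; chemotype labels are renumbered by descending
#' group size (ties by first occurrence).
#'
#' @param model A `som_model` with `node_cluster` set (see
#'   [cluster_codebook()]).
#' @param x Collection matrix.
#' @return A `chemotype_assignment` tibble: `collection_id`, `chemotype`,
#'   `bmu_row`, `bmu_col`.
#' @export
assign_chemotypes <- function(model, x) {
  if (is.null(model$node_cluster)) abort("run cluster_codebook() first.")
  m <- as_collection_matrix(x)
  bmu <- som_bmu(model, m)
  new_chemotype_assignment(
    rownames(m), model$node_cluster[bmu], method = "som", k = model$k,
    extra = tibble::tibble(bmu_row = model$grid$row[bmu],
                           bmu_col = model$grid$col[bmu])
  )
}

#' @rdname train_som
#' @param x,object A `som_model`.
#' @param ... Unused.
#' @export
tidy.som_model <- function(x, ...) x$trace

#' @rdname train_som
#' @export
glance.som_model <- function(x, ...) {
  tibble::tibble(rows = x$rows, cols = x$cols, qe = x$qe, te = x$te,
                 k = x$k %||% NA_integer_)
}

#' @rdname train_som
#' @export
autoplot.som_model <- function(object, ...) {
  df <- object$grid
  df$node_cluster <- if (is.null(object$node_cluster)) NA_integer_ else
    object$node_cluster
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$node_cluster))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "chemotype",
                  title = sprintf("SOM grid (%d x %d), qe %.3f, te %.3f",
                                  object$rows, object$cols, object$qe, object$te)) +
    ggplot2::theme_minimal()
}
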