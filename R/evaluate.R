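#' Random-forest discriminant evaluation of a candidate classification
#'
#' The adjudication protocol for competing chemotype classifications: the
#' collections are split 75/25 (stratified by class), a random forest
#' (default 1,000 trees, sqrt(p) features per split) is trained on the
#' training set, and its out-of-bag training accuracy, independent-set
#' accuracy and macro one-vs-rest AUC are recorded. Reported accuracies
#' are averages over `n_repeats` seeded splits.
#'
#' @param x Collection matrix (tibble with `collection_id` or matrix).
#' @param labels A `chemotype_assignment` tibble, or a vector of labels in
#'   the row order of `x`.
#' @param split Training fraction (default 0.75).
#' @param n_trees Trees per forest (default 1000).
#' @param n_repeats Number of repeated splits to average over (default 20).
#' @param seed Integer seed; results are exactly reproducible.
#' @return An `rf_eval` list: `train_accuracy` (out-of-bag),
#'   `test_accuracy`, `auc` (macro one-vs-rest on the independent set),
#'   `per_class` accuracy tibble, and the per-repeat table `repeats`.
#' @export
rf_discriminant_eval <- function(x, labels, split = 0.75, n_trees = 1000,
                                 n_repeats = 20, seed = 1) {
  m <- as_collection_matrix(x)
  y <- extract_labels(labels, rownames(m))
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("need at least 2 classes.")
  if (any(base::table(y) < 2)) abort("every class needs at least 2 members.")
  y <- factor(y)

  one_repeat <- function(rep_seed) {
    set.seed(rep_seed)
    redraws <- 0
    repeat {
      train_idx <- unlist(lapply(levels(y), function(cl) {
        rows <- which(y == cl)
        sample(rows, max(1, round(split * length(rows))))
      }))
      if (all(levels(y) %in% y[train_idx]) &&
          length(train_idx) < length(y)) break
      redraws <- redraws + 1
      if (redraws > 10) abort("could not draw a valid stratified split.")
      warn("a class was absent from the training split; re-drawing.")
    }
    test_idx <- setdiff(seq_along(y), train_idx)
    fit <- randomForest::randomForest(
      x = m[train_idx, , drop = FALSE], y = droplevels(y[train_idx]),
      ntree = n_trees)
    oob_acc <- 1 - fit$err.rate[n_trees, "OOB"]
    pred <- predict(fit, m[test_idx, , drop = FALSE])
    prob <- predict(fit, m[test_idx, , drop = FALSE], type = "prob")
    test_acc <- mean(as.character(pred) == as.character(y[test_idx]))
    aucs <- vapply(levels(y), function(cl) {
      resp <- y[test_idx] == cl
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::roc(resp, prob[, cl], quiet = TRUE,
                           levels = c(FALSE, TRUE), direction = "<")$auc)
    }, numeric(1))
    per_class <- vapply(levels(y), function(cl) {
      rows <- which(y[test_idx] == cl)
      if (length(rows) == 0) return(NA_real_)
      mean(as.character(pred[rows]) == cl)
    }, numeric(1))
    list(train = unname(oob_acc), test = test_acc,
         auc = mean(aucs, na.rm = TRUE), per_class = per_class)
  }

  reps <- purrr::map(seq_len(n_repeats), function(r) {
    one_repeat(stage_seed(seed, paste0("rf_split_", r)))
  })
  repeats <- tibble::tibble(
    repeat_id = seq_len(n_repeats),
    train_accuracy = purrr::map_dbl(reps, "train"),
    test_accuracy = purrr::map_dbl(reps, "test"),
    auc = purrr::map_dbl(reps, "auc")
  )
  per_class <- tibble::tibble(
    chemotype = levels(y),
    test_accuracy = colMeans(do.call(rbind, purrr::map(reps, "per_class")),
                             na.rm = TRUE)
  )
  structure(
    list(train_accuracy = mean(repeats$train_accuracy),
         test_accuracy = mean(repeats$test_accuracy),
         auc = mean(repeats$auc),
         per_class = per_class, repeats = repeats,
         n_trees = n_trees, split = split, n_repeats = n_repeats),
    class = "rf_eval"
  )
}

extract_labels <- function(labels, ids) {
  if (inherits(labels, "chemotype_assignment") ||
      (is.data.frame(labels) && all(c("collection_id", "chemotype") %in% names(labels)))) {
    idx <- match(ids, labels$collection_id)
    if (anyNA(idx)) abort("labels do not cover all collections.")
    return(labels$chemotype[idx])
  }
  if (length(labels) != length(ids)) abort("label length mismatch.")
  labels
}

#' @export
print.rf_eval <- function(x, ...) {
  cat(sprintf(
    "<rf_eval> %d trees, %.0f/%.0f split, %d repeats\n  train (OOB) %.2f%%  independent %.2f%%  macro AUC %.3f\n",
    x$n_trees, 100 * x$split, 100 * (1 - x$split), x$n_repeats,
    100 * x$train_accuracy, 100 * x$test_accuracy, x$auc))
  invisible(x)
}

#' @rdname rf_discriminant_eval
#' @param x,object An `rf_eval`.
#' @param ... Unused.
#' @export
tidy.rf_eval <- function(x, ...) x$repeats

#' @rdname rf_discriminant_eval
#' @export
glance.rf_eval <- function(x, ...) {
  tibble::tibble(train_accuracy = x$train_accuracy,
                 test_accuracy = x$test_accuracy, auc = x$auc,
                 n_trees = x$n_trees, split = x$split,
                 n_repeats = x$n_repeats)
}

#' Compare candidate chemotype classifications with the RF protocol
#'
#' One [rf_discriminant_eval()] row per candidate; the winner is the
#' candidate with the highest mean of training and independent-set
#' accuracy — the adjudication that decides between SOM and K-means and
#' between cluster counts.
#'
#' @param x Collection matrix.
#' @param candidates Named list of `chemotype_assignment` objects.
#' @param ... Passed to [rf_discriminant_eval()].
#' @return A tibble: name, method, k, train/test accuracy, mean_accuracy,
#'   auc, winner flag; sorted as given.
#' @export
compare_classifications <- function(x, candidates, ...) {
  if (length(candidates) == 0) abort("no candidates supplied.")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  rows <- purrr::imap_dfr(candidates, function(a, nm) {
    ev <- rf_discriminant_eval(x, a, ...)
    tibble::tibble(name = nm,
                   method = attr(a, "method") %||% NA_character_,
                   k = attr(a, "k") %||% length(unique(a$chemotype)),
                   train_accuracy = ev$train_accuracy,
                   test_accuracy = ev$test_accuracy,
                   mean_accuracy = (ev$train_accuracy + ev$test_accuracy) / 2,
                   auc = ev$auc)
  })
  rows$winner <- seq_len(nrow(rows)) == which.max(rows$mean_accuracy)
  rows
}

#' PCA summary of a collection matrix
#'
#' Centered (not re-scaled; the matrix is already autoscaled) singular
#' value decomposition; explained-variance fractions are relative to the
#' total variance and sorted descending.
#'
#' @param x Collection matrix.
#' @param n_components Number of components to keep (default 12).
#' @return A list: `scores` tibble (`collection_id`, PC1..PCn),
#'   `explained` (variance fractions), `cumulative` (their cumsum).
#' @export
pca_summary <- function(x, n_components = 12) {
  m <- as_collection_matrix(x)
  n_components <- min(n_components, nrow(m) - 1, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(collection_id = rownames(m)), scores)
  list(scores = scores, explained = frac[seq_len(n_components)],
       cumulative = cumsum(frac)[seq_len(n_components)])
}
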