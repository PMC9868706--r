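#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used throughout to score recovered chemotype or module assignments
#' against planted ground truth. Invariant to label permutation.
#'
#' @param a,b Vectors of cluster labels (any atomic type), same length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-stage seeds so that
#' stages are individually reproducible. Stable across platforms (pure
#' integer arithmetic, result < 2^31).
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

# coerce a "collection matrix" (tibble with collection_id + feature cols,
# or a plain matrix with rownames) to a numeric matrix
as_collection_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(x)
  }
  stopifnot(is.data.frame(x), "collection_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "collection_id")])
  rownames(m) <- x$collection_id
  storage.mode(m) <- "double"
  m
}

# column-wise sample variance of a matrix
col_vars <- function(m) {
  n <- nrow(m)
  stopifnot(n >= 2)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
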