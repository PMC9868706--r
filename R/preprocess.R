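#' Relative standard deviation
#'
#' sd/mean with the sample (n-1) standard deviation; the feature-level
#' reproducibility metric computed over repeated QC injections.
#'
#' @param values Numeric vector, length >= 2, nonzero mean. `NA`s dropped.
#' @return A single non-negative number.
#' @export
#' @examples
#' rsd(c(1, 2, 3))  # 0.5
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("rsd needs at least 2 observed values.")
  m <- mean(values)
  if (m == 0) abort("rsd undefined for zero mean.")
  sd(values) / m
}

# vectorized per-column RSD with NA handling; columns with <2 observed -> NA
col_rsd <- function(m) {
  apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
}

#' Remove features undetected in most biological samples
#'
#' Drops features whose missing fraction among *biological* samples is at
#' or above `max_undetected` (inclusive boundary); QC samples never count.
#' Surviving feature order is preserved.
#'
#' @param table A [feature_table()].
#' @param max_undetected Missing-fraction threshold (default 0.80).
#' @return A filtered [feature_table()].
#' @export
filter_features <- function(table, max_undetected = 0.80) {
  bio <- table$sample_meta$role == "biological"
  if (!any(bio)) abort("no biological samples in table.")
  miss_frac <- colMeans(is.na(table$intensities[bio, , drop = FALSE]))
  keep <- miss_frac < max_undetected
  if (!any(keep)) abort("all features removed by the detection filter.")
  subset_feature_table(table, features = which(keep))
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' Each missing cell is replaced by the mean of that feature over the `k`
#' nearest samples among those where the feature was observed. Distance
#' between two samples is the Euclidean distance over features observed in
#' both, normalized by the shared-feature count, so samples with different
#' missingness patterns stay comparable.
#'
#' @param table A [feature_table()].
#' @param k Number of neighbours (default 10); must be below the sample count.
#' @return A [feature_table()] with no missing values; observed cells are
#'   never altered.
#' @export
impute_knn <- function(table, k = 10) {
  m <- table$intensities
  if (!anyNA(m)) return(table)
  n <- nrow(m)
  stopifnot(k >= 1, k < n)
  if (any(rowSums(!is.na(m)) == 0)) {
    abort("a sample has all features missing; cannot impute.")
  }
  if (any(colSums(!is.na(m)) == 0)) {
    abort("a feature has no observed values; filter it first.")
  }
  obs <- !is.na(m)
  x0 <- m
  x0[!obs] <- 0
  s <- obs * 1
  shared <- s %*% t(s)                                   # shared counts
  a <- (x0^2) %*% t(s)
  d2 <- a + t(a) - 2 * (x0 %*% t(x0))
  d2 <- d2 / pmax(shared, 1)
  d2[shared == 0] <- Inf
  diag(d2) <- Inf

  out <- m
  need <- which(!obs, arr.ind = TRUE)
  for (j in unique(need[, 2])) {
    rows <- need[need[, 2] == j, 1]
    donors <- which(obs[, j])
    for (i in rows) {
      dd <- d2[i, donors]
      nb <- donors[order(dd)[seq_len(min(k, length(donors)))]]
      out[i, j] <- mean(m[nb, j])
    }
  }
  table$intensities <- out
  table
}

# fit one drift regressor on QC points and return factors at all orders
drift_fit <- function(qc_order, qc_y, all_order, method, params, seed) {
  fitted_at <- switch(
    method,
    rf = {
      set.seed(seed)
      fit <- randomForest::randomForest(
        x = data.frame(order = qc_order), y = qc_y,
        ntree = params$rf_ntree, nodesize = params$rf_nodesize)
      predict(fit, data.frame(order = all_order))
    },
    loess = {
      fit <- loess(y ~ ord, data = data.frame(ord = qc_order, y = qc_y),
                   span = params$loess_span, degree = 2,
                   control = loess.control(surface = "direct"))
      predict(fit, data.frame(ord = all_order))
    },
    svr = {
      fit <- e1071::svm(x = matrix(qc_order, ncol = 1), y = qc_y,
                        kernel = "radial", epsilon = params$svr_epsilon,
                        gamma = params$svr_gamma)
      predict(fit, matrix(all_order, ncol = 1))
    }
  )
  qc_fit <- fitted_at[match(qc_order, all_order)]
  med <- median(qc_fit, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) return(rep(1, length(all_order)))
  fac <- fitted_at / med
  fac[!is.finite(fac)] <- 1
  pmin(pmax(fac, 0.1), 10)
}

default_drift_params <- function() {
  list(rf_ntree = 500, rf_nodesize = 5, loess_span = 0.75,
       svr_epsilon = 0.1, svr_gamma = 1)
}

#' QC-anchored correction of injection-order drift
#'
#' Per platform and per feature, a regressor of QC intensity on injection
#' order is fitted using the QC samples only; the drift factor at any
#' injection order is the fitted value divided by the median fitted value
#' at the QC orders (so QC median intensity is preserved), clipped to
#' \[0.1, 10\]; every sample's intensity is divided by its factor.
#'
#' @param table A [feature_table()] (at least 5 QC samples per platform).
#' @param method One of "rf" (random-forest regressor, 500 trees), "loess"
#'   (span 0.75, degree 2) or "svr" (radial-kernel support vector
#'   regression, epsilon 0.1).
#' @param params Optional list overriding regressor defaults
#'   (`rf_ntree`, `rf_nodesize`, `loess_span`, `svr_epsilon`, `svr_gamma`).
#' @param seed Integer seed (the RF regressor is stochastic).
#' @return A list: `table` (corrected [feature_table()]) and `report`
#'   (tibble: feature_id, rsd_before, rsd_after, corrected flag).
#' @export
correct_drift <- function(table, method = c("rf", "loess", "svr"),
                          params = list(), seed = 1) {
  method <- match.arg(method)
  params <- utils::modifyList(default_drift_params(), params)
  m <- table$intensities
  sm <- table$sample_meta
  rsd_before <- rsd_after <- rep(NA_real_, ncol(m))
  corrected <- rep(TRUE, ncol(m))
  for (pf in unique(sm$platform)) {
    rows <- which(sm$platform == pf)
    qc_rows <- rows[sm$role[rows] == "qc"]
    if (length(qc_rows) < 5) {
      abort(sprintf("platform %s has fewer than 5 QC samples.", pf))
    }
    all_order <- sm$injection_order[rows]
    qc_order <- sm$injection_order[qc_rows]
    rsd_before_pf <- col_rsd(m[qc_rows, , drop = FALSE])
    for (j in seq_len(ncol(m))) {
      y <- m[qc_rows, j]
      ok <- !is.na(y)
      if (sum(ok) < 5) {           # uncorrectable feature: pass through
        corrected[j] <- FALSE
        next
      }
      fac <- drift_fit(qc_order[ok], y[ok], all_order, method, params,
                       stage_seed(seed, paste0(pf, "_", j)))
      m[rows, j] <- m[rows, j] / fac
    }
    rsd_before <- ifelse(is.na(rsd_before), rsd_before_pf, rsd_before)
    rsd_after_pf <- col_rsd(m[qc_rows, , drop = FALSE])
    rsd_after <- ifelse(is.na(rsd_after), rsd_after_pf, rsd_after)
  }
  table$intensities <- m
  report <- tibble::tibble(
    feature_id = table$feature_meta$feature_id,
    rsd_before = rsd_before, rsd_after = rsd_after, corrected = corrected
  )
  list(table = table, report = report, method = method)
}

platform_rsd_threshold <- function(platform) {
  if (platform == "gcms") 0.50 else 0.30
}

#' Run all three drift-correction algorithms and pick one
#'
#' All of RF, LOESS and SVR are run; a method qualifies when its reserved
#' fraction (share of features with corrected QC RSD below the platform
#' threshold: 0.50 for GC-MS, 0.30 for LC-MS) is at least `proportion_min`.
#' Among qualifiers the largest reserved fraction wins; ties prefer RF,
#' then LOESS, then SVR. If no method qualifies the best reserved fraction
#' is taken with a warning.
#'
#' @param table A [feature_table()] (single platform).
#' @param proportion_min Qualification threshold on the reserved fraction
#'   (default 0.70).
#' @param params,seed Passed to [correct_drift()].
#' @return A list: `table` (corrected by the selected method), `selected`
#'   (method name), `summary` (tibble: method, reserved_fraction,
#'   median_rsd_before/after, selected), `reports` (per-method per-feature
#'   RSD tibbles).
#' @export
select_correction <- function(table, proportion_min = 0.70, params = list(),
                              seed = 1) {
  methods <- c("rf", "loess", "svr")
  runs <- purrr::map(methods, function(me) {
    correct_drift(table, me, params = params, seed = stage_seed(seed, me))
  })
  names(runs) <- methods
  thr <- platform_rsd_threshold(table$sample_meta$platform[1])
  summary <- purrr::map_dfr(runs, function(r) {
    tibble::tibble(
      method = r$method,
      rsd_threshold = thr,
      reserved_fraction = mean(r$report$rsd_after < thr, na.rm = TRUE),
      median_rsd_before = median(r$report$rsd_before, na.rm = TRUE),
      median_rsd_after = median(r$report$rsd_after, na.rm = TRUE)
    )
  })
  qualified <- summary$reserved_fraction >= proportion_min
  pool <- if (any(qualified)) which(qualified) else seq_len(nrow(summary))
  if (!any(qualified)) {
    warn("no drift-correction method reached the reserved-fraction minimum; taking the best available.")
  }
  # methods ordered rf, loess, svr, so which.max resolves ties in that order
  best <- pool[which.max(summary$reserved_fraction[pool])]
  summary$selected <- seq_len(nrow(summary)) == best
  list(table = runs[[best]]$table, selected = summary$method[best],
       summary = summary, reports = purrr::map(runs, "report"))
}

#' Remove replicate outliers per collection in the global PC plane
#'
#' Biological samples are autoscaled and projected onto the global top-2
#' principal components; within each collection the `n_remove` replicates
#' farthest (Euclidean) from the collection centroid in that plane are
#' dropped. Collections with too few replicates are kept intact with a
#' warning. QC samples are untouched.
#'
#' @param table A [feature_table()] with no missing values.
#' @param n_remove Replicates to drop per collection (default 3).
#' @return A [feature_table()].
#' @export
remove_replicate_outliers <- function(table, n_remove = 3) {
  if (n_remove == 0) return(table)
  sm <- table$sample_meta
  bio <- which(sm$role == "biological")
  x <- scale(log10(pmax(table$intensities[bio, , drop = FALSE],
                        .Machine$double.xmin)))
  x[, !is.finite(colSums(x))] <- 0
  pc <- prcomp(x, center = FALSE, rank. = 2)
  scores <- pc$x
  drop_rows <- integer(0)
  too_few <- character(0)
  for (cc in unique(sm$collection_id[bio])) {
    rows <- which(sm$collection_id[bio] == cc)
    if (length(rows) <= n_remove) {
      too_few <- c(too_few, cc)
      next
    }
    centroid <- colMeans(scores[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(scores[rows, , drop = FALSE], 2, centroid)^2))
    drop_rows <- c(drop_rows, bio[rows[order(-d)[seq_len(n_remove)]]])
  }
  if (length(too_few) > 0) {
    warn(sprintf("%d collection(s) have <= n_remove replicates and were kept intact.",
                 length(too_few)))
  }
  if (length(drop_rows) == 0) return(table)
  subset_feature_table(table, samples = setdiff(seq_len(nrow(sm)), drop_rows))
}

#' Log-standardize and average replicates into a collection matrix
#'
#' Intensities are log10-transformed, autoscaled per feature to mean 0 and
#' sd 1 over the biological samples, then averaged within collection. QC
#' samples are dropped.
#'
#' @param table A [feature_table()] with strictly positive intensities
#'   (run imputation and drift correction first).
#' @return A tibble: `collection_id` plus one standardized column per
#'   feature.
#' @export
log_standardize_and_average <- function(table) {
  bio <- table$sample_meta$role == "biological"
  m <- table$intensities[bio, , drop = FALSE]
  if (anyNA(m) || any(m <= 0)) {
    abort("intensities must be positive and complete; impute and correct first.")
  }
  z <- scale(log10(m))
  const <- !is.finite(colSums(z))
  z[, const] <- 0
  coll <- table$sample_meta$collection_id[bio]
  counts <- base::table(coll)
  agg <- rowsum(z, coll)
  agg <- agg / as.vector(counts)[match(rownames(agg), names(counts))]
  tibble::as_tibble(agg, rownames = "collection_id")
}

#' One-call preprocessing chain
#'
#' filter -> KNN impute -> drift-correction selection -> optional
#' replicate-outlier removal -> log-standardize and average.
#'
#' @param table A [feature_table()].
#' @param max_undetected,k,proportion_min,n_outlier_remove,seed Stage
#'   parameters; `n_outlier_remove = 0` (default) skips outlier screening,
#'   appropriate when collections have few replicates.
#' @return A list: `matrix` (collection x feature tibble), `table`
#'   (corrected feature table), `linear_means` (collection x feature tibble
#'   of linear-scale replicate means, for fold changes), `correction`
#'   (output of [select_correction()]).
#' @export
preprocess_pipeline <- function(table, max_undetected = 0.80, k = 10,
                                proportion_min = 0.70, n_outlier_remove = 0,
                                seed = 1) {
  ft <- filter_features(table, max_undetected)
  ft <- impute_knn(ft, k = k)
  corr <- select_correction(ft, proportion_min = proportion_min,
                            seed = stage_seed(seed, "correction"))
  ft <- corr$table
  if (n_outlier_remove > 0) {
    ft <- remove_replicate_outliers(ft, n_remove = n_outlier_remove)
  }
  x <- log_standardize_and_average(ft)
  bio <- ft$sample_meta$role == "biological"
  counts <- base::table(ft$sample_meta$collection_id[bio])
  lm_m <- rowsum(ft$intensities[bio, , drop = FALSE],
                 ft$sample_meta$collection_id[bio])
  lm_m <- lm_m / as.vector(counts)[match(rownames(lm_m), names(counts))]
  list(matrix = x, table = ft,
       linear_means = tibble::as_tibble(lm_m, rownames = "collection_id"),
       correction = corr)
}
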