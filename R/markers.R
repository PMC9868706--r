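#' Fold change of one chemotype against the rest
#'
#' Computed on linear-scale (pre-log) collection-mean intensities:
#' fc = mean(group) / mean(rest), log2fc = log2(fc).
#'
#' @param linear_means Collection x feature tibble (with `collection_id`)
#'   or matrix of linear-scale mean intensities.
#' @param group_mask Logical vector over collections: TRUE = chemotype
#'   group, FALSE = rest. Both groups must be non-empty.
#' @return A tibble: feature_id, fc, log2fc.
#' @export
fold_change <- function(linear_means, group_mask) {
  m <- as_collection_matrix(linear_means)
  stopifnot(length(group_mask) == nrow(m))
  if (!any(group_mask) || all(group_mask)) abort("both groups must be non-empty.")
  mg <- unname(colMeans(m[group_mask, , drop = FALSE]))
  mr <- unname(colMeans(m[!group_mask, , drop = FALSE]))
  if (any(mr == 0)) abort("zero rest-group mean; fold change undefined.")
  tibble::tibble(feature_id = colnames(m), fc = mg / mr,
                 log2fc = log2(mg / mr))
}

#' Per-feature two-sided Student's t-test
#'
#' Pooled-variance (Student's) two-sample t-test of each feature between a
#' chemotype group and the rest, with exact p-values from the t
#' distribution. Features with zero pooled variance (identical values in
#' both groups) are reported with p = 1 and flagged.
#'
#' @param x Standardized collection matrix.
#' @param group_mask Logical group indicator over collections.
#' @param welch Use Welch's unequal-variance test instead (default FALSE).
#' @return A tibble: feature_id, statistic, p_value, zero_variance flag.
#' @export
feature_t_test <- function(x, group_mask, welch = FALSE) {
  m <- as_collection_matrix(x)
  stopifnot(length(group_mask) == nrow(m))
  n1 <- sum(group_mask); n2 <- sum(!group_mask)
  if (n1 < 2 || n2 < 2) abort("both groups need at least 2 collections.")
  m1 <- colMeans(m[group_mask, , drop = FALSE])
  m2 <- colMeans(m[!group_mask, , drop = FALSE])
  v1 <- col_vars(m[group_mask, , drop = FALSE])
  v2 <- col_vars(m[!group_mask, , drop = FALSE])
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, ncol(m))
  }
  zero_var <- se2 <= 0 | !is.finite(se2)
  stat <- ifelse(zero_var, 0, (m1 - m2) / sqrt(se2))
  p <- ifelse(zero_var, 1, 2 * pt(-abs(stat), df))
  tibble::tibble(feature_id = colnames(m), statistic = unname(stat),
                 p_value = unname(p), zero_variance = unname(zero_var))
}

#' Random-forest mean decrease accuracy per feature
#'
#' Permutation importance from a random-forest classifier of the group
#' indicator: the per-tree out-of-bag accuracy drop when a feature is
#' permuted, averaged over trees and divided by its standard error (the
#' z-like scaled convention under which a >= 2 threshold is meaningful).
#'
#' @param x Collection matrix.
#' @param group_mask Logical group indicator (one-vs-rest), or a factor
#'   for multi-class importance.
#' @param n_trees Trees (default 1000).
#' @param seed Integer seed.
#' @return A tibble: feature_id, mda.
#' @export
rf_mda <- function(x, group_mask, n_trees = 1000, seed = 1) {
  m <- as_collection_matrix(x)
  y <- if (is.logical(group_mask)) factor(ifelse(group_mask, "group", "rest"))
       else factor(group_mask)
  stopifnot(length(y) == nrow(m))
  set.seed(seed)
  fit <- randomForest::randomForest(x = m, y = y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)
  tibble::tibble(feature_id = colnames(m), mda = unname(imp[, 1]))
}

default_marker_thresholds <- function() {
  list(vip = 2, p = 0.05, log2fc = 0.5, mda = 2)
}

#' Four-criterion chemomarker screen
#'
#' A feature is a chemomarker of a chemotype iff it jointly satisfies:
#' VIP >= 2 (inclusive), Student's t-test p < 0.05, |log2 fold change| >
#' 0.5, and scaled mean decrease accuracy >= 2. Direction is the sign of
#' log2fc. The fold-change criterion is interpreted two-sided on the log2
#' scale (matching volcano plots and the existence of down-regulated
#' markers); the literal raw-ratio rule (`fc > 0.5`) is available via
#' `fc_rule = "raw"`.
#'
#' @param vip,p,fc,mda Tibbles as returned by [opls_fit()] VIPs
#'   (`tidy()`), [feature_t_test()], [fold_change()] and [rf_mda()]; all
#'   must cover the same feature set.
#' @param thresholds Named list overriding `vip`, `p`, `log2fc`, `mda`.
#' @param fc_rule "log2" (default) or "raw".
#' @param chemotype Label stored in the output records.
#' @return A marker-record tibble: feature_id, chemotype, vip, p_value,
#'   fc, log2fc, mda, per-criterion pass flags, `marker` (joint pass) and
#'   `direction`.
#' @export
screen_markers <- function(vip, p, fc, mda,
                           thresholds = list(), fc_rule = c("log2", "raw"),
                           chemotype = NA) {
  fc_rule <- match.arg(fc_rule)
  th <- utils::modifyList(default_marker_thresholds(), thresholds)
  ids <- vip$feature_id
  if (!setequal(ids, p$feature_id) || !setequal(ids, fc$feature_id) ||
      !setequal(ids, mda$feature_id)) {
    abort("the four statistics must cover the same feature set.")
  }
  fc_v <- fc$fc[match(ids, fc$feature_id)]
  log2fc_v <- fc$log2fc[match(ids, fc$feature_id)]
  rec <- tibble::tibble(feature_id = ids, chemotype = chemotype,
                        vip = vip$vip,
                        p_value = p$p_value[match(ids, p$feature_id)],
                        fc = fc_v, log2fc = log2fc_v,
                        mda = mda$mda[match(ids, mda$feature_id)])
  rec$pass_vip <- rec$vip >= th$vip
  rec$pass_p <- rec$p_value < th$p
  rec$pass_fc <- if (fc_rule == "log2") abs(rec$log2fc) > th$log2fc else
    rec$fc > 0.5
  rec$pass_mda <- rec$mda >= th$mda
  rec$marker <- rec$pass_vip & rec$pass_p & rec$pass_fc & rec$pass_mda
  rec$direction <- ifelse(rec$log2fc > 0, "up", "down")
  rec
}

#' Screen chemomarkers for every chemotype
#'
#' Runs the full per-chemotype one-vs-rest battery — OPLS-DA VIP,
#' Student's t-test, linear-scale fold change, RF mean decrease accuracy —
#' and applies the joint four-criterion screen.
#'
#' @param x Standardized collection matrix.
#' @param linear_means Linear-scale collection-mean tibble/matrix (for
#'   fold changes).
#' @param assignment A `chemotype_assignment`.
#' @param n_trees RF trees (default 1000).
#' @param n_orth Orthogonal OPLS components (default 1).
#' @param thresholds,fc_rule Passed to [screen_markers()].
#' @param seed Integer seed.
#' @return A marker-record tibble over all chemotypes (one row per
#'   feature x chemotype) with an `exclusive` flag on marker rows.
#' @export
screen_chemomarkers <- function(x, linear_means, assignment, n_trees = 1000,
                                n_orth = 1, thresholds = list(),
                                fc_rule = "log2", seed = 1) {
  m <- as_collection_matrix(x)
  labels <- extract_labels(assignment, rownames(m))
  recs <- purrr::map_dfr(sort(unique(labels)), function(cc) {
    mask <- labels == cc
    if (min(sum(mask), sum(!mask)) < 2) {
      warn(sprintf("chemotype %s has fewer than 2 collections; skipping its screen.", cc))
      return(NULL)
    }
    cv <- max(2, min(7, sum(mask), sum(!mask)))
    fit <- opls_fit(m, ifelse(mask, 1, -1), n_orth = n_orth, cv_folds = cv,
                    seed = stage_seed(seed, paste0("opls_", cc)))
    screen_markers(
      vip = tibble::tibble(feature_id = names(fit$vip), vip = unname(fit$vip)),
      p = feature_t_test(m, mask),
      fc = fold_change(linear_means, mask),
      mda = rf_mda(m, mask, n_trees = n_trees,
                   seed = stage_seed(seed, paste0("mda_", cc))),
      thresholds = thresholds, fc_rule = fc_rule, chemotype = cc)
  })
  marker_sets <- recs |>
    dplyr::filter(.data$marker) |>
    dplyr::count(.data$feature_id, name = "n_chemotypes")
  recs$exclusive <- recs$marker &
    recs$feature_id %in% marker_sets$feature_id[marker_sets$n_chemotypes == 1]
  recs
}

#' Venn partition of per-chemotype marker sets
#'
#' @param markers Marker-record tibble from [screen_chemomarkers()] (only
#'   `marker` rows are used), or a list of feature-id character vectors.
#' @return A tibble: feature_id, chemotypes (comma-joined membership),
#'   n_chemotypes, exclusive.
#' @export
exclusive_markers <- function(markers) {
  sets <- if (is.data.frame(markers)) {
    mk <- dplyr::filter(markers, .data$marker)
    split(mk$feature_id, mk$chemotype)
  } else markers
  all_feats <- sort(unique(unlist(sets)))
  membership <- purrr::map(all_feats, function(f) {
    names(sets)[purrr::map_lgl(sets, ~ f %in% .x)]
  })
  tibble::tibble(
    feature_id = all_feats,
    chemotypes = purrr::map_chr(membership, paste, collapse = ","),
    n_chemotypes = lengths(membership),
    exclusive = lengths(membership) == 1
  )
}

#' Validate screened markers with the RF discriminant protocol
#'
#' Re-runs [rf_discriminant_eval()] on the matrix restricted to the union
#' of screened markers — the check that the marker panel alone still
#' separates the chemotypes.
#'
#' @param x Standardized collection matrix.
#' @param markers Marker-record tibble (rows with `marker = TRUE` are used)
#'   or a character vector of feature ids.
#' @param assignment Labels as in [rf_discriminant_eval()].
#' @param ... Passed to [rf_discriminant_eval()].
#' @return An `rf_eval`.
#' @export
marker_validation <- function(x, markers, assignment, ...) {
  ids <- if (is.data.frame(markers)) {
    unique(markers$feature_id[markers$marker])
  } else unique(markers)
  if (length(ids) == 0) abort("empty marker set.")
  m <- as_collection_matrix(x)
  rf_discriminant_eval(m[, intersect(colnames(m), ids), drop = FALSE],
                       assignment, ...)
}

#' Volcano export table
#'
#' @param markers Marker-record tibble for one chemotype (from
#'   [screen_markers()]).
#' @return A plot-ready tibble: feature_id, log2fc, neg_log10_p, marker.
#' @export
volcano_table <- function(markers) {
  tibble::tibble(feature_id = markers$feature_id,
                 log2fc = markers$log2fc,
                 neg_log10_p = -log10(markers$p_value),
                 marker = markers$marker)
}

#' Volcano plot of one chemotype's screen
#'
#' @param markers Marker-record tibble for one chemotype.
#' @return A ggplot object.
#' @export
plot_volcano <- function(markers) {
  df <- volcano_table(markers)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   color = .data$marker)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = "marker") +
    ggplot2::theme_minimal()
}

#' Score screened markers against planted ground truth
#'
#' One-vs-rest screening legitimately re-detects a chemotype's planted
#' up-markers as down-markers of the other chemotypes (their rest-group
#' mean is inflated), so recovery is scored at two levels: sensitivity
#' counts planted (chemotype, feature, up) triples recovered as up-markers
#' of their own chemotype; precision counts a screened record as correct
#' when its feature is a planted marker of some chemotype and the observed
#' direction is consistent with that planting (up in its own chemotype,
#' down elsewhere).
#'
#' @param markers Marker-record tibble from [screen_chemomarkers()].
#' @param truth Ground truth from [generate_dataset()] (uses
#'   `truth$markers`).
#' @return A one-row tibble: n_screened, n_planted, sensitivity, precision.
#' @export
marker_recovery <- function(markers, truth) {
  planted <- truth$markers
  screened <- dplyr::filter(markers, .data$marker)
  hit <- dplyr::inner_join(
    screened, planted,
    by = c("feature_id", "chemotype"), suffix = c("", "_true"))
  sens <- sum(hit$direction == hit$direction_true) / nrow(planted)
  own <- paste(planted$chemotype, planted$feature_id)
  correct <- purrr::map_lgl(seq_len(nrow(screened)), function(i) {
    f <- screened$feature_id[i]
    if (!f %in% planted$feature_id) return(FALSE)
    own_chem <- planted$chemotype[planted$feature_id == f]
    if (screened$chemotype[i] %in% own_chem) screened$direction[i] == "up"
    else screened$direction[i] == "down"
  })
  tibble::tibble(n_screened = nrow(screened), n_planted = nrow(planted),
                 sensitivity = sens,
                 precision = if (nrow(screened) == 0) NA_real_ else mean(correct))
}
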