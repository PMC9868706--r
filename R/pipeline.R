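#' Run the full chemotyping pipeline
#'
#' Orchestrates the analysis end to end on a feature table (and optional
#' trait table): preprocessing (filter, impute, QC drift-correction
#' selection, standardize), gap-statistic model selection, SOM and K-means
#' candidate classifications adjudicated by the RF discriminant protocol,
#' four-criterion chemomarker screening, and — when traits are supplied —
#' co-expression module detection, module-trait correlation, morphological
#' marker selection and LASSO trait predictability. Every stage draws its
#' seed deterministically from the global seed.
#'
#' @param table A [feature_table()] (e.g. from [generate_dataset()] or
#'   [read_feature_table()]).
#' @param traits Optional trait tibble (`collection_id` + trait columns).
#' @param seed Global integer seed.
#' @param k Number of chemotypes, or "auto" (default) to take the
#'   gap-statistic choice (floored at 2 for classification).
#' @param candidate_ks Cluster counts evaluated in the SOM-vs-K-means
#'   adjudication table (default `c(4, 5, 6)`).
#' @param som_rows,som_cols,som_epochs SOM settings (default 7 x 7, 100).
#' @param n_trees RF trees (default 1000).
#' @param rf_repeats Repeated stratified splits per RF evaluation
#'   (default 5).
#' @param gap_k_range,gap_B Gap-statistic settings.
#' @param n_outlier_remove Replicate outliers to drop per collection
#'   during preprocessing (default 0 = skip).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON.
#' @return A `chemotype_run` list with elements `preprocess`, `gap`,
#'   `som`, `assignment`, `candidates`, `comparison`, `markers`,
#'   `marker_eval`, `exclusivity`, and (with traits) `modules`, `mt_cor`,
#'   `morph_markers`, `predictability`, `trait_anova`, plus a `manifest`
#'   of stage seeds and timings.
#' @export
run_chemotyping <- function(table, traits = NULL, seed = 1, k = "auto",
                            candidate_ks = c(4, 5, 6),
                            som_rows = 7, som_cols = 7, som_epochs = 100,
                            n_trees = 1000, rf_repeats = 5,
                            gap_k_range = 1:10, gap_B = 50,
                            n_outlier_remove = 0, out_dir = NULL) {
  manifest <- list(seed = seed, stages = list())
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(seed, stage),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  pre <- tick("preprocess", preprocess_pipeline(
    table, n_outlier_remove = n_outlier_remove,
    seed = stage_seed(seed, "preprocess")))
  x <- pre$matrix

  gap <- tick("gap", gap_statistic(x, k_range = gap_k_range, B = gap_B,
                                   seed = stage_seed(seed, "gap")))
  k_use <- if (identical(k, "auto")) max(2L, gap$k_hat) else as.integer(k)

  som <- tick("som", train_som(x, rows = som_rows, cols = som_cols,
                               n_epochs = som_epochs,
                               seed = stage_seed(seed, "som")))

  candidates <- list()
  for (kk in sort(unique(c(candidate_ks, k_use)))) {
    candidates[[paste0("som_k", kk)]] <-
      assign_chemotypes(cluster_codebook(som, kk), x)
    candidates[[paste0("kmeans_k", kk)]] <-
      kmeans_classify(x, kk, seed = stage_seed(seed, paste0("kmeans", kk)))
  }
  # the RF protocol needs >= 2 collections per class; drop candidates
  # with singleton classes from the comparison (they stay assignable)
  evaluable <- purrr::map_lgl(candidates, function(a) {
    min(base::table(a$chemotype)) >= 2
  })
  if (!all(evaluable)) {
    warn(sprintf("dropping %d candidate(s) with singleton classes from the comparison: %s",
                 sum(!evaluable),
                 paste(names(candidates)[!evaluable], collapse = ", ")))
  }
  comparison <- tick("evaluate", compare_classifications(
    x, candidates[evaluable], n_trees = n_trees, n_repeats = rf_repeats,
    seed = stage_seed(seed, "evaluate")))
  if (!evaluable[[paste0("som_k", k_use)]]) {
    ok_som <- names(candidates)[evaluable & grepl("^som_k", names(candidates))]
    if (length(ok_som) == 0) abort("no SOM candidate has >= 2 collections per class.")
    k_fallback <- max(as.integer(sub("^som_k", "", ok_som)))
    warn(sprintf("SOM at k = %d has singleton classes; using k = %d instead.",
                 k_use, k_fallback))
    k_use <- k_fallback
  }
  assignment <- candidates[[paste0("som_k", k_use)]]

  markers <- tick("markers", screen_chemomarkers(
    x, pre$linear_means, assignment, n_trees = n_trees,
    seed = stage_seed(seed, "markers")))
  exclusivity <- exclusive_markers(markers)
  marker_eval <- if (any(markers$marker)) {
    tick("marker_eval", marker_validation(
      x, markers, assignment, n_trees = n_trees, n_repeats = rf_repeats,
      seed = stage_seed(seed, "marker_eval")))
  } else NULL

  run <- list(preprocess = pre, gap = gap, som = som,
              assignment = assignment, candidates = candidates,
              comparison = comparison, markers = markers,
              exclusivity = exclusivity, marker_eval = marker_eval,
              k = k_use)

  if (!is.null(traits)) {
    traits <- validate_trait_table(traits)
    st <- tick("soft_threshold", pick_soft_threshold(x))
    mods <- tick("modules", detect_modules(x, beta = st$beta))
    run$soft_threshold <- st
    run$modules <- mods
    if (!is.null(mods$eigenmetabolites)) {
      run$mt_cor <- module_trait_correlation(mods, traits)
      run$morph_markers <- select_morph_markers(markers, mods, run$mt_cor)
    }
    run$predictability <- tick("lasso", {
      purrr::map_dfr(setdiff(names(traits), "collection_id"), function(tr) {
        fit <- lasso_predictability(x, traits, trait_name = tr,
                                    seed = stage_seed(seed, paste0("lasso_", tr)))
        glance(fit)
      })
    })
    run$trait_anova <- anova_traits(traits, assignment)
  }
  run$manifest <- manifest
  class(run) <- "chemotype_run"

  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$assignment, file.path(out_dir, "assignment.tsv"))
  readr::write_tsv(run$gap$curve, file.path(out_dir, "gap_curve.tsv"))
  readr::write_tsv(run$comparison, file.path(out_dir, "classification_comparison.tsv"))
  readr::write_tsv(run$markers, file.path(out_dir, "marker_records.tsv"))
  readr::write_tsv(run$exclusivity, file.path(out_dir, "marker_venn.tsv"))
  readr::write_tsv(run$preprocess$correction$summary,
                   file.path(out_dir, "correction_summary.tsv"))
  if (!is.null(run$mt_cor)) {
    readr::write_tsv(run$mt_cor, file.path(out_dir, "module_trait_cor.tsv"))
    readr::write_tsv(run$modules$modules, file.path(out_dir, "modules.tsv"))
    readr::write_tsv(run$morph_markers, file.path(out_dir, "morph_markers.tsv"))
    readr::write_tsv(run$predictability, file.path(out_dir, "trait_predictability.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.chemotype_run <- function(x, ...) {
  cat(sprintf("<chemotype_run> k = %d chemotypes (gap selected %d)\n",
              x$k, x$gap$k_hat))
  cat(sprintf("  drift correction: %s (reserved fraction %.2f)\n",
              x$preprocess$correction$selected,
              x$preprocess$correction$summary$reserved_fraction[
                x$preprocess$correction$summary$selected]))
  cat(sprintf("  chemotype sizes: %s\n",
              paste(base::table(x$assignment$chemotype), collapse = ", ")))
  cat(sprintf("  markers: %d (%d exclusive)\n",
              sum(x$markers$marker), sum(x$exclusivity$exclusive)))
  invisible(x)
}

#' Summarize a pipeline run as a text report
#'
#' The headline skeleton of a chemotyping analysis: the drift-correction
#' adjudication, the selected k, the classification-comparison table,
#' chemotype sizes, marker counts and exclusivity, and (when traits were
#' supplied) per-chemotype morphological markers and trait
#' predictabilities.
#'
#' @param run A `chemotype_run` from [run_chemotyping()].
#' @param truth Optional ground truth from [generate_dataset()]; adds
#'   recovery metrics (ARI, marker sensitivity/precision).
#' @return A character vector of report lines (invisibly printed with
#'   `cat`).
#' @export
chemotype_report <- function(run, truth = NULL) {
  co <- run$comparison
  lines <- c(
    "== Chemotyping run report ==",
    sprintf("Drift correction: %s selected; reserved fractions: %s",
            run$preprocess$correction$selected,
            paste(sprintf("%s %.2f", run$preprocess$correction$summary$method,
                          run$preprocess$correction$summary$reserved_fraction),
                  collapse = ", ")),
    sprintf("Gap statistic selected k = %d; run used k = %d",
            run$gap$k_hat, run$k),
    "Classification comparison (mean of train/test accuracy):",
    paste(sprintf("  %-12s %5.1f%%%s", co$name, 100 * co$mean_accuracy,
                  ifelse(co$winner, "  <- winner", "")), collapse = "\n"),
    sprintf("Chemotype sizes: %s",
            paste(base::table(run$assignment$chemotype), collapse = ", ")),
    sprintf("Markers: %d total (%s per chemotype), %d exclusive",
            sum(run$markers$marker),
            paste(base::table(run$markers$chemotype[run$markers$marker]),
                  collapse = ", "),
            sum(run$exclusivity$exclusive))
  )
  if (!is.null(run$morph_markers)) {
    lines <- c(lines, "Morphological markers:",
               paste(sprintf("  chemotype %s -> %s (module %s, r = %.2f)",
                             run$morph_markers$chemotype,
                             run$morph_markers$trait,
                             run$morph_markers$module,
                             run$morph_markers$r), collapse = "\n"))
  }
  if (!is.null(run$predictability)) {
    lines <- c(lines, sprintf("Mean LASSO trait predictability: %.4f",
                              mean(run$predictability$predictability)))
  }
  if (!is.null(truth)) {
    ari <- adjusted_rand_index(
      truth$chemotype_of[run$assignment$collection_id],
      run$assignment$chemotype)
    rec <- marker_recovery(run$markers, truth)
    lines <- c(lines,
               sprintf("Recovery vs ground truth: ARI = %.3f; marker sensitivity %.2f, precision %.2f",
                       ari, rec$sensitivity, rec$precision))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
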