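#' Construct a feature table
#'
#' The pipeline's universal currency: a sample-by-feature intensity matrix
#' (arbitrary instrument units, missing values allowed) plus per-sample and
#' per-feature metadata. Samples are biological injections or pooled QC
#' injections; the QC/biological split and the injection order drive drift
#' correction downstream.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids. `NA` marks a
#'   missing (undetected) cell; negative values are rejected.
#' @param sample_meta Data frame with one row per sample: `sample_id`,
#'   `role` ("biological" or "qc"), `injection_order` (positive integer,
#'   unique within a platform), `collection_id`, `replicate_id`,
#'   `platform` (one of "gcms", "lcms_pos", "lcms_neg", "merged").
#' @param feature_meta Optional data frame with one row per feature:
#'   `feature_id`, `name`, `category`. Defaults to ids only.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_meta, feature_meta = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_meta <- tibble::as_tibble(sample_meta)
  if (is.null(feature_meta)) {
    feature_meta <- tibble::tibble(
      feature_id = colnames(intensities),
      name = colnames(intensities),
      category = NA_character_
    )
  }
  feature_meta <- tibble::as_tibble(feature_meta)
  ft <- structure(
    list(intensities = intensities, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table"
  )
  validate_feature_table(ft)
}

validate_feature_table <- function(ft) {
  m <- ft$intensities
  sm <- ft$sample_meta
  fm <- ft$feature_meta
  required <- c("sample_id", "role", "injection_order", "collection_id",
                "replicate_id", "platform")
  missing_cols <- setdiff(required, names(sm))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample metadata is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "chemotyper_schema_error")
  }
  if (!"feature_id" %in% names(fm)) {
    abort("feature metadata must contain `feature_id`.",
          class = "chemotyper_schema_error")
  }
  dup_s <- unique(sm$sample_id[duplicated(sm$sample_id)])
  if (length(dup_s) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(dup_s, collapse = ", ")),
          class = "chemotyper_validation_error")
  }
  dup_f <- unique(fm$feature_id[duplicated(fm$feature_id)])
  if (length(dup_f) > 0) {
    abort(sprintf("duplicate feature id(s): %s", paste(dup_f, collapse = ", ")),
          class = "chemotyper_validation_error")
  }
  if (nrow(sm) != nrow(m) || nrow(fm) != ncol(m)) {
    abort("metadata dimensions do not match the intensity matrix.",
          class = "chemotyper_validation_error")
  }
  if (!all(sm$role %in% c("biological", "qc"))) {
    abort("`role` must be 'biological' or 'qc'.",
          class = "chemotyper_validation_error")
  }
  if (!all(sm$platform %in% c("gcms", "lcms_pos", "lcms_neg", "merged"))) {
    abort("unknown platform tag.", class = "chemotyper_validation_error")
  }
  if (any(sm$injection_order <= 0 | sm$injection_order != round(sm$injection_order))) {
    abort("`injection_order` must be positive integers.",
          class = "chemotyper_validation_error")
  }
  dup_ord <- sm |>
    dplyr::count(.data$platform, .data$injection_order) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_ord) > 0) {
    abort("injection order must be unique within a platform.",
          class = "chemotyper_validation_error")
  }
  obs <- m[!is.na(m)]
  if (any(!is.finite(obs))) {
    abort("intensities must be finite or missing.",
          class = "chemotyper_validation_error")
  }
  if (any(obs < 0)) {
    abort("negative intensities are not allowed.",
          class = "chemotyper_validation_error")
  }
  rownames(ft$intensities) <- sm$sample_id
  colnames(ft$intensities) <- fm$feature_id
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  m <- x$intensities
  n_qc <- sum(x$sample_meta$role == "qc")
  cat(sprintf(
    "<feature_table> %d samples (%d biological, %d QC) x %d features; %d missing cells\n",
    nrow(m), nrow(m) - n_qc, n_qc, ncol(m), sum(is.na(m))))
  cat("platforms:", paste(unique(x$sample_meta$platform), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Number of samples / features in a feature table
#' @param ft A [feature_table()].
#' @return Integer count.
#' @export
n_samples <- function(ft) nrow(ft$intensities)

#' @rdname n_samples
#' @export
n_features <- function(ft) ncol(ft$intensities)

#' Tidy view of a feature table
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A long tibble (sample_id, feature_id, intensity) joined with the
#'   sample metadata; missing cells carried as `NA`.
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::as_tibble(x$intensities, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "intensity")
  dplyr::left_join(long, x$sample_meta, by = "sample_id")
}

#' Subset a feature table by samples and/or features
#'
#' @param ft A [feature_table()].
#' @param samples,features Logical, integer or character index vectors
#'   (default: keep all).
#' @return A [feature_table()].
#' @export
subset_feature_table <- function(ft, samples = NULL, features = NULL) {
  s_idx <- samples %||% seq_len(n_samples(ft))
  if (is.character(s_idx)) s_idx <- match(s_idx, ft$sample_meta$sample_id)
  f_idx <- features %||% seq_len(n_features(ft))
  if (is.character(f_idx)) f_idx <- match(f_idx, ft$feature_meta$feature_id)
  feature_table(ft$intensities[s_idx, f_idx, drop = FALSE],
                ft$sample_meta[s_idx, , drop = FALSE],
                ft$feature_meta[f_idx, , drop = FALSE])
}

sample_meta_cols <- c("sample_id", "role", "injection_order",
                      "collection_id", "replicate_id", "platform")

#' Read / write a feature table
#'
#' Flat-file interchange format: samples as rows; the first six columns are
#' the sample metadata (`sample_id`, `role`, `injection_order`,
#' `collection_id`, `replicate_id`, `platform`), every remaining column one
#' feature. Empty cells are missing values; zeros are measured values.
#'
#' @param path File path.
#' @param dialect "csv" or "tsv".
#' @return `read_feature_table()` returns a validated [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(sample_meta_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing metadata column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "chemotyper_schema_error")
  }
  feat_cols <- setdiff(names(df), sample_meta_cols)
  if (length(feat_cols) == 0) abort("no feature columns found.")
  m <- as.matrix(df[feat_cols])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  feature_table(m, df[sample_meta_cols])
}

#' @rdname read_feature_table
#' @param ft A [feature_table()] to write.
#' @export
write_feature_table <- function(ft, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  df <- dplyr::bind_cols(ft$sample_meta[sample_meta_cols],
                         tibble::as_tibble(ft$intensities))
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Merge per-platform feature tables into one
#'
#' Stacks tables column-wise on their shared collections and resolves
#' metabolites annotated on more than one platform: when two features carry
#' the same annotation `name`, the copy with the lower QC RSD (the more
#' reproducible measurement) is kept; ties keep the LC-MS/MS copy. The
#' provenance of the kept copy is recorded in `feature_meta$source_platform`.
#'
#' Samples keep their rows but are re-tagged with platform-suffixed sample
#' ids so injection orders stay interpretable per platform.
#'
#' @param tables List of [feature_table()] objects (one per platform).
#' @param qc_rsd Named numeric vector mapping feature id to its QC RSD,
#'   used to adjudicate duplicate annotations. Features absent from the map
#'   are treated as RSD `Inf` (least reproducible).
#' @return A merged [feature_table()] whose features are unique by name.
#' @export
merge_platform_tables <- function(tables, qc_rsd = NULL) {
  if (length(tables) == 0) abort("empty table list.")
  if (length(tables) == 1) return(tables[[1]])
  qc_rsd <- qc_rsd %||% setNames(numeric(0), character(0))

  # candidate features across all tables, one row per (table, feature)
  cand <- purrr::imap_dfr(tables, function(ft, i) {
    fm <- ft$feature_meta
    tibble::tibble(
      table = i,
      feature_id = fm$feature_id,
      name = if ("name" %in% names(fm)) fm$name else fm$feature_id,
      platform = ft$sample_meta$platform[1],
      rsd = unname(qc_rsd[fm$feature_id])
    )
  })
  cand$rsd[is.na(cand$rsd)] <- Inf
  # lower QC RSD wins; tie -> LC-MS/MS copy
  cand <- cand |>
    dplyr::mutate(lcms = .data$platform %in% c("lcms_pos", "lcms_neg")) |>
    dplyr::arrange(.data$name, .data$rsd, dplyr::desc(.data$lcms)) |>
    dplyr::distinct(.data$name, .keep_all = TRUE)

  sample_key <- function(ft) paste(ft$sample_meta$collection_id,
                                   ft$sample_meta$replicate_id,
                                   ft$sample_meta$role, sep = "\r")
  keys <- sample_key(tables[[1]])
  for (ft in tables[-1]) {
    if (!setequal(unique(tables[[1]]$sample_meta$collection_id),
                  unique(ft$sample_meta$collection_id))) {
      abort("tables do not cover the same collections.")
    }
  }
  blocks <- purrr::imap(tables, function(ft, i) {
    keep <- cand$feature_id[cand$table == i]
    idx <- match(keys, sample_key(ft))
    if (any(is.na(idx))) abort("tables do not share a common sample layout.")
    ft$intensities[idx, keep, drop = FALSE]
  })
  m <- do.call(cbind, blocks)

  fm <- purrr::imap_dfr(tables, function(ft, i) {
    keep <- cand$feature_id[cand$table == i]
    ft$feature_meta |>
      dplyr::filter(.data$feature_id %in% keep) |>
      dplyr::mutate(source_platform = ft$sample_meta$platform[1])
  })
  fm <- fm[match(colnames(m), fm$feature_id), ]

  sm <- tables[[1]]$sample_meta
  sm$platform <- "merged"
  feature_table(m, sm, fm)
}
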