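#' Read / write a collection-by-trait table
#'
#' Leaf morphology traits, one row per collection, columns drawn from the
#' fixed 13-trait vocabulary (LL, LTWR, LDH, LDW, LDN, LW, LA, CRV, LP, LT,
#' SL, SLFW, SLDW). The loader is strict: unknown trait columns and missing
#' cells are rejected rather than silently imputed.
#'
#' @param path File path.
#' @param dialect "csv" or "tsv".
#' @return A tibble with `collection_id` plus trait columns.
#' @export
read_trait_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_trait_table(df)
}

#' @rdname read_trait_table
#' @param traits A trait tibble as returned by [read_trait_table()].
#' @export
write_trait_table <- function(traits, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(traits, path, progress = FALSE)
  invisible(path)
}

validate_trait_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"collection_id" %in% names(df)) {
    abort("trait table must contain `collection_id`.",
          class = "chemotyper_schema_error")
  }
  unknown <- setdiff(names(df), c("collection_id", TRAIT_VOCABULARY))
  if (length(unknown) > 0) {
    abort(sprintf("unknown trait column(s): %s", paste(unknown, collapse = ", ")),
          class = "chemotyper_schema_error")
  }
  dup <- unique(df$collection_id[duplicated(df$collection_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate collection id(s): %s", paste(dup, collapse = ", ")),
          class = "chemotyper_validation_error")
  }
  if (anyNA(df)) {
    abort("trait table contains missing values; traits must be complete.",
          class = "chemotyper_validation_error")
  }
  df$collection_id <- as.character(df$collection_id)
  df
}
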