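#' Configuration for the synthetic leaf-metabolome generator
#'
#' The generator emulates the statistical structure of a large untargeted
#' leaf-metabolomics screen of clonally replicated germplasm collections:
#' a few latent chemotypes carrying group-specific marker metabolites,
#' correlated metabolite modules whose latent factors drive morphology
#' traits, smooth injection-order drift monitored by pooled-QC injections,
#' and abundance-linked missingness.
#'
#' Intensities are built multiplicatively on the natural-log scale:
#' baseline x chemotype marker effect (2^(+/-log2fc)) x module latent-factor
#' effect x drift(injection order) x log-normal replicate noise. QC samples
#' are the pooled mean of the expected biological profiles (zero chemotype
#' signal) with technical noise only.
#'
#' @param n_collections Number of collections (default 160).
#' @param n_replicates Clonal replicates per collection (default 3).
#' @param n_features Number of annotated features (default 600).
#' @param chemotype_sizes Integer vector of collections per chemotype,
#'   summing to `n_collections` (default `c(60, 50, 30, 20)`).
#' @param markers_per_chemotype Planted up-regulated markers per chemotype
#'   (default 25). Markers are disjoint across chemotypes and live inside
#'   that chemotype's metabolite module.
#' @param marker_log2fc Log2 fold change of a marker in its chemotype
#'   (default 1).
#' @param baseline_meanlog,baseline_sdlog Location/scale of per-feature
#'   log-normal baselines (natural-log units).
#' @param noise_sd Biological replicate noise sd, natural-log scale
#'   (default 0.25, about 25% CV).
#' @param qc_noise_sd Technical noise sd of QC injections (default 0.10).
#' @param module_sd Scale of the module latent-factor effect in ln units.
#'   The default 0.1 keeps module variation a secondary structure so the
#'   planted chemotypes dominate the standardized matrix; module-focused
#'   studies should raise it to ~0.5, at which the realized
#'   collection-level intra-module correlation approaches
#'   `intra_module_cor`.
#' @param drift_amplitude Drift magnitude as a fraction of baseline
#'   (default 0.2).
#' @param drift_smoothness Mixing weight of the monotone trend vs the
#'   low-frequency random-walk component, in \[0, 1\] (default 0.5).
#' @param qc_interval One pooled-QC injection after every `qc_interval`
#'   biological injections (default 10); one more QC opens the run.
#' @param missing_rate Overall fraction of masked cells (default 0.15);
#'   half MCAR, half preferentially in the lowest-intensity decile.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules (defaults 5 and 40).
#' @param intra_module_cor Target correlation of features within a module
#'   at the collection level (default 0.7), set via factor loading
#'   `sqrt(intra_module_cor)`.
#' @param trait_links Tibble with columns `module`, `trait`, `coef`,
#'   `noise_sd`: each linked trait is `coef` x module latent factor +
#'   Gaussian noise. Default links modules 1-4 to LL, CRV, LDH, LT with
#'   coefficient 0.75 against unit noise (true r = 0.6). Unlinked traits
#'   are standard-normal noise.
#' @param platform Platform tag written to the sample metadata.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_collections = 160,
                         n_replicates = 3,
                         n_features = 600,
                         chemotype_sizes = c(60, 50, 30, 20),
                         markers_per_chemotype = 25,
                         marker_log2fc = 1,
                         baseline_meanlog = log(1e5),
                         baseline_sdlog = 1,
                         noise_sd = 0.25,
                         qc_noise_sd = 0.10,
                         module_sd = 0.1,
                         drift_amplitude = 0.2,
                         drift_smoothness = 0.5,
                         qc_interval = 10,
                         missing_rate = 0.15,
                         n_modules = 5,
                         module_size = 40,
                         intra_module_cor = 0.7,
                         trait_links = NULL,
                         platform = "lcms_pos",
                         seed = 1) {
  trait_links <- trait_links %||% tibble::tibble(
    module = 1:4, trait = c("LL", "CRV", "LDH", "LT"),
    coef = 0.75, noise_sd = 1
  )
  trait_links <- dplyr::filter(tibble::as_tibble(trait_links),
                               .data$module <= n_modules)
  cfg <- list(
    n_collections = n_collections, n_replicates = n_replicates,
    n_features = n_features, chemotype_sizes = chemotype_sizes,
    n_chemotypes = length(chemotype_sizes),
    markers_per_chemotype = markers_per_chemotype,
    marker_log2fc = marker_log2fc,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    noise_sd = noise_sd, qc_noise_sd = qc_noise_sd, module_sd = module_sd,
    drift_amplitude = drift_amplitude, drift_smoothness = drift_smoothness,
    qc_interval = qc_interval, missing_rate = missing_rate,
    n_modules = n_modules, module_size = module_size,
    intra_module_cor = intra_module_cor,
    trait_links = tibble::as_tibble(trait_links),
    platform = platform, seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (sum(cfg$chemotype_sizes) != cfg$n_collections) {
    abort("chemotype_sizes must sum to n_collections.")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1).")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_features) {
    abort("modules do not fit into n_features.")
  }
  if (cfg$markers_per_chemotype > cfg$module_size &&
      cfg$markers_per_chemotype > 0 && cfg$n_chemotypes <= cfg$n_modules) {
    abort("markers_per_chemotype exceeds module_size.")
  }
  if (cfg$intra_module_cor < 0 || cfg$intra_module_cor >= 1) {
    abort("intra_module_cor must be in [0, 1).")
  }
  invisible(cfg)
}

# smooth positive per-feature drift factors over a set of injection orders:
# monotone trend + low-frequency random walk on the log scale, then
# normalized so every feature's mean factor over the run is exactly 1
drift_curves <- function(orders, n_features, amplitude, smoothness, seed) {
  t_n <- length(orders)
  if (amplitude == 0 || t_n < 2) {
    return(matrix(1, t_n, n_features, dimnames = list(orders, NULL)))
  }
  set.seed(seed)
  pos <- (rank(orders) - 1) / (t_n - 1)          # 0..1 along the run
  trend <- outer(2 * pos - 1, runif(n_features, -1, 1))
  rw <- apply(matrix(rnorm(t_n * n_features), t_n), 2, cumsum)
  # kill high frequencies with a wide running mean, then re-centre/scale
  win <- max(3, round(t_n / 5))
  kernel <- rep(1 / win, win)
  rw <- apply(rw, 2, function(z) stats::filter(z, kernel, circular = TRUE))
  rw <- scale(rw)
  curve <- smoothness * trend + (1 - smoothness) * rw
  curve <- scale(curve, center = TRUE, scale = apply(curve, 2, sd))
  fac <- exp(amplitude * curve)
  fac <- sweep(fac, 2, colMeans(fac), "/")
  fac <- matrix(as.vector(fac), nrow(fac), ncol(fac))   # drop scale() attrs
  dimnames(fac) <- list(orders, NULL)
  fac
}

#' Multiply a feature table by synthetic injection-order drift
#'
#' Each feature is multiplied by a smooth positive function of injection
#' order (monotone trend plus low-frequency random walk), normalized so the
#' mean factor over the run is 1 for every feature. This manufactures the
#' phenomenon that QC-anchored drift correction removes.
#'
#' @param table A [feature_table()].
#' @param amplitude Drift magnitude (>= 0); 0 returns the table unchanged.
#' @param smoothness Trend-vs-walk mixing weight in \[0, 1\].
#' @param seed Integer seed.
#' @return A [feature_table()] with drifted intensities.
#' @export
inject_drift <- function(table, amplitude, smoothness = 0.5, seed = 1) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(table)
  m <- table$intensities
  for (pf in unique(table$sample_meta$platform)) {
    idx <- which(table$sample_meta$platform == pf)
    ord <- table$sample_meta$injection_order[idx]
    fac <- drift_curves(sort(ord), ncol(m), amplitude, smoothness,
                        stage_seed(seed, paste0("drift_", pf)))
    m[idx, ] <- m[idx, ] * fac[match(ord, sort(ord)), , drop = FALSE]
  }
  table$intensities <- m
  table
}

#' Mask cells of a feature table completely at random
#'
#' Exactly `round(rate * n_cells)` observed cells are set to missing; the
#' mask is reproducible from the seed.
#'
#' @param table A [feature_table()].
#' @param rate Fraction of cells to mask, in \[0, 1).
#' @param seed Integer seed.
#' @return A [feature_table()] with masked cells.
#' @export
mask_missing <- function(table, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  m <- table$intensities
  n_mask <- round(rate * length(m))
  set.seed(seed)
  idx <- sample(which(!is.na(m)), n_mask)
  m[idx] <- NA_real_
  table$intensities <- m
  table
}

#' Generate a synthetic feature table, trait table and ground truth
#'
#' See [synth_config()] for the generative model. Biological samples are
#' `n_collections x n_replicates` clone injections in a seeded random run
#' order; pooled-QC injections open the run and recur after every
#' `qc_interval` biological injections.
#'
#' @param config A [synth_config()].
#' @return A list with elements `table` (a [feature_table()]), `traits`
#'   (collection x trait tibble) and `truth` (planted chemotype labels,
#'   marker ids, module memberships, drift factors and trait coefficients).
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_collections = 12, n_features = 50,
#'   chemotype_sizes = c(6, 6), markers_per_chemotype = 5, n_modules = 2,
#'   module_size = 10, missing_rate = 0, seed = 7))
#' d$table
generate_dataset <- function(config) {
  cfg <- if (inherits(config, "synth_config")) config else do.call(synth_config, config)
  set.seed(stage_seed(cfg$seed, "generate"))

  n_col <- cfg$n_collections
  n_rep <- cfg$n_replicates
  p <- cfg$n_features
  collections <- sprintf("C%03d", seq_len(n_col))
  features <- sprintf("F%04d", seq_len(p))
  chemotype_of <- rep(seq_along(cfg$chemotype_sizes), cfg$chemotype_sizes)
  names(chemotype_of) <- collections

  # module membership: contiguous feature blocks; 0 = unassigned
  module_of <- rep(0L, p)
  for (m in seq_len(cfg$n_modules)) {
    module_of[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)] <- m
  }
  names(module_of) <- features

  # markers of chemotype c = leading features of module c (disjoint blocks)
  markers <- tibble::tibble(chemotype = integer(0), feature_id = character(0),
                            direction = character(0))
  if (cfg$markers_per_chemotype > 0) {
    markers <- purrr::map_dfr(seq_len(cfg$n_chemotypes), function(cc) {
      block <- if (cc <= cfg$n_modules) {
        which(module_of == cc)[seq_len(cfg$markers_per_chemotype)]
      } else {
        # chemotypes beyond the module count draw from unassigned features
        which(module_of == 0)[(cc - cfg$n_modules - 1) * cfg$markers_per_chemotype +
                                seq_len(cfg$markers_per_chemotype)]
      }
      tibble::tibble(chemotype = cc, feature_id = features[block],
                     direction = "up")
    })
  }
  marker_shift <- matrix(0, cfg$n_chemotypes, p)
  marker_shift[cbind(markers$chemotype, match(markers$feature_id, features))] <-
    cfg$marker_log2fc * log(2)

  # per-feature log-normal baselines
  mu <- rnorm(p, cfg$baseline_meanlog, cfg$baseline_sdlog)

  # collection-level module structure: shared latent factor per module plus
  # idiosyncratic part, loading sqrt(rho) -> intra-module correlation rho
  g <- matrix(rnorm(n_col * cfg$n_modules), n_col)          # latent factors
  z <- matrix(0, n_col, p)
  rho <- cfg$intra_module_cor
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(module_of == m)
    z[, idx] <- sqrt(rho) * g[, m] +
      sqrt(1 - rho) * matrix(rnorm(n_col * length(idx)), n_col)
  }

  # expected (noise- and drift-free) ln intensity per collection
  ln_expect <- matrix(mu, n_col, p, byrow = TRUE) +
    marker_shift[chemotype_of, , drop = FALSE] + cfg$module_sd * z
  qc_profile <- colMeans(exp(ln_expect))   # pooled aliquot of all samples

  # injection layout: QC, then blocks of qc_interval biologicals + QC
  n_bio <- n_col * n_rep
  bio_ids <- paste0(rep(collections, each = n_rep), "_R", seq_len(n_rep))
  bio_order_perm <- sample(n_bio)
  n_qc <- 1 + ceiling(n_bio / cfg$qc_interval)
  total <- n_bio + n_qc
  is_qc <- rep(FALSE, total)
  qc_slots <- c(1, 1 + cumsum(rep(cfg$qc_interval + 1,
                                  ceiling(n_bio / cfg$qc_interval))))
  qc_slots <- qc_slots[qc_slots <= total]
  # if the last block is partial, still close the run with a QC
  if (length(qc_slots) < n_qc) qc_slots <- c(qc_slots, total)
  is_qc[qc_slots] <- TRUE

  sample_meta <- tibble::tibble(
    sample_id = character(total), role = ifelse(is_qc, "qc", "biological"),
    injection_order = seq_len(total), collection_id = NA_character_,
    replicate_id = NA_character_, platform = cfg$platform
  )
  bio_rows <- which(!is_qc)
  sample_meta$sample_id[bio_rows] <- bio_ids[bio_order_perm]
  sample_meta$collection_id[bio_rows] <-
    rep(collections, each = n_rep)[bio_order_perm]
  sample_meta$replicate_id[bio_rows] <-
    paste0("R", rep(seq_len(n_rep), n_col))[bio_order_perm]
  qc_rows <- which(is_qc)
  sample_meta$sample_id[qc_rows] <- sprintf("QC%03d", seq_along(qc_rows))
  sample_meta$collection_id[qc_rows] <- "QC"
  sample_meta$replicate_id[qc_rows] <- sprintf("Q%03d", seq_along(qc_rows))

  # assemble intensities
  ln_m <- matrix(0, total, p)
  coll_idx <- match(sample_meta$collection_id[bio_rows], collections)
  ln_m[bio_rows, ] <- ln_expect[coll_idx, , drop = FALSE] +
    matrix(rnorm(n_bio * p, sd = cfg$noise_sd), n_bio)
  ln_m[qc_rows, ] <- matrix(log(qc_profile), n_qc, p, byrow = TRUE) +
    matrix(rnorm(n_qc * p, sd = cfg$qc_noise_sd), n_qc)

  drift <- drift_curves(seq_len(total), p, cfg$drift_amplitude,
                        cfg$drift_smoothness,
                        stage_seed(cfg$seed, "generate_drift"))
  m <- exp(ln_m) * drift
  dimnames(m) <- list(sample_meta$sample_id, features)

  # missingness: half MCAR, half preferentially in the lowest-intensity decile
  if (cfg$missing_rate > 0) {
    n_mask <- round(cfg$missing_rate * length(m))
    n_mcar <- floor(n_mask / 2)
    set.seed(stage_seed(cfg$seed, "generate_missing"))
    mcar <- sample(length(m), n_mcar)
    low <- setdiff(which(m <= quantile(m, 0.1)), mcar)
    low_mask <- sample(low, min(length(low), n_mask - n_mcar))
    m[c(mcar, low_mask)] <- NA_real_
  }

  ft <- feature_table(m, sample_meta,
                      tibble::tibble(feature_id = features, name = features,
                                     category = ifelse(module_of > 0,
                                                       paste0("module_", module_of),
                                                       "unassigned")))

  # traits: linked traits = coef x module latent factor + noise; others noise
  set.seed(stage_seed(cfg$seed, "generate_traits"))
  traits <- tibble::tibble(collection_id = collections)
  for (tr in TRAIT_VOCABULARY) {
    links <- dplyr::filter(cfg$trait_links, .data$trait == tr)
    val <- rnorm(n_col, sd = if (nrow(links) > 0) links$noise_sd[1] else 1)
    if (nrow(links) > 0) {
      for (j in seq_len(nrow(links))) {
        val <- val + links$coef[j] * g[, links$module[j]]
      }
    }
    traits[[tr]] <- val
  }

  truth <- list(
    chemotype_of = chemotype_of,
    markers = markers,
    module_of = module_of,
    module_factors = g,
    drift_factors = drift,
    trait_links = cfg$trait_links,
    config = cfg
  )
  list(table = ft, traits = traits, truth = truth)
}
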