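# shared fixture builders; all data is generated in code at test time

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_collections = 20, n_replicates = 3, n_features = 60,
         chemotype_sizes = c(10, 10), markers_per_chemotype = 6,
         n_modules = 2, module_size = 12, missing_rate = 0.05, seed = seed),
    list(...))
  do.call(synth_config, args)
}

# k unit-sd Gaussian blobs whose centres are placed at random with
# pairwise separation >= sep sigma (the generic, asymmetric layout)
make_blobs <- function(seed, k = 4, n = 160, d = 3, sep = 6) {
  set.seed(seed)
  box <- sep * 2.5
  repeat {
    centers <- matrix(runif(k * d, 0, box), k)
    if (k == 1 || min(dist(centers)) >= sep) break
  }
  lab <- rep(seq_len(k), length.out = n)
  x <- centers[lab, , drop = FALSE] + matrix(rnorm(n * d), n)
  rownames(x) <- sprintf("C%03d", seq_len(n))
  colnames(x) <- paste0("V", seq_len(d))
  list(x = x, labels = lab)
}

# wrap planted chemotype labels as an assignment object
truth_assignment <- function(truth) {
  structure(
    tibble::tibble(collection_id = names(truth$chemotype_of),
                   chemotype = unname(truth$chemotype_of)),
    method = "truth", k = length(unique(truth$chemotype_of)),
    class = c("chemotype_assignment", class(tibble::tibble())))
}

ari_vs_truth <- function(assignment, truth) {
  adjusted_rand_index(truth$chemotype_of[assignment$collection_id],
                      assignment$chemotype)
}
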