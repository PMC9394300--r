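# Small cohorts and geometric fixtures shared across test files.

small_spec <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_samples = 60,
               n_marker_genes_per_subgroup = 30, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# Three well-separated Gaussian blobs in 2-D; returns coords + labels.
blob_embedding <- function(n_per = 50, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                           sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- rep(seq_len(k), each = n_per)
  Y <- centers[lab, ] + matrix(rnorm(2 * k * n_per, sd = sd), ncol = 2)
  rownames(Y) <- sprintf("s%03d", seq_len(nrow(Y)))
  list(coords = Y, labels = lab)
}

expect_ari <- function(labels, truth, min) {
  expect_gte(mclust::adjustedRandIndex(labels, truth), min)
}
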