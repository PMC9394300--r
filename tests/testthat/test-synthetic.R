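test_that("same spec and seed give bit-identical cohorts", {
  spec <- small_spec(seed = 7)
  a <- generate_fpkm(spec)
  b <- generate_fpkm(spec)
  expect_identical(a$expression, b$expression)
  expect_identical(a$annotations, b$annotations)
})

test_that("empirical zero fraction matches the requested rate", {
  # 500 x 200 = 1e5 entries: binomial sd of the empirical rate is ~0.0014,
  # so +/- 0.01 is a > 3 sd band
  spec <- synthetic_spec(n_genes = 500, n_samples = 200,
                         n_marker_genes_per_subgroup = 50,
                         zero_fraction = 0.3, seed = 2)
  co <- generate_fpkm(spec)
  zf <- mean(co$expression == 0)
  expect_lt(abs(zf - 0.3), 0.01)
  expect_true(all(co$expression >= 0))
})

test_that("zero effect size plants no marker enrichment", {
  spec <- small_spec(seed = 3, log2_effect_size = 0)
  co <- generate_fpkm(spec)
  L <- apply_transform(co$expression, "log10p1")
  truth <- co$annotations$subgroup_truth
  # per-gene between-subgroup F statistic; markers should look like the rest
  fstat <- apply(L, 1, function(v) {
    summary(stats::aov(v ~ factor(truth)))[[1]]$`F value`[1]
  })
  markers <- unlist(attr(co, "marker_genes"))
  p <- stats::wilcox.test(fstat[markers], fstat[setdiff(names(fstat), markers)])$p.value
  expect_gt(p, 0.01)
})

test_that("planted subgroups are linearly separable on the log10+1 scale", {
  for (sd in 1:2) {
    co <- generate_fpkm(small_spec(seed = sd))
    L <- apply_transform(co$expression, "log10p1")
    truth <- co$annotations$subgroup_truth
    cent <- sapply(unique(truth), function(s) rowMeans(L[, truth == s, drop = FALSE]))
    scoremat <- t(L) %*% cent -
      matrix(colSums(cent^2) / 2, ncol(L), ncol(cent), byrow = TRUE)
    pred <- colnames(cent)[apply(scoremat, 1, which.max)]
    expect_gte(mean(pred == truth), 0.95)
  }
})

test_that("site labels are independent of the planted subgroups", {
  co <- generate_fpkm(synthetic_spec(n_genes = 200, n_samples = 400,
                                     n_marker_genes_per_subgroup = 20, seed = 5))
  ann <- co$annotations
  p <- suppressWarnings(
    stats::chisq.test(table(ann$site, ann$subgroup_truth)))$p.value
  expect_gt(p, 0.001)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synthetic_spec(zero_fraction = 1), "zero_fraction")
  expect_error(synthetic_spec(n_genes = 0), "n_genes")
  expect_error(synthetic_spec(log2_effect_size = -1), "log2_effect_size")
  expect_error(synthetic_spec(n_marker_genes_per_subgroup = 900, n_genes = 1000,
                              n_subgroups = 3), "n_marker_genes_per_subgroup")
  expect_error(synthetic_spec(base_log_sd = 0), "base_log_sd")
})

test_that("gradient cohort interpolates between centroid profiles", {
  spec <- small_spec(seed = 9, gradient_fraction = 0.8)
  co <- generate_gradient_cohort(spec)
  cent <- attr(co, "centroids")
  sig <- attr(co, "signal")
  w <- co$annotations$mixing_weight
  # endpoints and midpoint of the noiseless pattern
  i0 <- which(w == 0)[1]
  expect_equal(unname(sig[, i0]), cent$primary)
  i1 <- which(w == 1)[1]
  expect_equal(unname(sig[, i1]), cent$metastatic)
  expect_equal(unname(sig[, 3]),
               (1 - w[3]) * cent$primary + w[3] * cent$metastatic)
  # sample_type by thresholding at 0.5
  expect_identical(co$annotations$sample_type,
                   ifelse(w > 0.5, "metastatic", "primary"))
})

test_that("mixing weight aligns with the leading axis of the noiseless signal", {
  spec <- small_spec(seed = 10, gradient_fraction = 1)
  co <- generate_gradient_cohort(spec)
  sig <- t(attr(co, "signal"))
  pc1 <- prcomp(sig, rank. = 1)$x[, 1]
  expect_gt(abs(stats::cor(pc1, co$annotations$mixing_weight)), 0.99)
})

test_that("gradient generator refuses a zero gradient fraction", {
  expect_error(generate_gradient_cohort(small_spec()), "generate_fpkm")
})
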