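test_that("squared pairwise distances match the naive double loop", {
  expect_equal(pairwise_sq_euclidean(rbind(c(0, 3), c(0, 4)))[1, 2], 25)
  set.seed(1)
  X <- matrix(rnorm(10 * 5), 10, 5)                  # 10 genes x 5 samples
  D <- pairwise_sq_euclidean(X)
  expect_identical(unname(diag(D)), rep(0, 5))
  naive <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) naive[i, j] <- sum((X[, i] - X[, j])^2)
  expect_lt(max(abs(D - naive)), 1e-9)
  expect_identical(D, t(D))
})

test_that("bandwidth search reproduces the closed form for uniform gaps", {
  # 15 neighbours all at gap 1: 15 exp(-1/sigma) = log2(15)
  expect_equal(solve_sigma(rep(1, 15)), 1 / log(15 / log2(15)),
               tolerance = 1e-4)
  # independent scalar root-finder oracle at a different gap scale
  oracle <- stats::uniroot(function(s) sum(exp(-rep(2.5, 15) / s)) - log2(15),
                           c(1e-6, 100), tol = 1e-12)$root
  expect_equal(solve_sigma(rep(2.5, 15)), oracle, tolerance = 1e-4)
})

test_that("calibration residuals are below 1e-4 on random data", {
  set.seed(2)
  X <- matrix(rnorm(30 * 40), 30, 40)
  D <- pairwise_sq_euclidean(X)
  sc <- calibrate_local_scales(D, k_local = 15)
  for (i in seq_len(ncol(X))) {
    d <- sort(D[i, -i])[1:15]
    mass <- sum(exp(-pmax(0, d - sc$rho[i]) / sc$sigma[i]))
    expect_lt(abs(mass - log2(15)), 1e-4)
  }
  expect_true(all(sc$sigma > 0))
})

test_that("duplicate points fall back to the bandwidth floor without error", {
  X <- matrix(1, 5, 20)                               # all samples identical
  D <- pairwise_sq_euclidean(X)
  sc <- calibrate_local_scales(D, k_local = 10)
  expect_identical(sc$sigma, rep(1e-8, 20))
})

test_that("directed affinities respect the edge set and monotonicity", {
  set.seed(3)
  X <- matrix(rnorm(20 * 30), 20, 30)
  D <- pairwise_sq_euclidean(X)
  sc <- calibrate_local_scales(D, k_local = 5)
  P <- build_affinities(D, sc$rho, sc$sigma, k_graph = 10)
  for (i in 1:30) {
    expect_identical(sum(P[i, ] > 0), 10L)            # sparsity
    expect_equal(max(P[i, ]), 1)                      # nearest neighbour gets 1
    nz <- which(P[i, ] > 0)
    ord <- nz[order(D[i, nz])]
    expect_true(all(diff(P[i, ord]) <= 1e-12))        # non-increasing in D
  }
  expect_true(all(P >= 0 & P <= 1))
})

test_that("half-sum symmetrisation averages the two directions", {
  P <- matrix(0, 2, 2); P[1, 2] <- 1
  S <- symmetrize_half_sum(P)
  expect_identical(S[1, 2], 0.5)
  expect_identical(S[2, 1], 0.5)
  set.seed(4)
  Q <- matrix(runif(25), 5, 5)
  Qs <- symmetrize_half_sum(Q)
  expect_identical(Qs, t(Qs))
  expect_identical(symmetrize_half_sum(Qs), Qs)       # fixed point
  expect_true(all(Qs >= 0 & Qs <= 1))
  expect_error(symmetrize_half_sum(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("kernel fit matches an independent grid-search least-squares oracle", {
  k <- fit_ab(0.25)
  expect_gt(k$a, 0); expect_gt(k$b, 0)
  expect_equal(1 / (1 + k$a * 0^(2 * k$b)), 1)        # w(0) = 1
  d <- seq(0, 3, length.out = 300)
  psi <- ifelse(d <= 0.25, 1, exp(-(d - 0.25)))
  w <- 1 / (1 + k$a * d^(2 * k$b))
  expect_true(all(diff(w) < 0))                       # strictly decreasing
  rms <- sqrt(mean((w - psi)^2))
  expect_lt(rms, 0.03)
  # oracle: exhaustive grid over (a, b)
  grid <- expand.grid(a = seq(0.5, 3, by = 0.025), b = seq(0.5, 2, by = 0.025))
  gr <- vapply(seq_len(nrow(grid)), function(r) {
    sqrt(mean((1 / (1 + grid$a[r] * d^(2 * grid$b[r])) - psi)^2))
  }, numeric(1))
  expect_lte(rms, min(gr) + 1e-4)
})

test_that("normalised Q is a distribution with the expected symmetries", {
  k <- fit_ab(0.25)
  Q2 <- normalized_q(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE), k)
  expect_equal(Q2[1, 2] + Q2[2, 1], 1)                # single pair
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))  # equilateral triangle
  Q3 <- normalized_q(eq, k)
  off <- Q3[row(Q3) != col(Q3)]
  expect_equal(off, rep(1 / 6, 6), tolerance = 1e-12)
  set.seed(5)
  Qr <- normalized_q(matrix(rnorm(40), 20, 2), k)
  expect_equal(sum(Qr), 1, tolerance = 1e-12)
  expect_identical(unname(diag(Qr)), rep(0, 20))
})

test_that("cross-entropy is bounded below by the entropy of P (Gibbs)", {
  k <- fit_ab(0.25)
  set.seed(6)
  for (rep in 1:5) {
    n <- 12
    P <- matrix(runif(n * n), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
    Phat <- P / sum(P)
    Y <- matrix(rnorm(n * 2), n, 2)
    Q <- normalized_q(Y, k)
    entropy <- -sum(Phat[Phat > 0] * log(Phat[Phat > 0]))
    expect_gte(cross_entropy_cost(P, Q) - entropy, -1e-10)
  }
  # minimum attained at Q = Phat
  n <- 8
  P <- matrix(runif(n * n), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
  Phat <- P / sum(P)
  entropy <- -sum(Phat[Phat > 0] * log(Phat[Phat > 0]))
  expect_equal(-sum(Phat * log(Phat + 1e-12)), entropy, tolerance = 1e-6)
  expect_error(cross_entropy_cost(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("analytic gradient matches central finite differences", {
  k <- fit_ab(0.25)
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:15, 1)
    P <- matrix(runif(n * n), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
    Phat <- P / sum(P)
    Y <- matrix(rnorm(n * 2), n, 2)
    g <- vizclust:::ce_gradient(Y, Phat, k)
    h <- 1e-5
    num <- matrix(0, n, 2)
    for (i in seq_len(n)) for (j in 1:2) {
      Yp <- Y; Yp[i, j] <- Y[i, j] + h
      Ym <- Y; Ym[i, j] <- Y[i, j] - h
      num[i, j] <- (cross_entropy_cost(Phat, normalized_q(Yp, k)) -
                    cross_entropy_cost(Phat, normalized_q(Ym, k))) / (2 * h)
    }
    expect_lt(max(abs(g$grad - num)) / max(abs(num)), 1e-4)
  }
})

test_that("a single pair has a flat cost and barely moves", {
  k <- fit_ab(0.25)
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  e <- gradient_descent_embed(P, k, umap_params(n_iter = 50, seed = 1))
  set.seed(1)
  init <- matrix(rnorm(4, sd = 1e-2), 2, 2)
  expect_lt(max(abs(e$coords - init)), 1e-4)
  expect_equal(tail(e$cost_trace, 1), e$cost_trace[1], tolerance = 1e-8)
})

test_that("gradient descent reduces the cost on random affinities", {
  k <- fit_ab(0.25)
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(25 * n), 25, n)
  D <- pairwise_sq_euclidean(X)
  sc <- calibrate_local_scales(D, 10)
  P <- symmetrize_half_sum(build_affinities(D, sc$rho, sc$sigma, 20))
  e <- gradient_descent_embed(P, k, umap_params(n_iter = 100, seed = 2))
  expect_lt(tail(e$cost_trace, 1), e$cost_trace[1])
  expect_identical(length(e$cost_trace), 101L)
})

test_that("the full adapted UMAP is deterministic and resolves k_graph", {
  co <- generate_fpkm(small_spec(seed = 11, n_samples = 40))
  L <- apply_transform(co$expression, "log10p1")
  p <- umap_params(n_iter = 50, seed = 5)
  e1 <- umap_adapted_embed(L, p)
  e2 <- umap_adapted_embed(L, p)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$provenance$params$k_graph, 25L)  # small-cohort rule
  co2 <- generate_fpkm(small_spec(seed = 11, n_samples = 60))
  L2 <- apply_transform(co2$expression, "log10p1")
  e3 <- umap_adapted_embed(L2, umap_params(n_iter = 10, seed = 5))
  expect_identical(e3$provenance$params$k_graph, 50L)
  expect_identical(e3$provenance$method, "UMAP (adapted)")
})

test_that("permuting samples with a permuted init permutes the map", {
  co <- generate_fpkm(small_spec(seed = 12, n_samples = 40))
  L <- apply_transform(co$expression, "log10p1")
  set.seed(13)
  init <- matrix(rnorm(40 * 2, sd = 1e-2), 40, 2)
  # few iterations: descent on this landscape is expansive, so last-ulp
  # float reordering would swamp a long run
  p <- umap_params(n_iter = 10, seed = 13)
  e1 <- umap_adapted_embed(L, p, init = init)
  perm <- sample(40)
  e2 <- umap_adapted_embed(L[, perm], p, init = init[perm, ])
  expect_equal(e2$coords[order(perm), ], e1$coords[, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("adapted UMAP with Leiden recovers planted subgroups", {
  co <- generate_fpkm(synthetic_spec(n_genes = 500, n_samples = 120,
                                     n_marker_genes_per_subgroup = 150,
                                     seed = 14))
  L <- apply_transform(co$expression, "log10p1")
  e <- umap_adapted_embed(L, umap_params(seed = 3))
  cl <- leiden_cluster(knn_graph(e, 15), resolution = 1, seed = 4)
  expect_ari(cl$labels, co$annotations$subgroup_truth, 0.9)
})
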