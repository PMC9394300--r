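#' Parameters for the adapted UMAP
#'
#' The adapted UMAP works directly on the transformed expression matrix
#' (no PCA): squared pairwise Euclidean distances, smooth k-NN bandwidth
#' calibration against 15 local neighbours, a 50-neighbour affinity edge
#' set (25 for cohorts under 50 samples), half-sum symmetrisation, a fitted
#' low-dimensional kernel with `min_dist = 0.25`, and full-batch gradient
#' descent on a cross-entropy cost with a normalised Q distribution.
#'
#' @param k_local Neighbour count for the bandwidth calibration (default 15).
#' @param k_graph Neighbour count for the affinity edge set. `NULL` (the
#'   default) resolves at embedding time to 50, or 25 when the cohort has
#'   fewer than 50 samples.
#' @param min_dist Minimum-distance parameter of the low-dimensional kernel.
#' @param n_iter Gradient-descent iterations.
#' @param learning_rate Gradient-descent step size.
#' @param seed Integer seed for the Gaussian initialisation.
#' @param sigma_tol Tolerance on the calibration residual.
#' @param sigma_max_iter Maximum bisection iterations per sample.
#' @return An object of class `vc_umap_params`.
#' @export
umap_params <- function(k_local = 15, k_graph = NULL, min_dist = 0.25,
                        n_iter = 200, learning_rate = 100, seed = 1L,
                        sigma_tol = 1e-5, sigma_max_iter = 64) {
  if (min_dist <= 0) abort("`min_dist` must be positive")
  if (!is.null(k_graph) && k_local > k_graph) {
    abort("`k_local` must not exceed `k_graph`")
  }
  structure(
    list(k_local = k_local, k_graph = k_graph, min_dist = min_dist,
         n_iter = n_iter, learning_rate = learning_rate,
         seed = as.integer(seed), sigma_tol = sigma_tol,
         sigma_max_iter = sigma_max_iter),
    class = "vc_umap_params"
  )
}

#' Squared pairwise Euclidean distances between samples
#'
#' @param X Numeric matrix. With `samples_in = "columns"` (the default,
#'   matching the genes x samples orientation of expression matrices)
#'   distances are between columns; with `"rows"` between rows.
#' @param samples_in `"columns"` or `"rows"`.
#' @return A symmetric n x n matrix with zero diagonal,
#'   `D[i, j] = sum_g (x_ig - x_jg)^2`.
#' @export
pairwise_sq_euclidean <- function(X, samples_in = c("columns", "rows")) {
  samples_in <- match.arg(samples_in)
  if (!all(is.finite(X))) abort("`X` must be finite")
  M <- if (samples_in == "columns") t(X) else X
  if (nrow(M) < 2) abort("need at least 2 samples")
  D <- row_sq_dist(M)
  D <- (D + t(D)) / 2
  rownames(D) <- colnames(D) <- rownames(M)
  D
}

#' Smooth k-NN bandwidth root-finder
#'
#' Solves `sum_j exp(-gaps[j] / sigma) = target` for `sigma > 0` by bracket
#' expansion and bisection; `gaps` are the nonnegative distance offsets
#' `D_ij - rho_i` of a sample's calibration neighbours. When the equation
#' has no root — every gap is 0, so the sum is `length(gaps)` for any
#' bandwidth — the documented floor `1e-8` is returned.
#'
#' @param gaps Nonnegative numeric vector of distance offsets.
#' @param target Target affinity mass; defaults to `log2(length(gaps))`.
#' @param tol Residual tolerance.
#' @param max_iter Maximum bisection iterations.
#' @return The calibrated bandwidth (scalar).
#' @export
solve_sigma <- function(gaps, target = log2(length(gaps)), tol = 1e-5,
                        max_iter = 64) {
  stopifnot(all(gaps >= 0), target > 0)
  floor_sigma <- 1e-8
  f <- function(s) sum(exp(-gaps / s))
  if (f(floor_sigma) >= target) return(floor_sigma)   # degenerate: duplicates
  lo <- floor_sigma; hi <- 1
  while (f(hi) < target && hi < 1e3) hi <- hi * 2     # geometric expansion
  s <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    s <- (lo + hi) / 2
    val <- f(s)
    if (abs(val - target) < tol) break
    if (val < target) lo <- s else hi <- s
  }
  s
}

#' Calibrate per-sample offsets and bandwidths
#'
#' For each sample i, `rho[i]` is the (squared-unit) distance to its nearest
#' neighbour and `sigma[i]` is the bandwidth at which the affinity mass over
#' the `k_local` nearest neighbours, `sum_j exp(-max(0, D_ij - rho_i) /
#' sigma_i)`, equals `log2(k_local)`.
#'
#' @param D Symmetric squared-distance matrix from
#'   [pairwise_sq_euclidean()].
#' @param k_local Calibration neighbour count (default 15); must be below
#'   the sample count.
#' @param tol,max_iter Passed to [solve_sigma()].
#' @return A list with numeric vectors `rho` and `sigma`.
#' @export
calibrate_local_scales <- function(D, k_local = 15, tol = 1e-5,
                                   max_iter = 64) {
  n <- nrow(D)
  if (k_local >= n) {
    abort(sprintf("`k_local` (%d) must be below the number of samples (%d)",
                  k_local, n))
  }
  rho <- numeric(n); sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(D[i, -i], partial = k_local)[seq_len(k_local)]
    d <- sort(d)
    rho[i] <- d[1]
    sigma[i] <- solve_sigma(pmax(0, d - rho[i]), log2(k_local), tol, max_iter)
  }
  list(rho = rho, sigma = sigma)
}

#' Directed affinities over each sample's neighbour edge set
#'
#' `p[j|i] = exp(-max(0, D_ij - rho_i) / sigma_i)` for j among i's `k_graph`
#' nearest neighbours (distance ties broken by sample index) and 0
#' elsewhere. The nearest neighbour of every sample receives affinity 1.
#'
#' @param D Squared-distance matrix.
#' @param rho,sigma Calibrated scales from [calibrate_local_scales()].
#' @param k_graph Edge-set neighbour count.
#' @return An n x n matrix of directed affinities in `[0, 1]`.
#' @export
build_affinities <- function(D, rho, sigma, k_graph = 50) {
  n <- nrow(D)
  if (k_graph >= n) {
    abort(sprintf("`k_graph` (%d) must be below the number of samples (%d)",
                  k_graph, n))
  }
  nn <- nn_index_matrix(D, k_graph)
  P <- matrix(0, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    j <- nn[i, ]
    P[i, j] <- exp(-pmax(0, D[i, j] - rho[i]) / sigma[i])
  }
  P
}

#' Half-sum symmetrisation
#'
#' `P_ij = (p[j|i] + p[i|j]) / 2` — the simplified symmetry rule used by the
#' adapted UMAP in place of the fuzzy-union formula.
#'
#' @param P_directed Matrix of directed affinities in `[0, 1]`.
#' @return An exactly symmetric matrix with entries in `[0, 1]`.
#' @export
symmetrize_half_sum <- function(P_directed) {
  if (any(P_directed < 0 | P_directed > 1)) {
    abort("directed affinities must lie in [0, 1]")
  }
  (P_directed + t(P_directed)) / 2
}

#' Fit the low-dimensional kernel constants a and b
#'
#' Least-squares fit of `w(d) = 1 / (1 + a d^(2b))` to the target curve
#' `psi(d) = 1` for `d <= min_dist`, `exp(-(d - min_dist))` beyond, over an
#' evenly spaced grid of 300 points on `[0, 3]`.
#'
#' @param min_dist Positive minimum-distance parameter.
#' @param d_max,n_grid Fitting grid extent and size.
#' @return A list of class `vc_kernel` with `a`, `b`, `min_dist` and the
#'   RMS residual `rms` of the fit.
#' @export
fit_ab <- function(min_dist = 0.25, d_max = 3, n_grid = 300) {
  if (min_dist <= 0) abort("`min_dist` must be positive")
  d <- seq(0, d_max, length.out = n_grid)
  psi <- ifelse(d <= min_dist, 1, exp(-(d - min_dist)))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((1 / (1 + a * d^(2 * b)) - psi)^2)
  }
  fit <- optim(c(0, 0), obj, method = "L-BFGS-B")
  if (fit$convergence != 0) {
    abort(sprintf("kernel fit did not converge (residual %.3g): %s",
                  fit$value, fit$message %||% ""))
  }
  structure(
    list(a = exp(fit$par[1]), b = exp(fit$par[2]), min_dist = min_dist,
         rms = sqrt(fit$value / n_grid)),
    class = "vc_kernel"
  )
}

#' Normalised low-dimensional affinity distribution Q
#'
#' `w_ij = 1 / (1 + a ||y_i - y_j||^(2b))` for `i != j`;
#' `Q = w / sum(w)` over all ordered off-diagonal pairs, so Q sums to 1.
#'
#' @param Y n x 2 coordinate matrix (n >= 2).
#' @param kernel A `vc_kernel` from [fit_ab()].
#' @return An n x n matrix with zero diagonal summing to 1.
#' @export
normalized_q <- function(Y, kernel) {
  if (nrow(Y) < 2) abort("need at least 2 points")
  W <- lowdim_w(Y, kernel)
  W / sum(W)
}

# Unnormalised kernel weights; d2 clamped away from 0 off-diagonal so that
# the gradient's d2^(b-1) factor stays finite for b < 1.
lowdim_w <- function(Y, kernel, d2 = NULL) {
  d2 <- d2 %||% row_sq_dist(Y)
  W <- 1 / (1 + kernel$a * pmax(d2, 1e-12)^kernel$b)
  diag(W) <- 0
  W
}

#' Cross-entropy cost with normalised Q
#'
#' `C = -sum_{i != j} Phat_ij log(Q_ij + eps)` where `Phat` is `P`
#' renormalised to sum 1 over off-diagonal pairs. By Gibbs' inequality the
#' cost is bounded below by the Shannon entropy of `Phat`, attained iff
#' `Q = Phat`.
#'
#' @param P Symmetric high-dimensional affinity matrix (any positive total;
#'   renormalised internally).
#' @param Q Normalised low-dimensional distribution from [normalized_q()].
#' @param eps Numerical guard inside the logarithm.
#' @return Finite scalar cost.
#' @export
cross_entropy_cost <- function(P, Q, eps = 1e-12) {
  if (!all(dim(P) == dim(Q))) abort("`P` and `Q` must have identical shapes")
  Phat <- P / sum(P)
  diag(Phat) <- 0
  -sum(Phat * log(Q + eps))
}

# Analytic gradient of cross_entropy_cost with respect to Y, for Phat
# already normalised.  Derivation: with w_ij the kernel weights, S their
# off-diagonal sum and Q = w/S,
#   dC/dw_kl = T/S^2 - Phat_kl / ((Q_kl + eps) S),  T = sum Phat w / (Q + eps)
#   dw_ij/d(d2_ij) = -a b d2^(b-1) w^2
#   dC/dy_i = sum_j 2 (G_ij + G_ji) phi_ij (y_i - y_j).
ce_gradient <- function(Y, Phat, kernel, eps = 1e-12) {
  d2 <- row_sq_dist(Y)
  d2c <- pmax(d2, 1e-12)
  W <- 1 / (1 + kernel$a * d2c^kernel$b)
  diag(W) <- 0
  S <- sum(W)
  Q <- W / S
  Tsum <- sum(Phat * W / (Q + eps))
  G <- Tsum / S^2 - Phat / ((Q + eps) * S)
  diag(G) <- 0
  phi <- -kernel$a * kernel$b * d2c^(kernel$b - 1) * W^2
  diag(phi) <- 0
  M <- 2 * (G + t(G)) * phi
  grad <- rowSums(M) * Y - M %*% Y
  list(grad = grad, cost = -sum(Phat * log(Q + eps)))
}

#' Optimise embedding coordinates by full-batch gradient descent
#'
#' Coordinates start from seeded Gaussian noise (scale 1e-2) and follow the
#' analytic gradient of [cross_entropy_cost()] for `n_iter` steps at a
#' constant learning rate. The per-iteration cost is recorded; a non-finite
#' cost aborts with advice to lower the learning rate.
#'
#' @param P Symmetric affinity matrix from [symmetrize_half_sum()].
#' @param kernel A `vc_kernel`.
#' @param params A [umap_params()] object.
#' @param init Optional n x 2 matrix of starting coordinates (overrides the
#'   seeded Gaussian; used e.g. for equivariance checks).
#' @param unit,transform Provenance fields.
#' @param sample_ids Sample identifiers (defaults to `P`'s row names).
#' @return A `vc_embedding` with the full per-iteration `cost_trace`.
#' @export
gradient_descent_embed <- function(P, kernel, params = umap_params(),
                                   init = NULL, unit = "FPKM",
                                   transform = "unprocessed",
                                   sample_ids = NULL) {
  n <- nrow(P)
  Phat <- P / sum(P)
  diag(Phat) <- 0
  if (is.null(init)) {
    set.seed(params$seed)
    Y <- matrix(rnorm(n * 2, sd = 1e-2), n, 2)
  } else {
    Y <- init
  }
  trace <- numeric(params$n_iter + 1)
  trace[1] <- cross_entropy_cost(Phat, normalized_q(Y, kernel))
  for (it in seq_len(params$n_iter)) {
    g <- ce_gradient(Y, Phat, kernel)
    Y <- Y - params$learning_rate * g$grad
    cost <- cross_entropy_cost(Phat, normalized_q(Y, kernel))
    if (!is.finite(cost)) {
      abort("gradient descent diverged (non-finite cost); try a smaller `learning_rate`")
    }
    trace[it + 1] <- cost
  }
  new_embedding(
    coords = Y,
    sample_ids = sample_ids %||% rownames(P) %||% as.character(seq_len(n)),
    provenance = list(unit = unit, transform = transform,
                      method = "UMAP (adapted)", method_label = "UMAP",
                      params = unclass(params), seed = params$seed),
    cost_trace = trace
  )
}

#' Adapted UMAP of a transformed expression matrix
#'
#' Composes the whole stage: squared pairwise distances, bandwidth
#' calibration, directed affinities over the `k_graph` edge set, half-sum
#' symmetrisation, kernel fit for `min_dist`, and gradient descent on the
#' normalised cross-entropy. When `k_graph` is unset it resolves to 50, or
#' 25 for cohorts with fewer than 50 samples (and never above
#' `n_samples - 1`).
#'
#' @param X_t Transformed expression matrix (genes x samples).
#' @param params A [umap_params()] object.
#' @param unit Expression unit for provenance.
#' @param init Optional explicit initial coordinates (see
#'   [gradient_descent_embed()]).
#' @return A `vc_embedding` with method `"UMAP (adapted)"` and the resolved
#'   parameter record in provenance.
#' @export
umap_adapted_embed <- function(X_t, params = umap_params(), unit = "FPKM",
                               init = NULL) {
  n <- ncol(X_t)
  k_graph <- params$k_graph %||% (if (n < 50) 25L else 50L)
  k_graph <- as.integer(min(k_graph, n - 1))
  if (params$k_local > k_graph) {
    abort(sprintf("`k_local` (%d) exceeds the resolved `k_graph` (%d)",
                  params$k_local, k_graph))
  }
  params$k_graph <- k_graph
  D <- pairwise_sq_euclidean(X_t)
  scales <- calibrate_local_scales(D, params$k_local, params$sigma_tol,
                                   params$sigma_max_iter)
  P <- build_affinities(D, scales$rho, scales$sigma, k_graph)
  P <- symmetrize_half_sum(P)
  kernel <- fit_ab(params$min_dist)
  gradient_descent_embed(
    P, kernel, params, init = init, unit = unit,
    transform = attr(X_t, "transform") %||% "unprocessed",
    sample_ids = colnames(X_t)
  )
}
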