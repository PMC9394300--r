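#' Parameters for the t-SNE stage
#'
#' Defaults follow the fixed setting used for every t-SNE map in this
#' package: PCA preprocessing to 50 components, perplexity 27 and learning
#' rate 300. "PCA with 50 components" is read as *preprocessing* of the
#' input to 50 dimensions (the standard pipeline), not as initialisation of
#' the 2-D map; initialisation is a separate option, defaulting to the
#' deterministic PCA-based scheme for reproducibility.
#'
#' @param n_pcs Number of principal components for preprocessing (>= 2).
#'   The effective number is capped at `min(n_pcs, n_samples - 1, n_genes)`.
#' @param perplexity Target perplexity of the conditional Gaussian
#'   neighbourhoods; must be below the sample count.
#' @param learning_rate Gradient-descent learning rate.
#' @param n_iter Number of gradient-descent iterations.
#' @param seed Integer seed (used by the random initialisation and recorded
#'   in provenance either way).
#' @param init `"pca"` (deterministic, default) or `"random"`.
#' @param early_exaggeration,exaggeration_iter Affinity exaggeration factor
#'   and the iteration at which it is switched off.
#' @return An object of class `vc_tsne_params`.
#' @export
tsne_params <- function(n_pcs = 50, perplexity = 27, learning_rate = 300,
                        n_iter = 1000, seed = 1L, init = c("pca", "random"),
                        early_exaggeration = 4, exaggeration_iter = 100) {
  init <- match.arg(init)
  if (n_pcs < 2) abort("`n_pcs` must be >= 2")
  if (perplexity <= 0) abort("`perplexity` must be positive")
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  structure(
    list(n_pcs = n_pcs, perplexity = perplexity,
         learning_rate = learning_rate, n_iter = n_iter,
         seed = as.integer(seed), init = init,
         early_exaggeration = early_exaggeration,
         exaggeration_iter = exaggeration_iter),
    class = "vc_tsne_params"
  )
}

#' PCA preprocessing of a transformed expression matrix
#'
#' Projects samples onto the top principal components of the
#' samples x genes matrix (genes centred). The effective number of
#' components is `min(n_pcs, n_samples - 1, n_genes)`, so a 49-sample
#' cohort asked for 50 components receives 48; smaller settings (such as 25
#' components for a small cohort) are an explicit override. Component signs
#' are fixed by making the largest-magnitude gene loading positive, so
#' scores are reproducible and permutation-equivariant.
#'
#' @param X_t Transformed expression matrix (genes x samples), all finite.
#' @param n_pcs Requested number of components.
#' @return A samples x effective_pcs score matrix with sample ids as row
#'   names; attributes `explained_variance` (per-component variances),
#'   `total_variance` (total variance of the centred input) and `transform`
#'   (carried through from `X_t`).
#' @export
pca_reduce <- function(X_t, n_pcs = 50) {
  if (!all(is.finite(X_t))) abort("`X_t` must be finite")
  n <- ncol(X_t)
  if (n < 3) abort("PCA preprocessing needs at least 3 samples")
  eff <- min(n_pcs, n - 1, nrow(X_t))
  M <- t(X_t)                             # samples x genes
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M, nu = eff, nv = eff)
  # sign convention: largest |loading| positive per component
  flip <- vapply(seq_len(eff), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(eff)], eff), 2, flip, "*")
  rownames(scores) <- colnames(X_t)
  colnames(scores) <- sprintf("PC%d", seq_len(eff))
  attr(scores, "explained_variance") <- (sv$d[seq_len(eff)]^2) / (n - 1)
  attr(scores, "total_variance") <- sum(M^2) / (n - 1)
  attr(scores, "transform") <- attr(X_t, "transform")
  scores
}

# Conditional affinities with per-point bandwidths calibrated by binary
# search to the target perplexity (entropy in nats = log(perplexity)).
tsne_affinities <- function(D, perplexity, tol = 1e-5, max_iter = 64) {
  n <- nrow(D)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    # shifting distances by their minimum leaves the conditional
    # distribution unchanged and keeps exp() in range for heavy-tailed input
    d <- d - min(d)
    beta <- 1 / max(mean(d), .Machine$double.eps)
    lo <- -Inf; hi <- Inf
    for (iter in seq_len(max_iter)) {
      p <- exp(-d * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(d * p) / sp
      diff <- H - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- exp(-d * beta) / sum(exp(-d * beta))
  }
  P
}

#' Embed PCA scores with t-SNE
#'
#' Standard t-SNE: per-sample Gaussian bandwidths calibrated by binary
#' search to the stated perplexity, symmetrised and normalised affinities,
#' Student-t low-dimensional kernel, and KL divergence minimised by
#' momentum gradient descent with adaptive gains and early exaggeration.
#' Deterministic given the seed (and fully deterministic under the default
#' PCA initialisation).
#'
#' @param scores Samples x components matrix from [pca_reduce()].
#' @param params A [tsne_params()] object.
#' @param unit Expression unit recorded in provenance (default `"FPKM"`).
#' @param transform Transform kind for provenance; defaults to the
#'   `transform` attribute of `scores` when present.
#' @return A `vc_embedding`; `cost_trace` holds the KL divergence (on the
#'   unexaggerated affinities) recorded every 25 iterations and at the end.
#' @export
tsne_embed <- function(scores, params = tsne_params(), unit = "FPKM",
                       transform = NULL) {
  n <- nrow(scores)
  if (params$perplexity >= n) {
    abort(sprintf("perplexity (%g) must be below the number of samples (%d)",
                  params$perplexity, n))
  }
  transform <- transform %||% attr(scores, "transform") %||% "unprocessed"
  D <- row_sq_dist(scores)
  P <- tsne_affinities(D, params$perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  if (params$init == "pca") {
    sv <- svd(sweep(scores, 2, colMeans(scores)), nu = 2, nv = 2)
    Y <- sv$u %*% diag(sv$d[1:2], 2)
    Y <- Y / stats::sd(Y[, 1]) * 1e-4
  } else {
    set.seed(params$seed)
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  }

  kl <- function(Q) sum(P * log(P / Q))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  trace <- numeric(0)
  lr <- params$learning_rate
  best_kl <- Inf
  best_Y <- Y
  for (it in seq_len(params$n_iter)) {
    num <- 1 / (1 + row_sq_dist(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    if (it == 1 || it %% 25 == 0) {
      cur <- kl(Q)
      trace <- c(trace, cur)
      # best-iterate safeguard: a checkpoint KL above the best seen means
      # the step size overshoots on this instance — back up and damp
      if (cur > best_kl) {
        Y <- best_Y
        inc[] <- 0
        gains[] <- 1
        lr <- lr / 2
        next
      }
      best_kl <- cur
      best_Y <- Y
    }
    Pnow <- if (it <= params$exaggeration_iter) P * params$early_exaggeration else P
    PQ <- (Pnow - Q) * num
    grad <- 4 * (diag(rowSums(PQ)) - PQ) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
    inc <- mom * inc - lr * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  num <- 1 / (1 + row_sq_dist(Y))
  diag(num) <- 0
  final_kl <- kl(pmax(num / sum(num), 1e-12))
  if (final_kl <= best_kl) {
    best_kl <- final_kl
    best_Y <- Y
  }
  Y <- best_Y
  trace <- c(trace, best_kl)
  new_embedding(
    coords = Y,
    sample_ids = rownames(scores) %||% as.character(seq_len(n)),
    provenance = list(unit = unit, transform = transform,
                      method = "t-SNE", method_label = "t-SNE",
                      params = unclass(params), seed = params$seed),
    cost_trace = trace
  )
}

#' Full t-SNE stage on a transformed expression matrix
#'
#' Convenience composition of [pca_reduce()] and [tsne_embed()].
#'
#' @param X_t Transformed expression matrix (genes x samples).
#' @inheritParams tsne_embed
#' @return A `vc_embedding`.
#' @export
tsne_map <- function(X_t, params = tsne_params(), unit = "FPKM") {
  scores <- pca_reduce(X_t, params$n_pcs)
  tsne_embed(scores, params, unit = unit)
}
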