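#' Specification for a synthetic FPKM cohort
#'
#' Describes the generative model used by [generate_fpkm()] and
#' [generate_gradient_cohort()]: a log-normal FPKM baseline with
#' multiplicative subgroup effects on disjoint marker-gene panels,
#' independent zero-inflation (exact zeros, as in real FPKM tables),
#' resection-site labels drawn independently of expression, and an optional
#' primary-to-metastatic mixing gradient.
#'
#' @param n_genes,n_samples Matrix dimensions (genes x samples).
#' @param n_subgroups Number of planted transcriptomic subgroups (>= 1).
#' @param n_marker_genes_per_subgroup Size of each subgroup's disjoint
#'   marker panel. `n_subgroups * n_marker_genes_per_subgroup` must not
#'   exceed `n_genes`.
#' @param log2_effect_size Mean shift of a subgroup's marker genes on the
#'   log2 scale (0 disables the planted structure).
#' @param base_log_mean,base_log_sd Mean and sd of the natural-log baseline;
#'   FPKM values are `exp(Normal(base_log_mean, base_log_sd))`.
#' @param zero_fraction Probability that any entry is set to exactly 0
#'   (in `[0, 1)`).
#' @param n_sites Number of resection-site labels, drawn uniformly and
#'   independently of expression.
#' @param gradient_fraction Fraction of samples placed on a
#'   primary-to-metastatic interpolation gradient (0 disables; only used by
#'   [generate_gradient_cohort()]).
#' @param seed Integer seed; one seed drives all draws in a fixed order.
#'
#' @return An object of class `vc_synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_genes = 200, n_samples = 60, seed = 1)
#' cohort <- generate_fpkm(spec)
#' dim(cohort$expression)
synthetic_spec <- function(n_genes = 2000,
                           n_samples = 300,
                           n_subgroups = 3,
                           n_marker_genes_per_subgroup = 200,
                           log2_effect_size = 2,
                           base_log_mean = 1,
                           base_log_sd = 1.5,
                           zero_fraction = 0.3,
                           n_sites = 5,
                           gradient_fraction = 0,
                           seed = 1L) {
  spec <- list(
    n_genes = n_genes, n_samples = n_samples, n_subgroups = n_subgroups,
    n_marker_genes_per_subgroup = n_marker_genes_per_subgroup,
    log2_effect_size = log2_effect_size, base_log_mean = base_log_mean,
    base_log_sd = base_log_sd, zero_fraction = zero_fraction,
    n_sites = n_sites, gradient_fraction = gradient_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "vc_synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  chk_count <- function(x, field, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
      abort(sprintf("invalid synthetic spec: `%s` must be a count >= %d (got %s)",
                    field, min, deparse(x)))
    }
  }
  chk_count(spec$n_genes, "n_genes")
  chk_count(spec$n_samples, "n_samples")
  chk_count(spec$n_subgroups, "n_subgroups")
  chk_count(spec$n_marker_genes_per_subgroup, "n_marker_genes_per_subgroup", min = 0)
  chk_count(spec$n_sites, "n_sites")
  if (!is.numeric(spec$log2_effect_size) || spec$log2_effect_size < 0) {
    abort("invalid synthetic spec: `log2_effect_size` must be a nonnegative real")
  }
  if (!is.numeric(spec$base_log_sd) || spec$base_log_sd <= 0) {
    abort("invalid synthetic spec: `base_log_sd` must be a positive real")
  }
  if (!is.numeric(spec$zero_fraction) || spec$zero_fraction < 0 || spec$zero_fraction >= 1) {
    abort("invalid synthetic spec: `zero_fraction` must lie in [0, 1)")
  }
  if (!is.numeric(spec$gradient_fraction) || spec$gradient_fraction < 0 ||
      spec$gradient_fraction > 1) {
    abort("invalid synthetic spec: `gradient_fraction` must lie in [0, 1]")
  }
  if (spec$n_subgroups * spec$n_marker_genes_per_subgroup > spec$n_genes) {
    abort("invalid synthetic spec: `n_marker_genes_per_subgroup` times `n_subgroups` exceeds `n_genes`")
  }
  invisible(spec)
}

site_labels <- function(n_sites) {
  pool <- c("bone", "liver", "lymph_node", "lung", "brain", "adrenal",
            "soft_tissue", "skin")
  if (n_sites <= length(pool)) pool[seq_len(n_sites)] else
    sprintf("site_%02d", seq_len(n_sites))
}

#' Generate a synthetic FPKM cohort with planted subgroups
#'
#' Draw order under the single seed: (1) balanced random subgroup
#' assignment, (2) log-normal baseline matrix, (3) marker genes of each
#' sample's subgroup multiplied by `2^log2_effect_size`, (4) independent
#' zeroing of entries with probability `zero_fraction`, (5) site labels
#' uniform and independent of expression. Same spec and seed give
#' bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `vc_cohort` with elements `expression`
#'   (nonnegative genes x samples matrix with gene/sample dimnames) and
#'   `annotations` (tibble: `sample_id`, `site`, `sample_type`,
#'   `subgroup_truth`). Attribute `marker_genes` holds the per-subgroup
#'   marker panels; attribute `signal` the noiseless log-mean matrix.
#' @export
generate_fpkm <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  ng <- spec$n_genes; ns <- spec$n_samples; k <- spec$n_subgroups
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  sample_ids <- sprintf("sample_%04d", seq_len(ns))

  subgroup <- sample(rep_len(seq_len(k), ns))
  signal <- matrix(spec$base_log_mean, ng, ns,
                   dimnames = list(gene_ids, sample_ids))
  m <- spec$n_marker_genes_per_subgroup
  markers <- lapply(seq_len(k), function(s) gene_ids[((s - 1) * m + 1):(s * m)])
  if (m == 0) markers <- rep(list(character(0)), k)
  shift <- spec$log2_effect_size * log(2)
  for (s in seq_len(k)) {
    if (m > 0) signal[((s - 1) * m + 1):(s * m), subgroup == s] <-
        signal[((s - 1) * m + 1):(s * m), subgroup == s] + shift
  }
  values <- exp(signal + matrix(rnorm(ng * ns, 0, spec$base_log_sd), ng, ns))
  if (spec$zero_fraction > 0) {
    values[matrix(runif(ng * ns), ng, ns) < spec$zero_fraction] <- 0
  }
  site <- sample(site_labels(spec$n_sites), ns, replace = TRUE)

  ann <- tibble(
    sample_id = sample_ids,
    site = site,
    sample_type = "metastatic",
    subgroup_truth = sprintf("subgroup_%d", subgroup)
  )
  structure(
    list(expression = values, annotations = ann),
    marker_genes = stats::setNames(markers, sprintf("subgroup_%d", seq_len(k))),
    signal = signal,
    class = "vc_cohort"
  )
}

#' Generate a cohort with a primary-to-metastatic expression gradient
#'
#' A fraction `gradient_fraction` of samples receive a per-sample mixing
#' weight uniform on `[0, 1]` and their (log-scale) expression pattern is the
#' linear interpolation between a "primary" and a "metastatic" centroid
#' profile at that weight, before log-normal noise and zero-inflation. The
#' remaining samples sit at the pure endpoints (weight 0 or 1, alternating).
#' `sample_type` is assigned by thresholding the weight at 0.5.
#'
#' Draw order under the single seed: (1) gradient-sample selection,
#' (2) mixing weights, (3) noise matrix, (4) zero mask, (5) site labels.
#'
#' @inheritParams generate_fpkm
#' @return A `vc_cohort` as in [generate_fpkm()]; `annotations` gains a
#'   `mixing_weight` column and `subgroup_truth` is `NA`. Attribute
#'   `centroids` holds the two log-scale centroid profiles.
#' @export
generate_gradient_cohort <- function(spec) {
  validate_synthetic_spec(spec)
  if (spec$gradient_fraction == 0) {
    abort("`gradient_fraction` is 0: use `generate_fpkm()` for a gradient-free cohort")
  }
  set.seed(spec$seed)
  ng <- spec$n_genes; ns <- spec$n_samples
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  sample_ids <- sprintf("sample_%04d", seq_len(ns))

  m <- max(spec$n_marker_genes_per_subgroup, 1)
  shift <- spec$log2_effect_size * log(2)
  centroid_primary <- rep(spec$base_log_mean, ng)
  centroid_metastatic <- centroid_primary
  centroid_metastatic[seq_len(m)] <- centroid_metastatic[seq_len(m)] + shift

  n_grad <- ceiling(spec$gradient_fraction * ns)
  grad_idx <- sort(sample(ns, n_grad))
  weight <- rep_len(c(0, 1), ns)           # pure endpoints
  weight[grad_idx] <- runif(n_grad)

  signal <- outer(centroid_primary, rep(1, ns)) +
    outer(centroid_metastatic - centroid_primary, weight)
  dimnames(signal) <- list(gene_ids, sample_ids)
  values <- exp(signal + matrix(rnorm(ng * ns, 0, spec$base_log_sd), ng, ns))
  if (spec$zero_fraction > 0) {
    values[matrix(runif(ng * ns), ng, ns) < spec$zero_fraction] <- 0
  }
  site <- sample(site_labels(spec$n_sites), ns, replace = TRUE)

  ann <- tibble(
    sample_id = sample_ids,
    site = site,
    sample_type = ifelse(weight > 0.5, "metastatic", "primary"),
    subgroup_truth = NA_character_,
    mixing_weight = weight
  )
  structure(
    list(expression = values, annotations = ann),
    centroids = list(primary = centroid_primary, metastatic = centroid_metastatic),
    signal = signal,
    class = "vc_cohort"
  )
}

#' @export
print.vc_cohort <- function(x, ...) {
  cat(sprintf("<vc_cohort> %d genes x %d samples; %.1f%% zeros\n",
              nrow(x$expression), ncol(x$expression),
              100 * mean(x$expression == 0)))
  invisible(x)
}
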