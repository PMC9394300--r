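#' Association between a clustering and a sample label
#'
#' Quantifies what the eye judges in an annotated embedding: how strongly
#' do cluster assignments align with an external label (resection site,
#' sample type, planted subgroup)? Reports the adjusted Rand index, the
#' chi-square statistic of the cluster x label contingency table and
#' Cramer's V derived from it. With a single cluster or a single label
#' level the chi-square and V are undefined and reported as `NA`.
#'
#' @param clusters A `vc_cluster`, or a vector of cluster labels.
#' @param labels A vector of sample labels aligned with the clustering (for
#'   a `vc_cluster`, a named vector is realigned by sample id).
#' @return A one-row tibble: `n_clusters`, `n_levels`, `ari`, `chisq`,
#'   `cramers_v`.
#' @export
#' @examples
#' cl <- c(0, 0, 1, 1)
#' association_metrics(cl, c("a", "a", "b", "b"))
association_metrics <- function(clusters, labels) {
  if (inherits(clusters, "vc_cluster")) {
    if (!is.null(names(labels))) {
      missing <- setdiff(names(clusters$labels), names(labels))
      if (length(missing) > 0) {
        abort(sprintf("labels missing for samples: %s",
                      paste(head(missing, 5), collapse = ", ")))
      }
      labels <- labels[names(clusters$labels)]
    }
    clusters <- clusters$labels
  }
  if (length(clusters) != length(labels)) {
    abort("`clusters` and `labels` must have the same length")
  }
  keep <- !is.na(labels)
  clusters <- clusters[keep]; labels <- labels[keep]
  tab <- table(clusters, labels)
  r <- nrow(tab); s <- ncol(tab)
  ari <- mclust::adjustedRandIndex(clusters, labels)
  if (r < 2 || s < 2) {
    chisq <- NA_real_; v <- NA_real_
  } else {
    chisq <- unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic)
    v <- sqrt(chisq / (sum(tab) * (min(r, s) - 1)))
  }
  tibble(n_clusters = r, n_levels = s, ari = ari, chisq = chisq,
         cramers_v = v)
}
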