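#' Scale-dependent k-NN overlap between two embeddings
#'
#' For every pair of neighbourhood scales `(k_a, k_b)` the entry is the mean
#' over samples of `|NN_A(i, k_a) intersect NN_B(i, k_b)| / min(k_a, k_b)`,
#' with neighbour sets computed independently in each map (Euclidean
#' metric, distance ties broken by sample index). Small scales probe local
#' structure preservation, large scales global structure. Comparing a map
#' with itself gives 1 everywhere (same-map neighbour sets are nested), and
#' swapping the two maps transposes the matrix.
#'
#' @param embA,embB Two embeddings (`vc_embedding`, matrix, or tidy
#'   data frame) over the *same* sample set.
#' @param scales Ordered neighbour counts; defaults to
#'   `c(1, 2, 5, 10, 25, 50, 100, 250)` truncated below the sample count.
#' @return An object of class `vc_similarity`: list with `scales`, `values`
#'   (the scales x scales grid) and `provenance` (a two-row tibble
#'   describing the maps when available).
#' @export
neighbor_overlap <- function(embA, embB, scales = NULL) {
  idsA <- embedding_ids(embA); idsB <- embedding_ids(embB)
  if (!setequal(idsA, idsB) || length(idsA) != length(idsB)) {
    onlyA <- setdiff(idsA, idsB); onlyB <- setdiff(idsB, idsA)
    abort(sprintf(
      "sample sets differ between the two embeddings (only in A: %s; only in B: %s)",
      paste(head(onlyA, 5), collapse = ", ") %|e|% "none",
      paste(head(onlyB, 5), collapse = ", ") %|e|% "none"))
  }
  YA <- embedding_coords(embA)
  YB <- embedding_coords(embB)[match(idsA, idsB), , drop = FALSE]
  n <- nrow(YA)
  scales <- scales %||% c(1, 2, 5, 10, 25, 50, 100, 250)
  scales <- sort(unique(as.integer(scales[scales < n])))
  if (length(scales) == 0) abort("no usable scales below the sample count")
  kmax <- max(scales)
  nnA <- nn_index_matrix(row_sq_dist(YA), kmax)
  nnB <- nn_index_matrix(row_sq_dist(YB), kmax)

  vals <- matrix(NA_real_, length(scales), length(scales),
                 dimnames = list(scales, scales))
  for (a in seq_along(scales)) {
    for (b in seq_along(scales)) {
      ka <- scales[a]; kb <- scales[b]
      ov <- vapply(seq_len(n), function(i) {
        length(intersect(nnA[i, seq_len(ka)], nnB[i, seq_len(kb)]))
      }, numeric(1))
      vals[a, b] <- mean(ov) / min(ka, kb)
    }
  }
  prov <- tryCatch(
    dplyr::bind_rows(A = glance(embA), B = glance(embB), .id = "map"),
    error = function(e) NULL)
  structure(list(scales = scales, values = vals, provenance = prov),
            class = "vc_similarity")
}

`%|e|%` <- function(x, y) if (nchar(x) == 0) y else x

#' @export
print.vc_similarity <- function(x, ...) {
  cat(sprintf("<vc_similarity> %d scales (%s); mean overlap %.3f\n",
              length(x$scales), paste(x$scales, collapse = ", "),
              mean(x$values)))
  invisible(x)
}

#' Tidy a similarity matrix into long format
#' @param x A `vc_similarity`.
#' @param ... Unused.
#' @return A tibble with columns `k_a`, `k_b`, `overlap`.
#' @method tidy vc_similarity
#' @export
tidy.vc_similarity <- function(x, ...) {
  grid <- expand.grid(k_a = x$scales, k_b = x$scales, KEEP.OUT.ATTRS = FALSE)
  tibble(k_a = grid$k_a, k_b = grid$k_b,
         overlap = as.vector(x$values[cbind(match(grid$k_a, x$scales),
                                            match(grid$k_b, x$scales))]))
}

#' Heatmap of a scale-dependent similarity matrix
#' @param object A `vc_similarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vc_similarity
#' @export
autoplot.vc_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$k_a), factor(.data$k_b),
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "neighbourhood scale, map A",
                  y = "neighbourhood scale, map B",
                  fill = "mean k-NN\noverlap") +
    ggplot2::theme_minimal()
}

#' Local and global structure-preservation summary
#'
#' Averages the diagonal (equal-scale) entries of a similarity matrix over
#' the small scales (`k <= local_max_k`) and over the large scales
#' (`k >= global_min_k`). A local mean below the global mean indicates that
#' two maps agree on coarse organisation while arranging immediate
#' neighbourhoods differently.
#'
#' @param S A `vc_similarity`.
#' @param local_max_k Largest scale counted as local.
#' @param global_min_k Smallest scale counted as global.
#' @return A one-row tibble with `mean_local` and `mean_global`.
#' @export
local_global_summary <- function(S, local_max_k = 10, global_min_k = 100) {
  d <- diag(S$values)
  loc <- d[S$scales <= local_max_k]
  glo <- d[S$scales >= global_min_k]
  if (length(loc) == 0 || length(glo) == 0) {
    abort("empty scale selection: adjust `local_max_k` / `global_min_k` to the available scales")
  }
  tibble(mean_local = mean(loc), mean_global = mean(glo))
}
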