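#' Construct a cluster result
#' @keywords internal
new_cluster_result <- function(labels, sample_ids, method, params, seed) {
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  structure(
    list(labels = stats::setNames(labels, sample_ids), method = method,
         params = params, seed = seed),
    class = "vc_cluster"
  )
}

#' @export
print.vc_cluster <- function(x, ...) {
  cat(sprintf("<vc_cluster> %s: %d samples in %d clusters\n",
              cluster_label(x), length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Tidy a cluster result into a per-sample tibble
#' @param x A `vc_cluster`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `label` (integers from 0),
#'   `method`.
#' @method tidy vc_cluster
#' @export
tidy.vc_cluster <- function(x, ...) {
  tibble(sample_id = names(x$labels),
         label = unname(x$labels),
         method = cluster_label(x))
}

#' One-row summary of a cluster result
#' @param x A `vc_cluster`.
#' @param ... Unused.
#' @return A one-row tibble: method, parameter string, cluster count, seed.
#' @method glance vc_cluster
#' @export
glance.vc_cluster <- function(x, ...) {
  tibble(method = x$method,
         params = cluster_label(x),
         n_clusters = length(unique(x$labels)),
         seed = x$seed)
}

# Short display label, e.g. "k-means(k=3)" or "Leiden(res=0.05)".
cluster_label <- function(x) {
  if (x$method == "kmeans") sprintf("k-means(k=%d)", x$params$k)
  else sprintf("Leiden(res=%g)", x$params$resolution)
}

#' k-means clustering of an embedding
#'
#' Lloyd's algorithm on the 2-D embedding coordinates with a seeded
#' multi-restart (10 restarts, best within-cluster sum of squares kept).
#'
#' @param emb A `vc_embedding` (or n x 2 coordinate matrix).
#' @param k Number of clusters, `2 <= k <= n_samples - 1`.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @return A `vc_cluster`; element `wss` holds the total within-cluster sum
#'   of squares.
#' @export
kmeans_cluster <- function(emb, k, seed = 1L, nstart = 10) {
  Y <- embedding_coords(emb)
  n <- nrow(Y)
  if (k < 2 || k > n - 1) {
    abort(sprintf("`k` must lie in [2, %d] for %d samples (got %d)",
                  n - 1, n, k))
  }
  set.seed(seed)
  km <- kmeans(Y, centers = k, nstart = nstart, iter.max = 100)
  res <- new_cluster_result(km$cluster, embedding_ids(emb), "kmeans",
                            list(k = as.integer(k)), as.integer(seed))
  res$wss <- km$tot.withinss
  res
}

#' Select a cluster count by the elbow method
#'
#' Computes the within-cluster sum of squares WSS(k) over `k_range`
#' (together with the exact WSS at k = 1, the total centred sum of squares,
#' so that the smallest k in the range is a candidate) and returns the k
#' maximising the discrete second difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)`; ties go to the smallest k. When the
#' curve has no pronounced elbow — the WSS step into the candidate k removes
#' less than 60% of the remaining WSS, as for a smooth `1/k` decay — the
#' boundary default `min(k_range)` is returned with a message and attribute
#' `low_confidence = TRUE`.
#'
#' @param emb A `vc_embedding` or coordinate matrix.
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param seed Integer seed for the k-means restarts.
#' @return An integer k with attributes `wss` (the profile, named by k,
#'   including k = 1) and `low_confidence`.
#' @export
elbow_select_k <- function(emb, k_range = 2:10, seed = 1L) {
  Y <- embedding_coords(emb)
  n <- nrow(Y)
  if (all(row_sq_dist(Y) == 0)) {
    abort("degenerate embedding: all points identical, no elbow exists")
  }
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) < 2) abort("`k_range` must contain at least two usable values")
  ks <- c(1L, k_range)
  wss <- vapply(ks, function(k) {
    if (k == 1) sum(sweep(Y, 2, colMeans(Y))^2)
    else {
      set.seed(derive_seed(seed, k))
      kmeans(Y, centers = k, nstart = 10, iter.max = 100)$tot.withinss
    }
  }, numeric(1))
  names(wss) <- ks
  # second differences at interior positions of the extended curve
  interior <- 2:(length(ks) - 1)
  d2 <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
  best <- interior[which.max(d2)]
  # scale-free elbow strength: fraction of WSS removed at the elbow step.
  # A pronounced elbow removes nearly everything (~1); a smooth 1/k decay
  # removes at most ~1/2.
  confidence <- 1 - wss[best] / max(wss[best - 1], .Machine$double.eps)
  low <- confidence < 0.6
  k_sel <- if (low) {
    inform(sprintf(
      "no clear elbow (confidence %.2f); falling back to k = %d", confidence,
      min(k_range)))
    min(k_range)
  } else ks[best]
  structure(as.integer(k_sel), wss = wss, low_confidence = low)
}

#' k-nearest-neighbour graph of an embedding
#'
#' Undirected union of the directed k-NN relations on the 2-D coordinates
#' (Euclidean metric, distance ties broken by sample index), all edge
#' weights 1. The graph is invariant under rigid motions of the embedding.
#'
#' @param emb A `vc_embedding` or coordinate matrix.
#' @param n_neighbors Directed out-degree; must be below the sample count.
#' @return An `igraph` undirected graph with vertex names set to sample ids
#'   and graph attribute `n_neighbors`.
#' @export
knn_graph <- function(emb, n_neighbors = 15) {
  Y <- embedding_coords(emb)
  n <- nrow(Y)
  if (n_neighbors >= n) {
    abort(sprintf("`n_neighbors` (%d) must be below the number of samples (%d)",
                  n_neighbors, n))
  }
  nn <- nn_index_matrix(row_sq_dist(Y), n_neighbors)
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- embedding_ids(emb)
  g <- igraph::set_graph_attr(g, "n_neighbors", as.integer(n_neighbors))
  igraph::E(g)$weight <- 1
  g
}

#' Leiden community detection on a neighbour graph
#'
#' Runs the Leiden algorithm with the modularity objective (the
#' Reichardt-Bornholdt configuration null model) at the given resolution.
#' Seeded for determinism.
#'
#' @param graph An `igraph` graph, e.g. from [knn_graph()].
#' @param resolution Resolution parameter (larger values give more, smaller
#'   communities).
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations (`-1` = until stable).
#' @return A `vc_cluster` with method `"leiden"`.
#' @export
leiden_cluster <- function(graph, resolution = 1, seed = 1L,
                           n_iterations = -1) {
  if (!igraph::is_igraph(graph)) abort("`graph` must be an igraph object")
  if (igraph::vcount(graph) == 0) abort("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  nn <- igraph::graph_attr(graph, "n_neighbors")
  new_cluster_result(igraph::membership(cl), ids, "leiden",
                     list(resolution = resolution,
                          n_neighbors = if (is.null(nn)) NA_integer_ else nn),
                     as.integer(seed))
}
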