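#' Configuration for the comparison grid
#'
#' Describes one full run of the method x transformation comparison: which
#' transforms and dimension-reduction methods to cross, the stage
#' parameters, the clustering grids (k-means k in 2..4 plus the
#' elbow-selected k; Leiden at (n_neighbors, resolution) in
#' \{15, 50, 100\} x \{0.05\} plus (15, 1)), and the neighbourhood scales of
#' the map-similarity stage. One config seed drives every stage through a
#' fixed documented derivation, so the grid is reproducible as a unit.
#'
#' @param transforms Subset of `c("unprocessed", "log10", "log10p1")`.
#' @param methods Subset of `c("tsne", "umap")`.
#' @param tsne,umap Stage parameter objects ([tsne_params()],
#'   [umap_params()]); their `seed` fields are overridden by the derived
#'   per-cell seeds.
#' @param kmeans_k Integer vector of k-means cluster counts.
#' @param leiden_grid Data frame with columns `n_neighbors`, `resolution`.
#' @param scales Neighbourhood scales for [neighbor_overlap()].
#' @param local_max_k,global_min_k Thresholds for
#'   [local_global_summary()]; `global_min_k` is lowered to the largest
#'   available scale when needed.
#' @param unit Expression unit recorded in all provenance.
#' @param seed Integer master seed.
#' @return An object of class `vc_grid_config`.
#' @export
grid_config <- function(transforms = c("unprocessed", "log10", "log10p1"),
                        methods = c("tsne", "umap"),
                        tsne = tsne_params(),
                        umap = umap_params(),
                        kmeans_k = 2:4,
                        leiden_grid = data.frame(
                          n_neighbors = c(15, 50, 100, 15),
                          resolution = c(0.05, 0.05, 0.05, 1)),
                        scales = c(1, 2, 5, 10, 25, 50, 100, 250),
                        local_max_k = 10, global_min_k = 100,
                        unit = "FPKM", seed = 1L) {
  transforms <- match.arg(transforms, c("unprocessed", "log10", "log10p1"),
                          several.ok = TRUE)
  methods <- match.arg(methods, c("tsne", "umap"), several.ok = TRUE)
  if (length(transforms) == 0 || length(methods) == 0) {
    abort("`transforms` and `methods` must be non-empty")
  }
  structure(
    list(transforms = transforms, methods = methods, tsne = tsne,
         umap = umap, kmeans_k = as.integer(kmeans_k),
         leiden_grid = leiden_grid, scales = scales,
         local_max_k = local_max_k, global_min_k = global_min_k,
         unit = unit, seed = as.integer(seed)),
    class = "vc_grid_config"
  )
}

# Fixed seed-derivation offsets: cells are enumerated methods-major in config
# order; clustering seeds add a further offset per clustering index.
cell_offset <- function(method_idx, transform_idx) {
  100L * method_idx + transform_idx
}

#' Run the full comparison grid
#'
#' For every (method, transform) cell: transform the matrix, embed it,
#' cluster the embedding over the configured k-means and Leiden grids, and
#' measure cluster-label associations (adjusted Rand index against site,
#' sample type and - when present - planted subgroup, plus Cramer's V for
#' site). Within each method, every pair of transforms is compared with the
#' scale-dependent k-NN overlap. When `out_dir` is given the bundle is
#' written to disk: one directory per cell (`<method>__<transform>` with
#' embedding TSV + provenance JSON + cluster TSV), `similarity/`,
#' `figures/` (embeddings coloured by site and sample type, each carrying
#' its UTMC legend) and a machine-readable `summary.json`.
#'
#' @param X Expression matrix (genes x samples) or a `vc_cohort`.
#' @param annotations Annotation tibble (`sample_id`, `site`,
#'   `sample_type`, optional `subgroup_truth`); taken from the cohort when
#'   `X` is a `vc_cohort`.
#' @param config A [grid_config()].
#' @param out_dir Optional output directory.
#' @param figures Write figures? Defaults to `TRUE` when `out_dir` is
#'   given.
#' @return A list of class `vc_grid`: `embeddings` (named list of
#'   `vc_embedding`), `clusterings` (named list of lists of `vc_cluster`),
#'   `associations` (tibble), `similarities` (named list of
#'   `vc_similarity`), `similarity_summary` (tibble), `config`.
#' @export
run_grid <- function(X, annotations = NULL, config = grid_config(),
                     out_dir = NULL, figures = !is.null(out_dir)) {
  if (inherits(X, "vc_cohort")) {
    annotations <- annotations %||% X$annotations
    X <- X$expression
  }
  validate_expression_matrix(X)
  if (is.null(annotations)) abort("`annotations` is required")
  absent <- setdiff(colnames(X), annotations$sample_id)
  if (length(absent) > 0) {
    abort(sprintf("annotation missing samples present in the matrix: %s",
                  paste(head(absent, 10), collapse = ", ")))
  }
  ann <- annotations[match(colnames(X), annotations$sample_id), ]
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  embeddings <- list()
  clusterings <- list()
  assoc_rows <- list()
  for (mi in seq_along(config$methods)) {
    method <- config$methods[mi]
    for (ti in seq_along(config$transforms)) {
      tr <- config$transforms[ti]
      cell <- sprintf("%s__%s", method, tr)
      cell_seed <- derive_seed(config$seed, cell_offset(mi, ti))
      X_t <- apply_transform(X, tr)
      emb <- if (method == "tsne") {
        p <- config$tsne; p$seed <- cell_seed
        tsne_map(X_t, p, unit = config$unit)
      } else {
        p <- config$umap; p$seed <- cell_seed
        umap_adapted_embed(X_t, p, unit = config$unit)
      }
      embeddings[[cell]] <- emb

      cls <- list()
      ci <- 0L
      k_elbow <- tryCatch(
        suppressMessages(elbow_select_k(
          emb, seed = derive_seed(cell_seed, 900L))),
        error = function(e) NA_integer_)
      for (k in unique(c(config$kmeans_k,
                         if (!is.na(k_elbow)) as.integer(k_elbow)))) {
        ci <- ci + 1L
        cls[[sprintf("kmeans_k%d", k)]] <-
          kmeans_cluster(emb, k, seed = derive_seed(cell_seed, ci))
      }
      for (li in seq_len(nrow(config$leiden_grid))) {
        ci <- ci + 1L
        nn <- config$leiden_grid$n_neighbors[li]
        if (nn >= ncol(X)) next
        res <- config$leiden_grid$resolution[li]
        g <- knn_graph(emb, nn)
        cls[[sprintf("leiden_nn%d_res%g", nn, res)]] <-
          leiden_cluster(g, res, seed = derive_seed(cell_seed, ci))
      }
      clusterings[[cell]] <- cls

      for (nm in names(cls)) {
        cl <- cls[[nm]]
        row_site <- association_metrics(cl, stats::setNames(ann$site, ann$sample_id))
        row_type <- association_metrics(cl, stats::setNames(ann$sample_type, ann$sample_id))
        ari_sub <- if (!is.null(ann$subgroup_truth) &&
                       any(!is.na(ann$subgroup_truth))) {
          association_metrics(
            cl, stats::setNames(ann$subgroup_truth, ann$sample_id))$ari
        } else NA_real_
        assoc_rows[[length(assoc_rows) + 1L]] <- tibble(
          method = method, transform = tr, clustering = nm,
          clustering_label = cluster_label(cl),
          n_clusters = row_site$n_clusters,
          ari_site = row_site$ari, cramers_v_site = row_site$cramers_v,
          chisq_site = row_site$chisq,
          ari_sample_type = row_type$ari, ari_subgroup = ari_sub)
      }
    }
  }
  associations <- dplyr::bind_rows(assoc_rows)

  similarities <- list()
  sim_rows <- list()
  if (length(config$transforms) >= 2) {
    pairs <- utils::combn(config$transforms, 2, simplify = FALSE)
    for (method in config$methods) {
      for (pr in pairs) {
        key <- sprintf("%s__%s__vs__%s", method, pr[1], pr[2])
        S <- neighbor_overlap(embeddings[[sprintf("%s__%s", method, pr[1])]],
                              embeddings[[sprintf("%s__%s", method, pr[2])]],
                              scales = config$scales)
        similarities[[key]] <- S
        gk <- min(config$global_min_k, max(S$scales))
        lg <- local_global_summary(S, config$local_max_k, gk)
        sim_rows[[length(sim_rows) + 1L]] <- tibble(
          method = method, transform_a = pr[1], transform_b = pr[2],
          mean_overlap = mean(S$values),
          mean_local = lg$mean_local, mean_global = lg$mean_global)
      }
    }
  }
  similarity_summary <- dplyr::bind_rows(sim_rows)

  out <- structure(
    list(embeddings = embeddings, clusterings = clusterings,
         associations = associations, similarities = similarities,
         similarity_summary = similarity_summary, config = config),
    class = "vc_grid"
  )
  if (!is.null(out_dir)) write_grid_bundle(out, ann, out_dir, figures)
  out
}

write_grid_bundle <- function(grid, ann, out_dir, figures) {
  for (cell in names(grid$embeddings)) {
    cell_dir <- file.path(out_dir, cell)
    dir.create(cell_dir, showWarnings = FALSE)
    write_embedding(grid$embeddings[[cell]],
                    file.path(cell_dir, "embedding.tsv"))
    cl_tab <- dplyr::bind_rows(
      lapply(grid$clusterings[[cell]], tidy), .id = "clustering")
    readr::write_tsv(cl_tab, file.path(cell_dir, "clusters.tsv"))
  }
  sim_dir <- file.path(out_dir, "similarity")
  dir.create(sim_dir, showWarnings = FALSE)
  for (key in names(grid$similarities)) {
    readr::write_tsv(tidy(grid$similarities[[key]]),
                     file.path(sim_dir, paste0(key, ".tsv")))
  }
  readr::write_tsv(grid$associations, file.path(out_dir, "associations.tsv"))
  if (figures) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (cell in names(grid$embeddings)) {
      emb <- grid$embeddings[[cell]]
      for (field in c("site", "sample_type")) {
        render_embedding_plot(
          emb, colour_by = stats::setNames(ann[[field]], ann$sample_id),
          out_path = file.path(fig_dir, sprintf("%s__%s.png", cell, field)))
      }
    }
  }
  summary <- list(
    seed = grid$config$seed,
    methods = grid$config$methods,
    transforms = grid$config$transforms,
    n_samples = length(grid$embeddings[[1]]$sample_ids),
    embeddings = lapply(grid$embeddings, function(e) {
      g <- glance(e); as.list(g)
    }),
    associations = grid$associations,
    similarity = grid$similarity_summary
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.vc_grid <- function(x, ...) {
  cat(sprintf("<vc_grid> %d embeddings (%s x %s); %d association rows\n",
              length(x$embeddings),
              paste(x$config$methods, collapse = "/"),
              paste(x$config$transforms, collapse = "/"),
              nrow(x$associations)))
  invisible(x)
}
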