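#' Construct an embedding object
#'
#' Internal constructor shared by the t-SNE and adapted-UMAP stages. An
#' embedding is a fitted object: n x 2 coordinates plus full provenance
#' (expression unit, transform, method, parameter record, seed) so that any
#' figure or table derived from it can carry a complete UTMC legend.
#'
#' @param coords Numeric n x 2 matrix of finite coordinates.
#' @param sample_ids Character vector, one id per row of `coords`.
#' @param provenance Named list with at least `unit`, `transform`, `method`,
#'   `method_label`, `params`, `seed`.
#' @param cost_trace Optional numeric vector of the optimiser's cost per
#'   recorded iteration.
#' @return An object of class `vc_embedding`.
#' @keywords internal
new_embedding <- function(coords, sample_ids, provenance, cost_trace = NULL) {
  if (!is.matrix(coords) || ncol(coords) != 2 || !all(is.finite(coords))) {
    abort("embedding coordinates must be a finite n x 2 matrix")
  }
  if (length(sample_ids) != nrow(coords) || anyDuplicated(sample_ids)) {
    abort("`sample_ids` must be unique, one per embedding row")
  }
  needed <- c("unit", "transform", "method", "method_label", "params", "seed")
  missing <- setdiff(needed, names(provenance))
  if (length(missing) > 0) {
    abort(sprintf("embedding provenance is incomplete: missing %s",
                  paste(missing, collapse = ", ")))
  }
  rownames(coords) <- sample_ids
  structure(
    list(coords = coords, sample_ids = as.character(sample_ids),
         provenance = provenance, cost_trace = cost_trace),
    class = "vc_embedding"
  )
}

#' @export
print.vc_embedding <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<vc_embedding> %d samples | %s on %s-transformed %s (seed %s)\n",
              nrow(x$coords), p$method, transform_label(p$transform),
              p$unit, p$seed))
  invisible(x)
}

#' @export
as.matrix.vc_embedding <- function(x, ...) x$coords

#' Tidy an embedding into a per-sample tibble
#'
#' @param x A `vc_embedding`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `x`, `y`.
#' @method tidy vc_embedding
#' @export
tidy.vc_embedding <- function(x, ...) {
  co <- x$coords
  tibble(sample_id = x$sample_ids, x = co[, 1], y = co[, 2])
}

#' One-row summary of an embedding
#'
#' @param x A `vc_embedding`.
#' @param ... Unused.
#' @return A one-row tibble: method, transform, unit, sample count, seed and
#'   the optimiser's initial/final cost (NA when no trace was recorded).
#' @method glance vc_embedding
#' @export
glance.vc_embedding <- function(x, ...) {
  tr <- x$cost_trace
  tibble(
    method = x$provenance$method,
    transform = x$provenance$transform,
    unit = x$provenance$unit,
    n_samples = nrow(x$coords),
    seed = x$provenance$seed,
    initial_cost = if (length(tr)) tr[[1]] else NA_real_,
    final_cost = if (length(tr)) tr[[length(tr)]] else NA_real_
  )
}

# Coordinates from anything embedding-like (vc_embedding, matrix, or a
# data frame with x/y columns).
embedding_coords <- function(emb) {
  if (inherits(emb, "vc_embedding")) return(emb$coords)
  if (is.matrix(emb) && ncol(emb) >= 2) return(emb[, 1:2, drop = FALSE])
  if (is.data.frame(emb) && all(c("x", "y") %in% names(emb))) {
    m <- as.matrix(emb[, c("x", "y")])
    if (!is.null(emb$sample_id)) rownames(m) <- emb$sample_id
    return(m)
  }
  abort("expected a `vc_embedding`, an n x 2 matrix, or a data frame with columns x, y")
}

embedding_ids <- function(emb) {
  if (inherits(emb, "vc_embedding")) return(emb$sample_ids)
  co <- embedding_coords(emb)
  rownames(co) %||% as.character(seq_len(nrow(co)))
}
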