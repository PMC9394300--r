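#' UTMC figure legend
#'
#' The UTMC legend makes every visual-clustering figure self-describing by
#' stating the expression Unit (FPKM, TPM, RPKM, read counts, ...), the
#' data Transformation, the dimension-reduction Method, and the Clustering
#' algorithm (or the sentinel `"NA"` when none was applied).
#'
#' @param unit,transformation,method Non-empty strings.
#' @param clustering Non-empty string, or `"NA"` when no clustering was
#'   applied.
#' @return An object of class `vc_utmc`.
#' @export
#' @examples
#' format_utmc(utmc_legend("FPKM", "log10 + 1", "UMAP"))
utmc_legend <- function(unit, transformation, method, clustering = "NA") {
  fields <- list(unit = unit, transformation = transformation,
                 method = method, clustering = clustering)
  for (nm in names(fields)) {
    x <- fields[[nm]]
    if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
      abort(sprintf("UTMC legend field `%s` must be a non-empty string", nm))
    }
  }
  structure(fields, class = "vc_utmc")
}

#' Format a UTMC legend as its canonical string
#'
#' @param legend A [utmc_legend()].
#' @return The string `"U: <unit> | T: <transformation> | M: <method> | C:
#'   <clustering>"`.
#' @export
format_utmc <- function(legend) {
  if (!inherits(legend, "vc_utmc")) abort("`legend` must be a `vc_utmc` object")
  sprintf("U: %s | T: %s | M: %s | C: %s",
          legend$unit, legend$transformation, legend$method,
          legend$clustering)
}

#' @export
print.vc_utmc <- function(x, ...) {
  cat(format_utmc(x), "\n")
  invisible(x)
}

#' Build a UTMC legend from embedding provenance
#'
#' @param emb A `vc_embedding`.
#' @param clusters Optional `vc_cluster` supplying the C field.
#' @return A `vc_utmc`.
#' @export
utmc_from_embedding <- function(emb, clusters = NULL) {
  p <- emb$provenance
  utmc_legend(
    unit = p$unit,
    transformation = transform_label(p$transform),
    method = p$method_label %||% p$method,
    clustering = if (is.null(clusters)) "NA" else cluster_label(clusters)
  )
}
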