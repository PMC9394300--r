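#' Scatter plot of an embedding with its UTMC legend
#'
#' @param object A `vc_embedding`.
#' @param colour_by Optional colouring: a `vc_cluster`, or a vector of
#'   labels aligned with the samples (a named vector is realigned by
#'   sample id).
#' @param legend Optional [utmc_legend()]; by default it is derived from
#'   the embedding's provenance (and `colour_by` when that is a cluster
#'   result).
#' @param point_size Point size.
#' @param ... Unused.
#' @return A ggplot object whose caption carries the UTMC string.
#' @method autoplot vc_embedding
#' @export
autoplot.vc_embedding <- function(object, colour_by = NULL, legend = NULL,
                                  point_size = 1.5, ...) {
  df <- tidy(object)
  colour_name <- "label"
  if (inherits(colour_by, "vc_cluster")) {
    legend <- legend %||% utmc_from_embedding(object, colour_by)
    lab <- tidy(colour_by)
    if (!setequal(lab$sample_id, df$sample_id)) {
      abort("cluster result and embedding cover different samples")
    }
    df$label <- factor(lab$label[match(df$sample_id, lab$sample_id)])
    colour_name <- "cluster"
  } else if (!is.null(colour_by)) {
    if (!is.null(names(colour_by))) {
      missing <- setdiff(df$sample_id, names(colour_by))
      if (length(missing) > 0) {
        abort(sprintf("`colour_by` misaligned: no label for %s",
                      paste(head(missing, 5), collapse = ", ")))
      }
      colour_by <- colour_by[df$sample_id]
    } else if (length(colour_by) != nrow(df)) {
      abort("`colour_by` must have one label per sample")
    }
    df$label <- factor(colour_by)
  }
  legend <- legend %||% utmc_from_embedding(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  p <- if (is.null(df$label)) {
    p + ggplot2::geom_point(size = point_size)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                            size = point_size) +
      ggplot2::labs(colour = colour_name)
  }
  p + ggplot2::labs(
    x = "dimension 1", y = "dimension 2",
    caption = format_utmc(legend)
  ) + ggplot2::theme_minimal()
}

#' Render an embedding figure to disk
#'
#' Writes a 2-D scatter of the embedding with a categorical palette and the
#' UTMC provenance string embedded in the figure. Output format follows the
#' file extension (`.png` or `.svg`).
#'
#' @inheritParams autoplot.vc_embedding
#' @param emb A `vc_embedding`.
#' @param out_path Output file path.
#' @param width,height,dpi Device geometry passed to [ggplot2::ggsave()].
#' @return `out_path`, invisibly.
#' @export
render_embedding_plot <- function(emb, colour_by = NULL, legend = NULL,
                                  out_path, width = 6, height = 5,
                                  dpi = 150) {
  p <- autoplot(emb, colour_by = colour_by, legend = legend)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}
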