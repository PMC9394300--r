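#' The three expression-value transformations
#'
#' @description
#' Applies one of the three transformations compared throughout the package
#' to a nonnegative FPKM-like matrix:
#'
#' * `unprocessed` — identity copy;
#' * `log10` — entrywise `log10(x)` where entries exactly 0 are set to 0.
#'   Entries in `(0, 1)` therefore yield *negative* values, which are
#'   retained by default: only exact zeros are remapped. This literal zero
#'   rule is the source of the divergence between `log10` and `log10p1`
#'   maps on zero-inflated data;
#' * `log10p1` — entrywise `log10(x + 1)`, always `>= 0` and 0 iff `x = 0`.
#'
#' The input is never mutated, and the transform kind travels with the
#' result (attribute `transform`) so downstream figures can carry complete
#' UTMC provenance.
#'
#' @param X Nonnegative numeric matrix (genes x samples), no missing values.
#' @param kind One of `"unprocessed"`, `"log10"`, `"log10p1"`.
#' @param sub_one Handling of entries in `(0, 1)` under `kind = "log10"`:
#'   `"retain"` (default) keeps their negative logarithms; `"zero"` maps
#'   every entry below 1 to 0 instead.
#'
#' @return A matrix of the same shape and dimnames, with attribute
#'   `transform` set to `kind`.
#' @export
#' @examples
#' X <- matrix(c(0, 0.1, 9, 100), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' apply_transform(X, "log10")    # 0 stays 0, 0.1 becomes -1
#' apply_transform(X, "log10p1")  # 9 becomes 1
apply_transform <- function(X, kind = c("unprocessed", "log10", "log10p1"),
                            sub_one = c("retain", "zero")) {
  kind <- match.arg(kind)
  sub_one <- match.arg(sub_one)
  validate_expression_matrix(X)
  out <- switch(kind,
    unprocessed = X + 0,  # force a copy
    log10 = {
      Y <- suppressWarnings(log10(X))
      Y[X == 0] <- 0
      if (sub_one == "zero") Y[X < 1] <- 0
      Y
    },
    log10p1 = log10(X + 1)
  )
  attr(out, "transform") <- kind
  out
}

#' Human-readable label for a transform kind
#' @param kind A transform kind string.
#' @return A display string such as `"log10 + 1"`.
#' @export
transform_label <- function(kind) {
  switch(kind,
    unprocessed = "unprocessed",
    log10 = "log10",
    log10p1 = "log10 + 1",
    kind %||% "unknown"
  )
}

validate_expression_matrix <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  }
  if (anyNA(X)) abort(sprintf("`%s` contains missing values", arg))
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    g <- if (!is.null(rownames(X))) rownames(X)[neg[1, 1]] else neg[1, 1]
    s <- if (!is.null(colnames(X))) colnames(X)[neg[1, 2]] else neg[1, 2]
    abort(sprintf("negative expression value at gene %s, sample %s (FPKM must be nonnegative)", g, s))
  }
  invisible(X)
}
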