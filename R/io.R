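#' Read an expression matrix from TSV
#'
#' Expects the dialect written by [write_expression_tsv()]: a header row of
#' sample ids, first column of gene ids, nonnegative numeric entries.
#' Duplicated ids, missing or negative values are rejected with messages
#' naming the offender.
#'
#' @param path Path to a TSV file.
#' @return A nonnegative numeric matrix with gene/sample dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols())
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicated gene id in %s: %s", path,
                  gene_ids[duplicated(gene_ids)][1]))
  }
  bad_col <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
  if (length(bad_col) > 0) {
    abort(sprintf("non-numeric expression column in %s: %s", path, bad_col[1]))
  }
  X <- as.matrix(df[, -1])
  rownames(X) <- gene_ids
  if (anyDuplicated(colnames(X))) {
    abort(sprintf("duplicated sample id in %s: %s", path,
                  colnames(X)[duplicated(colnames(X))][1]))
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at gene %s, sample %s (line %d of %s)",
                  gene_ids[bad[1]], colnames(X)[bad[2]], bad[1] + 1, path))
  }
  validate_expression_matrix(X)
  X
}

#' Write an expression matrix as TSV
#'
#' @param X Expression matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(X, path) {
  df <- tibble::as_tibble(X, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Requires columns `sample_id`, `site`, `sample_type`; `subgroup_truth`
#' and any further columns are carried along. When `sample_ids` is given,
#' the annotation must cover exactly those samples.
#'
#' @param path Path to a TSV file.
#' @param sample_ids Optional character vector to validate coverage
#'   against (e.g. the matrix column names).
#' @return A tibble.
#' @export
read_annotations <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ann <- readr::read_tsv(path, col_types = readr::cols())
  needed <- c("sample_id", "site", "sample_type")
  missing <- setdiff(needed, names(ann))
  if (length(missing) > 0) {
    abort(sprintf("annotation file %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample_id)) {
    abort(sprintf("duplicated sample_id in %s: %s", path,
                  ann$sample_id[duplicated(ann$sample_id)][1]))
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, ann$sample_id)
    if (length(absent) > 0) {
      abort(sprintf("annotation missing samples present in the matrix: %s",
                    paste(head(absent, 10), collapse = ", ")))
    }
  }
  ann
}

#' Write a sample-annotation table as TSV
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(ann, path)
  invisible(path)
}

#' Write an embedding as TSV plus a provenance JSON sidecar
#'
#' @param emb A `vc_embedding`.
#' @param path Output TSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  readr::write_tsv(tidy(emb), path)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  prov <- emb$provenance
  prov$utmc <- format_utmc(utmc_from_embedding(emb))
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path Path to the embedding TSV; the JSON sidecar is read from the
#'   same stem when present.
#' @return A `vc_embedding` (with minimal provenance if the sidecar is
#'   absent).
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double()))
  side <- sub("\\.tsv$", ".json", path)
  prov <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(unit = "unknown", transform = "unprocessed", method = "unknown",
         method_label = "unknown", params = list(), seed = NA_integer_)
  }
  new_embedding(as.matrix(df[, c("x", "y")]), df$sample_id, prov)
}
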