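#' Construct a reference atlas
#'
#' A reference atlas holds the in-situ expression of `D` genes over `B`
#' spatial bins, both on a continuous scale and as an ON/OFF binarization.
#' Row `i` of both matrices refers to the same physical bin as row `i` of
#' the accompanying geometry; this row correspondence is the index
#' convention every downstream matrix inherits.
#'
#' @param values numeric `B x D` matrix of in-situ expression, with gene
#'   names as column names.
#' @param binary `B x D` matrix with entries in `{0, 1}`, same genes and
#'   bin order as `values`.
#' @return An object of class `reference_atlas`: a list with elements
#'   `genes`, `values` and `binary`.
#' @export
reference_atlas <- function(values, binary) {
  values <- as.matrix(values)
  binary <- as.matrix(binary)
  genes <- colnames(values)
  if (is.null(genes)) abort("atlas `values` must have gene names as column names")
  if (anyDuplicated(genes)) abort("duplicate gene names in atlas")
  if (!identical(dim(values), dim(binary)))
    abort("atlas `values` and `binary` must have identical shape")
  if (!identical(genes, colnames(binary)))
    abort("atlas `values` and `binary` must have identical gene columns")
  if (!all(binary %in% c(0, 1)))
    abort("atlas `binary` entries must be 0 or 1")
  if (anyNA(values)) abort("atlas `values` contains missing entries")
  structure(list(genes = genes, values = values, binary = binary),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("<reference_atlas> %d bins x %d genes\n", nrow(x$values), length(x$genes)))
  invisible(x)
}

#' Number of bins in an atlas
#' @param atlas a [reference_atlas()].
#' @return integer bin count.
#' @export
n_bins <- function(atlas) nrow(atlas$values)

#' Construct a single-cell expression container
#'
#' Holds genes-by-cells matrices for one scRNA-seq experiment: raw counts
#' and, once computed (or supplied pre-computed, as the challenge data
#' were), normalized and binarized values.
#'
#' @param raw non-negative integer `G x C` count matrix, or `NULL` when
#'   only pre-normalized data are available.
#' @param normalized,binary optional `G x C` matrices on the same axes.
#' @param genes,barcodes character vectors naming the rows / columns; taken
#'   from the dimnames of the first non-NULL matrix when omitted.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(raw = NULL, normalized = NULL, binary = NULL,
                        genes = NULL, barcodes = NULL) {
  first <- raw %||% normalized %||% binary
  if (is.null(first)) abort("at least one of raw/normalized/binary is required")
  genes <- genes %||% rownames(first)
  barcodes <- barcodes %||% colnames(first)
  if (is.null(genes) || is.null(barcodes))
    abort("gene and barcode names are required (dimnames or explicit arguments)")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes")
  if (anyDuplicated(genes)) abort("duplicate gene names")
  fix <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      abort(sprintf("`%s` matrix shape does not match genes x barcodes", what))
    dimnames(m) <- list(genes, barcodes)
    m
  }
  raw <- fix(raw, "raw")
  if (!is.null(raw) && any(raw < 0)) abort("negative raw counts")
  x <- structure(list(genes = genes, barcodes = barcodes,
                      raw = raw, normalized = fix(normalized, "normalized"),
                      binary = fix(binary, "binary")),
                 class = "cell_matrix")
  if (!is.null(x$binary) && !all(x$binary %in% c(0, 1)))
    abort("`binary` entries must be 0 or 1")
  x
}

#' @export
print.cell_matrix <- function(x, ...) {
  slots <- c("raw", "normalized", "binary")
  have <- slots[!vapply(x[slots], is.null, logical(1))]
  cat(sprintf("<cell_matrix> %d genes x %d cells [%s]\n",
              length(x$genes), length(x$barcodes), paste(have, collapse = ", ")))
  invisible(x)
}

#' Cell-by-bin score matrix
#'
#' Wraps a `C x B` matrix of per-cell, per-bin similarity scores and tags
#' it with the score kind: `"mcc"` (binarized Matthews correlation),
#' `"overlap"` (projected cosine against reconstructed patterns) or
#' `"composite"` (their convex combination).
#'
#' @param values numeric `C x B` matrix, cell barcodes as row names.
#' @param kind one of `"mcc"`, `"overlap"`, `"composite"`.
#' @return the matrix with class `score_matrix` and a `kind` attribute.
#' @export
score_matrix <- function(values, kind = c("mcc", "overlap", "composite")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  structure(values, kind = kind, class = c("score_matrix", class(values)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix kind=%s> %d cells x %d bins\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname score_matrix
#' @param x a `score_matrix`.
#' @export
score_kind <- function(x) attr(x, "kind")

#' Reconstructed spatial patterns of the outgroup genes
#'
#' @param values numeric `B x M` matrix: reconstructed expression of `M`
#'   outgroup genes over `B` bins, gene names as column names.
#' @param no_prediction logical length-`B` vector flagging bins whose
#'   averaging weights all vanished (their rows are zero).
#' @return object of class `predicted_patterns`.
#' @export
predicted_patterns <- function(values, no_prediction = rep(FALSE, nrow(values))) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) abort("pattern matrix needs gene column names")
  if (length(no_prediction) != nrow(values))
    abort("`no_prediction` length must equal the number of bins")
  if (anyNA(values) || any(!is.finite(values))) abort("pattern values must be finite")
  structure(list(genes = colnames(values), values = values,
                 no_prediction = as.logical(no_prediction)),
            class = "predicted_patterns")
}

#' @export
print.predicted_patterns <- function(x, ...) {
  cat(sprintf("<predicted_patterns> %d bins x %d genes (%d bins without prediction)\n",
              nrow(x$values), length(x$genes), sum(x$no_prediction)))
  invisible(x)
}

# shared validation: predictions tibble produced by rank_bins()/read_predictions()
check_predictions <- function(preds) {
  need <- c("barcode", "rank", "bin_id", "score")
  if (!is.data.frame(preds) || !all(need %in% names(preds)))
    abort("predictions must be a data frame with columns barcode, rank, bin_id, score")
  invisible(preds)
}
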