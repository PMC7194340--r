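#' Matthews correlation coefficient of two binary vectors
#'
#' With confusion counts over positions (TP: both 1; TN: both 0; FP: 0 in
#' `u`, 1 in `v`; FN: 1 in `u`, 0 in `v`):
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the denominator is zero (either vector constant)
#' the score is 0 by convention.
#'
#' @param u,v binary vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(u, v) {
  if (length(u) != length(v)) abort("mcc: length mismatch")
  if (!length(u)) abort("mcc: empty vectors")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    abort("mcc: non-binary entry")
  tp <- sum(u == 1 & v == 1); tn <- sum(u == 0 & v == 0)
  fp <- sum(u == 0 & v == 1); fn <- sum(u == 1 & v == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' MCC of every cell against every atlas bin
#'
#' Vectorized over the full cells-by-bins grid via binary cross-products;
#' entry `(j, i)` equals `mcc(cell j, bin i)` exactly.
#'
#' @param cells_binary `C x N` binary matrix (cells in rows) over the
#'   selected genes, gene names as column names.
#' @param atlas_binary `B x N` binary matrix (bins in rows) over the same
#'   genes in the same order.
#' @return a [score_matrix()] of kind `"mcc"` (`C x B`).
#' @export
mcc_matrix <- function(cells_binary, atlas_binary) {
  cells_binary <- as.matrix(cells_binary)
  atlas_binary <- as.matrix(atlas_binary)
  if (ncol(cells_binary) != ncol(atlas_binary))
    abort("gene axes differ between cells and atlas")
  gc <- colnames(cells_binary); ga <- colnames(atlas_binary)
  if (!is.null(gc) && !is.null(ga) && !identical(gc, ga))
    abort("gene order differs between cells and atlas")
  if (!all(cells_binary %in% c(0, 1)) || !all(atlas_binary %in% c(0, 1)))
    abort("non-binary entry")
  n <- ncol(cells_binary)
  tp <- cells_binary %*% t(atlas_binary)                    # C x B
  ones_c <- rowSums(cells_binary)                           # 1s per cell
  ones_b <- rowSums(atlas_binary)                           # 1s per bin
  fn <- ones_c - tp
  fp <- matrix(ones_b, nrow(tp), ncol(tp), byrow = TRUE) - tp
  tn <- n - tp - fp - fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- ifelse(den == 0, 0, (tp * tn - fp * fn) / sqrt(pmax(den, 0)))
  rownames(out) <- rownames(cells_binary)
  score_matrix(out, "mcc")
}

#' Projected-cosine overlap between a cell and a predicted pattern
#'
#' The predicted pattern vector `v` is projected onto the subspace
#' spanned by the non-null components of the cell vector `u` (components
#' flagged in `null_mask` are zeroed in both vectors); the score is the
#' cosine of the angle on that subspace,
#' `u . v_p / (||u|| ||v_p||)`, or 0 when either norm vanishes. Masking
#' keeps dropout zeros — genes the cell expresses but the assay missed —
#' from dragging the similarity down.
#'
#' @param u cell expression over the outgroup genes (normalized scale).
#' @param v predicted pattern at one bin over the same genes.
#' @param null_mask logical/0-1 vector, `TRUE`/1 where `u`'s component is
#'   null (zero raw count).
#' @return scalar cosine in `[-1, 1]`.
#' @export
overlap <- function(u, v, null_mask = rep(FALSE, length(u))) {
  if (length(u) != length(v) || length(u) != length(null_mask))
    abort("overlap: length mismatch")
  keep <- !as.logical(null_mask)
  up <- u * keep
  vp <- v * keep
  nu <- sqrt(sum(up^2)); nv <- sqrt(sum(vp^2))
  if (nu == 0 || nv == 0) return(0)
  sum(up * vp) / (nu * nv)
}

#' Overlap of every cell against every bin of the predicted patterns
#'
#' Entry `(j, i)` is [overlap()] between cell `j`'s normalized outgroup
#' expression and row `i` of the reconstructed patterns, with cell `j`'s
#' null mask taken from its zero raw counts (the only unambiguous "not
#' expressed" signal, since normalized log values are negative).
#'
#' @param cells a [cell_matrix()] with normalized values and raw counts
#'   covering the pattern genes; set `null_mask` explicitly if raw counts
#'   are unavailable.
#' @param patterns a [predicted_patterns()] over the outgroup genes.
#' @param null_mask optional genes-by-cells logical matrix overriding the
#'   raw-count rule (TRUE = null component).
#' @return a [score_matrix()] of kind `"overlap"` (`C x B`).
#' @export
overlap_matrix <- function(cells, patterns, null_mask = NULL) {
  genes <- patterns$genes
  missing <- setdiff(genes, cells$genes)
  if (length(missing))
    abort(sprintf("outgroup genes absent from cell matrix: %s",
                  paste(missing, collapse = ", ")))
  if (is.null(cells$normalized)) abort("normalized values are required")
  U <- cells$normalized[genes, , drop = FALSE]            # M x C
  if (is.null(null_mask)) {
    if (is.null(cells$raw))
      abort("raw counts are required to derive the null mask (or pass `null_mask`)")
    null_mask <- cells$raw[genes, , drop = FALSE] == 0
  } else {
    null_mask <- as.matrix(null_mask)[genes, , drop = FALSE]
  }
  P <- patterns$values                                    # B x M
  P2 <- P^2
  C <- ncol(U); B <- nrow(P)
  out <- matrix(0, C, B, dimnames = list(colnames(U), NULL))
  for (j in seq_len(C)) {
    keep <- !null_mask[, j]
    uj <- U[, j] * keep
    nu <- sqrt(sum(uj^2))
    if (nu == 0) next
    nv <- sqrt(drop(P2 %*% keep))                         # ||v_p|| per bin
    num <- drop(P %*% uj)
    ok <- nv > 0
    out[j, ok] <- num[ok] / (nu * nv[ok])
  }
  score_matrix(out, "overlap")
}

#' Composite score S = w1 * MCC + w2 * overlap
#'
#' @param c_scores MCC [score_matrix()].
#' @param o_scores overlap [score_matrix()] of identical shape.
#' @param w1,w2 non-negative weights summing to 1; the reference analysis
#'   uses (0.7, 0.3) with 20 reference genes and (0.9, 0.1) with 60.
#' @return a [score_matrix()] of kind `"composite"`.
#' @export
composite_score <- function(c_scores, o_scores, w1, w2) {
  if (!identical(dim(c_scores), dim(o_scores)))
    abort("score matrices differ in shape")
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-8)
    abort("weights must be non-negative and sum to 1")
  out <- w1 * unclass(c_scores) + w2 * unclass(o_scores)
  attr(out, "kind") <- NULL
  score_matrix(out, "composite")
}

#' Default composite-score weights by reference-set size
#'
#' (0.7, 0.3) for 20 reference genes; (0.9, 0.1) for 60. The 40-gene
#' setting has no reported weights and defaults to (0.9, 0.1).
#'
#' @param n_reference reference gene count.
#' @return named numeric vector `c(w1 = , w2 = )`.
#' @export
default_weights <- function(n_reference) {
  if (n_reference <= 20) c(w1 = 0.7, w2 = 0.3) else c(w1 = 0.9, w2 = 0.1)
}
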