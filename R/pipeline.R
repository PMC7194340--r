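#' Rank the top-k bins per cell
#'
#' For each cell, the `k` highest-scoring bins in descending score order;
#' ties are broken toward the smaller bin id for determinism.
#'
#' @param scores a cells-by-bins [score_matrix()] (or bare matrix with
#'   barcode row names).
#' @param k bins to keep per cell (default 10, the putative-position
#'   count of the reference analysis); must not exceed the bin count.
#' @return tidy tibble: `barcode`, `rank` (1 = best), `bin_id` (0-based),
#'   `score`.
#' @export
rank_bins <- function(scores, k = 10) {
  m <- unclass(scores)
  if (k > ncol(m)) abort(sprintf("k (%d) exceeds the bin count (%d)", k, ncol(m)))
  if (k < 1) abort("k must be >= 1")
  barcodes <- rownames(m) %||% paste0("cell", seq_len(nrow(m)))
  top <- topk_bins(m, k)
  tibble::tibble(barcode = rep(barcodes, each = k),
                 rank = rep(seq_len(k), nrow(m)),
                 bin_id = as.integer(t(top$idx)) - 1L,
                 score = as.numeric(t(top$score)))
}

# per-row top-k by descending score, ties to the smaller (1-based) column
topk_bins <- function(m, k) {
  bins <- seq_len(ncol(m))
  idx <- matrix(0L, nrow(m), k)
  for (j in seq_len(nrow(m))) idx[j, ] <- order(-m[j, ], bins)[seq_len(k)]
  score <- matrix(m[cbind(rep(seq_len(nrow(m)), k), as.integer(idx))], nrow(m), k)
  list(idx = idx, score = score)
}

#' Reconstruct outgroup spatial patterns as score-weighted cell averages
#'
#' For each bin `i`, the `top_k_cells` cells with the highest score
#' against that bin contribute; the reconstructed expression of gene `g`
#' is `e_ig = sum_j c_ij * e_jg` over those cells, divided by
#' `sum_j c_ij` when `normalize_weighted_average` is on (the literal
#' unnormalized sum is available with the switch off; the overlap score
#' is scale-invariant, so downstream results agree either way). Negative
#' scores are clipped to zero before use as weights when
#' `clip_negative_scores` is on; a bin whose clipped weights all vanish
#' gets an all-zero row flagged in `no_prediction`.
#'
#' @param scores cells-by-bins [score_matrix()].
#' @param cells a [cell_matrix()] with normalized values covering
#'   `outgroup_genes`.
#' @param outgroup_genes character vector of genes to reconstruct.
#' @param top_k_cells contributing cells per bin (default 10).
#' @param normalize_weighted_average divide by the weight sum (default
#'   TRUE).
#' @param clip_negative_scores clip weights at 0 (default TRUE).
#' @return a [predicted_patterns()] (`B x M`).
#' @export
predict_patterns <- function(scores, cells, outgroup_genes,
                             top_k_cells = 10,
                             normalize_weighted_average = TRUE,
                             clip_negative_scores = TRUE) {
  W <- unclass(scores)
  if (top_k_cells > nrow(W))
    abort(sprintf("top_k_cells (%d) exceeds the cell count (%d)", top_k_cells, nrow(W)))
  if (is.null(cells$normalized)) abort("normalized values are required")
  missing <- setdiff(outgroup_genes, cells$genes)
  if (length(missing))
    abort(sprintf("outgroup genes absent from cell matrix: %s",
                  paste(missing, collapse = ", ")))
  E <- t(cells$normalized[outgroup_genes, , drop = FALSE])  # C x M
  if (clip_negative_scores) W <- pmax(W, 0)
  B <- ncol(W)
  out <- matrix(0, B, length(outgroup_genes),
                dimnames = list(NULL, outgroup_genes))
  empty <- logical(B)
  cell_idx <- seq_len(nrow(W))
  for (i in seq_len(B)) {
    top <- order(-W[, i], cell_idx)[seq_len(top_k_cells)]
    w <- W[top, i]
    sw <- sum(w)
    if (sw == 0) { empty[i] <- TRUE; next }
    if (normalize_weighted_average) w <- w / sw
    out[i, ] <- drop(w %*% E[top, , drop = FALSE])
  }
  predicted_patterns(out, no_prediction = empty)
}

#' Map cells onto atlas bins by iterative composite scoring
#'
#' The full positioning procedure. Iteration 1 scores every binarized
#' cell against every binarized atlas bin with the MCC over the reference
#' genes — pure atlas matching. Each later iteration (i) reconstructs the
#' outgroup genes' spatial patterns from the previous iteration's scores
#' via [predict_patterns()], (ii) recomputes the projected-cosine overlap
#' of each cell against those patterns, and (iii) forms the composite
#' score `S = w1 * c + w2 * o`, with `c` held fixed at its iteration-1
#' MCC value. Two to three iterations suffice; with `w2 = 0` every
#' iteration equals the first. Fully deterministic.
#'
#' @param cells a [cell_matrix()] with normalized, binary and raw slots.
#' @param atlas a [reference_atlas()].
#' @param selection a [select_genes()] result, or any list with character
#'   elements `reference_genes` and `outgroup_genes`.
#' @param w1,w2 composite weights (defaults from [default_weights()] for
#'   the reference-set size).
#' @param n_iterations total scoring iterations (>= 1, default 3).
#' @param top_k_bins ranked bins kept per cell (default 10).
#' @param top_k_cells cells per bin in pattern reconstruction (default 10).
#' @param normalize_weighted_average,clip_negative_scores passed to
#'   [predict_patterns()].
#' @return object of class `cell_mapping`: list with `scores` (final
#'   [score_matrix()]), `mcc` (the fixed iteration-1 MCC), `patterns`
#'   (final [predicted_patterns()]), `predictions` (tidy tibble from
#'   [rank_bins()] on the final scores), `trace` (list of per-iteration
#'   score matrices) and `config`.
#' @export
map_cells <- function(cells, atlas, selection,
                      w1 = NULL, w2 = NULL,
                      n_iterations = 3, top_k_bins = 10, top_k_cells = 10,
                      normalize_weighted_average = TRUE,
                      clip_negative_scores = TRUE) {
  ref <- selection$reference_genes
  out <- selection$outgroup_genes
  if (is.null(ref) || is.null(out))
    abort("`selection` must provide reference_genes and outgroup_genes")
  miss_ref <- union(setdiff(ref, atlas$genes), setdiff(ref, cells$genes))
  if (length(miss_ref))
    abort(sprintf("reference genes missing from atlas or cells: %s",
                  paste(miss_ref, collapse = ", ")))
  miss_out <- setdiff(out, cells$genes)
  if (length(miss_out))
    abort(sprintf("outgroup genes missing from cells: %s",
                  paste(miss_out, collapse = ", ")))
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (is.null(cells$binary)) abort("binarized cell values are required")
  if (is.null(w1)) { w <- default_weights(length(ref)); w1 <- w[["w1"]]; w2 <- w[["w2"]] }

  cb <- t(cells$binary[ref, , drop = FALSE])          # C x N
  ab <- atlas$binary[, ref, drop = FALSE]             # B x N
  c_mat <- mcc_matrix(cb, ab)

  trace <- vector("list", n_iterations)
  trace[[1]] <- c_mat
  s_mat <- c_mat
  patterns <- NULL
  if (n_iterations >= 2) {
    for (it in 2:n_iterations) {
      patterns <- predict_patterns(s_mat, cells, out, top_k_cells,
                                   normalize_weighted_average,
                                   clip_negative_scores)
      o_mat <- overlap_matrix(cells, patterns)
      s_mat <- composite_score(c_mat, o_mat, w1, w2)
      trace[[it]] <- s_mat
    }
  } else {
    patterns <- predict_patterns(s_mat, cells, out, top_k_cells,
                                 normalize_weighted_average,
                                 clip_negative_scores)
  }
  structure(list(scores = s_mat, mcc = c_mat, patterns = patterns,
                 predictions = rank_bins(s_mat, top_k_bins),
                 trace = trace,
                 config = list(reference_genes = ref, outgroup_genes = out,
                               w1 = w1, w2 = w2, n_iterations = n_iterations,
                               top_k_bins = top_k_bins, top_k_cells = top_k_cells,
                               normalize_weighted_average = normalize_weighted_average,
                               clip_negative_scores = clip_negative_scores)),
            class = "cell_mapping")
}

#' @export
print.cell_mapping <- function(x, ...) {
  cat(sprintf("<cell_mapping> %d cells x %d bins, %d iteration(s), w1=%.2f w2=%.2f\n",
              nrow(x$scores), ncol(x$scores), x$config$n_iterations,
              x$config$w1, x$config$w2))
  invisible(x)
}

#' Surrogate truth: best full-atlas MCC bin per cell
#'
#' When true positions are unknown, the bin with the highest MCC computed
#' over *all* atlas genes serves as each cell's surrogate true position.
#' Ties go to the smallest bin id.
#'
#' @param cells a [cell_matrix()] binarized over all atlas genes.
#' @param atlas a [reference_atlas()].
#' @return tibble `barcode`, `bin_id`.
#' @export
truth_by_full_atlas <- function(cells, atlas) {
  missing <- setdiff(atlas$genes, cells$genes)
  if (length(missing))
    abort(sprintf("atlas genes missing from cell matrix: %s",
                  paste(missing, collapse = ", ")))
  if (is.null(cells$binary)) abort("binarized cell values are required")
  cb <- t(cells$binary[atlas$genes, , drop = FALSE])
  m <- unclass(mcc_matrix(cb, atlas$binary))
  best <- apply(m, 1, which.max) - 1L   # which.max takes the first (smallest id) on ties
  tibble::tibble(barcode = cells$barcodes, bin_id = as.integer(best))
}

#' Evaluate predictions against true (or surrogate-true) positions
#'
#' A cell is well predicted when its true bin appears among its ranked
#' bins; the performance is the percentage of well-predicted cells.
#'
#' @param preds tidy predictions tibble ([rank_bins()]).
#' @param truth tibble `barcode`, `bin_id` (or named vector barcode ->
#'   bin id).
#' @return object of class `position_eval`: list with `per_cell` tibble
#'   (`barcode`, `truth_bin`, `hit`) and `performance` in `[0, 100]`.
#' @export
evaluate_predictions <- function(preds, truth) {
  check_predictions(preds)
  if (!is.data.frame(truth))
    truth <- tibble::tibble(barcode = names(truth), bin_id = as.integer(truth))
  barcodes <- unique(preds$barcode)
  missing <- setdiff(barcodes, truth$barcode)
  if (length(missing))
    abort(sprintf("no truth entry for barcodes: %s",
                  paste(head(missing, 5), collapse = ", ")))
  tmap <- stats::setNames(truth$bin_id, truth$barcode)
  row_hit <- preds$bin_id == tmap[preds$barcode]
  hits <- vapply(split(row_hit, factor(preds$barcode, levels = barcodes)),
                 any, logical(1))
  per_cell <- tibble::tibble(barcode = barcodes,
                             truth_bin = as.integer(tmap[barcodes]),
                             hit = as.integer(hits))
  structure(list(per_cell = per_cell, performance = 100 * mean(hits)),
            class = "position_eval")
}

#' @export
print.position_eval <- function(x, ...) {
  cat(sprintf("<position_eval> %.2f%% of %d cells well predicted\n",
              x$performance, nrow(x$per_cell)))
  invisible(x)
}

#' Per-iteration performance trace of a mapping
#'
#' Re-ranks each iteration's score matrix and evaluates it, reproducing
#' the performance-vs-iteration curve.
#'
#' @param mapping a [map_cells()] result.
#' @param truth as in [evaluate_predictions()].
#' @param k top bins per cell (defaults to the mapping's `top_k_bins`).
#' @return tibble `iteration`, `performance`.
#' @export
performance_trace <- function(mapping, truth, k = NULL) {
  k <- k %||% mapping$config$top_k_bins
  perf <- vapply(mapping$trace, function(s) {
    evaluate_predictions(rank_bins(s, k), truth)$performance
  }, numeric(1))
  tibble::tibble(iteration = seq_along(perf), performance = perf)
}

#' Performance distribution of random reference-gene sets
#'
#' Draws `n_sets` uniform random gene subsets of size `set_size` from the
#' atlas genes (without replacement, seeded) and evaluates single-pass
#' MCC positioning with each — the null distribution against which an
#' entropy-selected set is judged.
#'
#' @param cells binarized [cell_matrix()] covering the atlas genes.
#' @param atlas a [reference_atlas()].
#' @param truth as in [evaluate_predictions()].
#' @param set_size genes per random set (the reference analysis uses 20).
#' @param n_sets number of random sets (default 200).
#' @param seed RNG seed.
#' @param top_k_bins ranked bins per cell (default 10).
#' @return tibble `set`, `performance`, plus the gene draws as attribute
#'   `"sets"`.
#' @export
random_baseline <- function(cells, atlas, truth, set_size, n_sets = 200,
                            seed = 1L, top_k_bins = 10) {
  if (set_size > length(atlas$genes))
    abort(sprintf("set_size (%d) exceeds the atlas gene count (%d)",
                  set_size, length(atlas$genes)))
  if (is.null(cells$binary)) abort("binarized cell values are required")
  sets <- withr::with_seed(seed, replicate(n_sets, sample(atlas$genes, set_size),
                                           simplify = FALSE))
  if (!is.data.frame(truth))
    truth <- tibble::tibble(barcode = names(truth), bin_id = as.integer(truth))
  truth_bins <- truth$bin_id[match(cells$barcodes, truth$barcode)]
  if (anyNA(truth_bins)) abort("truth is missing barcodes present in `cells`")
  perf <- vapply(sets, function(genes) {
    cb <- t(cells$binary[genes, , drop = FALSE])
    ab <- atlas$binary[, genes, drop = FALSE]
    top <- topk_bins(unclass(mcc_matrix(cb, ab)), top_k_bins)
    100 * mean(vapply(seq_along(truth_bins),
                      function(j) (truth_bins[j] + 1L) %in% top$idx[j, ],
                      logical(1)))
  }, numeric(1))
  structure(tibble::tibble(set = seq_len(n_sets), performance = perf),
            sets = sets)
}
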