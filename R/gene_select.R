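#' Cluster genes by expression profile with UPGMA
#'
#' Agglomerative average-linkage (UPGMA) clustering of gene expression
#' profiles across cells, cut into exactly `n_clusters` flat groups.
#' Distances are Euclidean on the normalized values by default; the
#' Jaccard option (`stats::dist(method = "binary")`) is meant for
#' binarized matrices.
#'
#' @param expr genes-by-cells numeric matrix with gene row names.
#' @param n_clusters number of flat clusters (<= number of genes).
#' @param distance `"euclidean"` or `"jaccard"`.
#' @return named integer vector: cluster id per gene.
#' @export
cluster_genes <- function(expr, n_clusters, distance = c("euclidean", "jaccard")) {
  distance <- match.arg(distance)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) abort("`expr` must have gene row names")
  if (anyNA(expr)) abort("`expr` contains undefined values")
  if (n_clusters > nrow(expr))
    abort(sprintf("n_clusters (%d) exceeds the number of genes (%d)",
                  n_clusters, nrow(expr)))
  d <- stats::dist(expr, method = if (distance == "euclidean") "euclidean" else "binary")
  stats::cutree(stats::hclust(d, method = "average"), k = n_clusters)
}

#' Histogram entropy of an expression distribution
#'
#' Values are binned into fixed-width bins anchored at the minimum value;
#' with occupancy frequencies `p_i` over occupied bins the entropy is
#' `H = -sum_i p_i ln p_i` (nats). Anchoring at the minimum makes the
#' entropy invariant to adding a constant to all values, which matters
#' because normalized expression is a log fraction with an arbitrary
#' cell-depth offset.
#'
#' @param values numeric vector (at least one finite value).
#' @param bin_width positive bin width; the reference analysis uses 0.125.
#' @return entropy in nats, `>= 0`.
#' @export
bin_entropy <- function(values, bin_width = 0.125) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  values <- values[is.finite(values)]
  if (!length(values)) abort("no finite values")
  idx <- floor((values - min(values)) / bin_width)
  p <- tabulate(idx + 1L)
  p <- p[p > 0] / length(values)
  -sum(p * log(p))
}

select_by_entropy <- function(expr, n_clusters, distance, bin_width) {
  clus <- cluster_genes(expr, n_clusters, distance)
  ent <- apply(expr, 1, bin_entropy, bin_width = bin_width)
  tb <- tibble::tibble(gene = rownames(expr), cluster = unname(clus),
                       entropy = unname(ent))
  # per-cluster entropy argmax; ties broken lexicographically by gene name
  tb <- dplyr::arrange(tb, .data$cluster, dplyr::desc(.data$entropy), .data$gene)
  dplyr::mutate(dplyr::group_by(tb, .data$cluster),
                selected = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster, .data$gene)
}

#' Select reference genes: one maximum-entropy gene per UPGMA cluster
#'
#' The candidate genes (those present in the atlas) are clustered into
#' `n_genes` groups by [cluster_genes()]; within each cluster the gene
#' with the greatest histogram entropy — the broadest expression
#' distribution across the cell population — is kept. Zero-heavy genes
#' are implicitly discarded (a distribution concentrated at zero has low
#' entropy); `max_zero_fraction` adds an optional explicit filter.
#'
#' @param cells a [cell_matrix()] with normalized values.
#' @param atlas_genes character vector of candidate (atlas) gene names.
#' @param n_genes number of reference genes to select (20/40/60 in the
#'   challenge subchallenges).
#' @param distance,bin_width passed to [cluster_genes()] / [bin_entropy()].
#' @param max_zero_fraction optional cap on the fraction of zero raw
#'   counts a candidate may have (default `NULL`: no explicit filter).
#' @return tibble with one row per candidate: `gene`, `cluster`,
#'   `entropy`, `selected`.
#' @export
select_reference <- function(cells, atlas_genes, n_genes,
                             distance = "euclidean", bin_width = 0.125,
                             max_zero_fraction = NULL) {
  if (is.null(cells$normalized)) abort("normalized values are required")
  cand <- intersect(atlas_genes, cells$genes)
  if (!length(cand)) abort("no atlas genes present in the cell matrix")
  if (!is.null(max_zero_fraction)) {
    if (is.null(cells$raw)) abort("raw counts needed for the zero-fraction filter")
    zf <- rowMeans(cells$raw[cand, , drop = FALSE] == 0)
    cand <- cand[zf <= max_zero_fraction]
  }
  select_by_entropy(cells$normalized[cand, , drop = FALSE], n_genes,
                    distance, bin_width)
}

#' Select the outgroup gene set from the non-atlas genes
#'
#' Applies the same cluster-then-maximum-entropy procedure to the genes
#' *not* in the atlas, with `m` clusters, yielding `m` outgroup genes
#' whose spatial patterns the pipeline reconstructs and scores against.
#'
#' @param cells a [cell_matrix()] with normalized values.
#' @param exclude gene names to exclude (the atlas genes).
#' @param m outgroup size (default 100).
#' @inheritParams select_reference
#' @return tibble as in [select_reference()].
#' @export
select_outgroup <- function(cells, exclude, m = 100,
                            distance = "euclidean", bin_width = 0.125) {
  if (is.null(cells$normalized)) abort("normalized values are required")
  cand <- setdiff(cells$genes, exclude)
  if (length(cand) < m)
    abort(sprintf("only %d candidate genes after exclusion; %d requested",
                  length(cand), m))
  select_by_entropy(cells$normalized[cand, , drop = FALSE], m,
                    distance, bin_width)
}

#' Select reference and outgroup genes in one call
#'
#' @inheritParams select_reference
#' @param atlas a [reference_atlas()]; its genes are the reference
#'   candidates and are excluded from outgroup candidacy.
#' @param n_reference reference set size.
#' @param n_outgroup outgroup set size (default 100).
#' @return object of class `gene_selection`: list with tibbles
#'   `reference` and `outgroup` (per-candidate cluster/entropy/selected)
#'   and character vectors `reference_genes`, `outgroup_genes`.
#' @export
select_genes <- function(cells, atlas, n_reference, n_outgroup = 100,
                         distance = "euclidean", bin_width = 0.125) {
  ref <- select_reference(cells, atlas$genes, n_reference,
                          distance = distance, bin_width = bin_width)
  out <- select_outgroup(cells, atlas$genes, n_outgroup,
                         distance = distance, bin_width = bin_width)
  structure(list(reference = ref, outgroup = out,
                 reference_genes = ref$gene[ref$selected],
                 outgroup_genes = out$gene[out$selected]),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d reference genes, %d outgroup genes\n",
              length(x$reference_genes), length(x$outgroup_genes)))
  invisible(x)
}

#' Write selected gene lists as plain text, one gene per line
#' @param selection a `gene_selection`.
#' @param reference_path,outgroup_path output paths (`NULL` to skip one).
#' @return invisibly, the selection.
#' @export
write_gene_lists <- function(selection, reference_path = NULL, outgroup_path = NULL) {
  if (!is.null(reference_path))
    readr::write_lines(selection$reference_genes, reference_path)
  if (!is.null(outgroup_path))
    readr::write_lines(selection$outgroup_genes, outgroup_path)
  invisible(selection)
}
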