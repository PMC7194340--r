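#' Read a reference atlas from its continuous and binarized CSV files
#'
#' Both files follow the challenge layout: a header row of gene names,
#' then one row per spatial bin, rows sorted identically to the geometry
#' file. The two files must agree on genes and bin count.
#'
#' @param values_path CSV of continuous in-situ expression.
#' @param binary_path CSV of the ON/OFF binarization of the same genes.
#' @return a [reference_atlas()].
#' @export
read_atlas <- function(values_path, binary_path) {
  vals <- read_numeric_csv(values_path)
  bin <- read_numeric_csv(binary_path)
  if (!identical(colnames(vals), colnames(bin)))
    abort("gene headers differ between continuous and binarized atlas files")
  if (nrow(vals) != nrow(bin))
    abort("row (bin) counts differ between continuous and binarized atlas files")
  if (!all(bin %in% c(0, 1)))
    abort("binarized atlas file contains entries other than 0/1")
  reference_atlas(vals, bin)
}

#' Write a reference atlas back to the paired CSV layout
#' @param atlas a [reference_atlas()].
#' @param values_path,binary_path output CSV paths.
#' @return invisibly, the atlas.
#' @export
write_atlas <- function(atlas, values_path, binary_path) {
  readr::write_csv(tibble::as_tibble(atlas$values), values_path)
  readr::write_csv(tibble::as_tibble(atlas$binary), binary_path)
  invisible(atlas)
}

read_numeric_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb)
  if (!is.numeric(m)) abort(sprintf("non-numeric values in %s", path))
  m
}

#' Read bin geometry (x, y, z per bin)
#'
#' Accepts comma-, tab- or whitespace-delimited tables with exactly three
#' coordinate columns. A header row is detected automatically: the first
#' line is treated as a header iff any of its tokens is non-numeric.
#' Bin ids are assigned 0-based in row order, the same order as the atlas
#' rows.
#'
#' @param path geometry file.
#' @return tibble with columns `bin_id`, `x`, `y`, `z`.
#' @export
read_geometry <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty geometry file")
  split1 <- split_dsv(lines[1])
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) abort("geometry file has a header but no rows")
  toks <- lapply(lines, split_dsv)
  ncols <- unique(lengths(toks))
  if (!identical(ncols, 3L))
    abort("geometry file must have exactly 3 coordinate columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 3, byrow = TRUE)
  if (anyNA(m) || any(!is.finite(m))) abort("non-numeric coordinate in geometry file")
  tibble::tibble(bin_id = seq_len(nrow(m)) - 1L,
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

# delimiter auto-detection: comma, then tab, then any whitespace
split_dsv <- function(line) {
  line <- trimws(line)
  if (grepl(",", line, fixed = TRUE)) return(trimws(strsplit(line, ",", fixed = TRUE)[[1]]))
  if (grepl("\t", line, fixed = TRUE)) return(trimws(strsplit(line, "\t", fixed = TRUE)[[1]]))
  strsplit(line, "[[:space:]]+")[[1]]
}

#' Write bin geometry
#' @param geometry tibble as returned by [read_geometry()].
#' @param path output path (whitespace-delimited x y z with header).
#' @return invisibly, the geometry.
#' @export
write_geometry <- function(geometry, path) {
  readr::write_delim(geometry[, c("x", "y", "z")], path, delim = " ")
  invisible(geometry)
}

#' Read a genes-by-cells expression table
#'
#' @param path CSV/TSV with gene names and cell barcodes on the margins
#'   (first column = row names).
#' @param orientation `"genes_by_cells"` (rows are genes, the challenge
#'   layout) or `"cells_by_genes"`; the result is stored genes-by-cells
#'   either way.
#' @param values which slot the file fills: raw counts (validated
#'   non-negative), normalized values, or binary ON/OFF calls.
#' @return a [cell_matrix()].
#' @export
read_cells <- function(path, orientation = c("genes_by_cells", "cells_by_genes"),
                       values = c("raw", "normalized", "binary")) {
  orientation <- match.arg(orientation)
  values <- match.arg(values)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  rn <- as.character(tb[[1]])
  m <- as.matrix(tb[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric expression values in %s", path))
  rownames(m) <- rn
  if (orientation == "cells_by_genes") m <- t(m)
  if (values == "raw" && any(m < 0)) abort("negative count in raw expression file")
  args <- stats::setNames(list(m), values)
  do.call(cell_matrix, args)
}

#' Write one slot of a cell matrix as a genes-by-cells CSV
#' @param cells a [cell_matrix()].
#' @param path output CSV.
#' @param values which slot to write.
#' @return invisibly, `cells`.
#' @export
write_cells <- function(cells, path, values = c("raw", "normalized", "binary")) {
  values <- match.arg(values)
  m <- cells[[values]]
  if (is.null(m)) abort(sprintf("`%s` slot is empty", values))
  tb <- tibble::as_tibble(m, rownames = "gene")
  readr::write_csv(tb, path)
  invisible(cells)
}

#' Write ranked position predictions
#'
#' One row per cell: barcode, the k predicted bins best-first, then the k
#' scores. Bin identifiers are written 1-based (the challenge numbers
#' locations 1..B); internally everything is 0-based, and the shift
#' happens only here and in [read_predictions()].
#'
#' @param preds tidy predictions tibble from [rank_bins()] (columns
#'   `barcode`, `rank`, `bin_id`, `score`); every cell must have the same
#'   number of ranked bins.
#' @param path output CSV.
#' @return invisibly, `preds`.
#' @export
write_predictions <- function(preds, path) {
  check_predictions(preds)
  ks <- unique(table(preds$barcode))
  if (length(ks) > 1) abort("all cells must have the same number of ranked bins")
  k <- if (length(ks)) as.integer(ks) else 0L
  if (nrow(preds) == 0) {
    readr::write_lines("barcode", path)
    return(invisible(preds))
  }
  wide_bin <- tidyr::pivot_wider(
    dplyr::mutate(preds[, c("barcode", "rank", "bin_id")], bin_id = .data$bin_id + 1L),
    names_from = "rank", values_from = "bin_id", names_prefix = "bin")
  wide_score <- tidyr::pivot_wider(preds[, c("barcode", "rank", "score")],
    names_from = "rank", values_from = "score", names_prefix = "score")
  out <- dplyr::left_join(wide_bin, wide_score, by = "barcode")
  readr::write_csv(out, path)
  invisible(preds)
}

#' Read back a predictions CSV written by [write_predictions()]
#' @param path predictions CSV.
#' @return tidy tibble with columns `barcode`, `rank`, `bin_id` (0-based),
#'   `score`.
#' @export
read_predictions <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0)
    return(tibble::tibble(barcode = character(), rank = integer(),
                          bin_id = integer(), score = double()))
  bins <- tidyr::pivot_longer(tb[, c(1, grep("^bin", names(tb)))],
                              -1, names_to = "rank", values_to = "bin_id",
                              names_prefix = "bin")
  scores <- tidyr::pivot_longer(tb[, c(1, grep("^score", names(tb)))],
                                -1, names_to = "rank", values_to = "score",
                                names_prefix = "score")
  out <- dplyr::left_join(bins, scores, by = c("barcode", "rank"))
  dplyr::arrange(
    dplyr::mutate(out, rank = as.integer(.data$rank), bin_id = as.integer(.data$bin_id) - 1L),
    .data$barcode, .data$rank)
}

#' Export reconstructed spatial patterns alongside the geometry
#'
#' Writes one row per bin: x, y, z, then one column per gene, suitable
#' for plotting a reconstructed expression pattern over the embryo.
#'
#' @param patterns a [predicted_patterns()] (or bare bins-by-genes matrix).
#' @param geometry geometry tibble with the same number of bins.
#' @param path output CSV.
#' @return invisibly, the pattern matrix.
#' @export
write_pattern <- function(patterns, geometry, path) {
  m <- if (inherits(patterns, "predicted_patterns")) patterns$values else as.matrix(patterns)
  if (nrow(m) != nrow(geometry))
    abort("pattern row count does not match the geometry's bin count")
  out <- dplyr::bind_cols(geometry[, c("x", "y", "z")], tibble::as_tibble(m))
  readr::write_csv(out, path)
  invisible(m)
}

#' Read a pattern CSV written by [write_pattern()]
#' @param path pattern CSV.
#' @return list with `geometry` (tibble bin_id/x/y/z) and `values`
#'   (bins-by-genes matrix).
#' @export
read_pattern <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  geom <- tibble::tibble(bin_id = seq_len(nrow(tb)) - 1L,
                         x = tb$x, y = tb$y, z = tb$z)
  vals <- as.matrix(tb[, setdiff(names(tb), c("x", "y", "z")), drop = FALSE])
  list(geometry = geom, values = vals)
}

#' Check that atlas, geometry and cells can be assembled
#'
#' Verifies the shared bin count between atlas and geometry, and reports
#' (rather than silently intersecting) the gene overlap between atlas and
#' cell matrix; matching is exact and case-sensitive.
#'
#' @param atlas a [reference_atlas()].
#' @param geometry geometry tibble.
#' @param cells a [cell_matrix()].
#' @return tibble with one row per atlas/cell gene: `gene`, `in_atlas`,
#'   `in_cells`.
#' @export
validate_inputs <- function(atlas, geometry, cells) {
  if (n_bins(atlas) != nrow(geometry))
    abort(sprintf("atlas has %d bins but geometry has %d rows",
                  n_bins(atlas), nrow(geometry)))
  genes <- union(atlas$genes, cells$genes)
  tibble::tibble(gene = genes,
                 in_atlas = genes %in% atlas$genes,
                 in_cells = genes %in% cells$genes)
}
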