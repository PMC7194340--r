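#' Tidy a cell mapping into its ranked predictions
#' @param x a [map_cells()] result.
#' @param ... unused.
#' @return tibble `barcode`, `rank`, `bin_id`, `score`.
#' @exportS3Method generics::tidy
tidy.cell_mapping <- function(x, ...) x$predictions

#' One-row summary of a cell mapping
#' @param x a [map_cells()] result.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.cell_mapping <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$scores), n_bins = ncol(x$scores),
                 n_reference = length(x$config$reference_genes),
                 n_outgroup = length(x$config$outgroup_genes),
                 w1 = x$config$w1, w2 = x$config$w2,
                 n_iterations = x$config$n_iterations,
                 mean_best_score = mean(apply(unclass(x$scores), 1, max)))
}

#' Per-cell hit table of an evaluation
#' @param x an [evaluate_predictions()] result.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.position_eval <- function(x, ...) x$per_cell

#' One-row summary of an evaluation
#' @param x an [evaluate_predictions()] result.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.position_eval <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$per_cell),
                 n_hit = sum(x$per_cell$hit),
                 performance = x$performance)
}

#' Per-gene selection table
#' @param x a [select_genes()] result.
#' @param ... unused.
#' @return the reference and outgroup candidate tables stacked, with a
#'   `set` column.
#' @exportS3Method generics::tidy
tidy.gene_selection <- function(x, ...) {
  dplyr::bind_rows(reference = x$reference, outgroup = x$outgroup, .id = "set")
}

#' One-row summary of a gene selection
#' @param x a [select_genes()] result.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.gene_selection <- function(x, ...) {
  tibble::tibble(n_reference = length(x$reference_genes),
                 n_outgroup = length(x$outgroup_genes),
                 mean_reference_entropy =
                   mean(x$reference$entropy[x$reference$selected]),
                 mean_outgroup_entropy =
                   mean(x$outgroup$entropy[x$outgroup$selected]))
}
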