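test_that("atlas reader validates shape and binary entries, round-trips", {
  atlas <- tiny_atlas()
  vp <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  write_atlas(atlas, vp, bp)
  back <- read_atlas(vp, bp)
  expect_equal(back$genes, atlas$genes)
  expect_equal(back$values, atlas$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$binary, atlas$binary, ignore_attr = TRUE)

  # header mismatch between the paired files
  atlas2 <- atlas
  colnames(atlas2$binary) <- colnames(atlas2$values) <- c("gA", "gB", "gX")
  bp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(atlas2$binary), bp2)
  expect_error(read_atlas(vp, bp2), "headers differ")

  # non-binary entry in the binarized file
  bad <- atlas$binary; bad[1, 1] <- 2
  bp3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(bad), bp3)
  expect_error(read_atlas(vp, bp3), "0/1")
})

test_that("geometry reader auto-detects delimiter and header, assigns 0-based ids", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), p)
  g <- read_geometry(p)
  expect_equal(g$bin_id, 0:2)
  expect_equal(g$x, c(0, 1, 0))

  writeLines(c("x y z", "1.5\t2\t3", "4\t5\t6"), p)
  g2 <- read_geometry(p)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$x, c(1.5, 4))

  writeLines(c("x,y,z", "1,2,3", "4,5,6"), p)
  expect_equal(read_geometry(p)$z, c(3, 6))

  writeLines(c("1 2", "3 4"), p)
  expect_error(read_geometry(p), "3 coordinate columns")
  writeLines(c("1 2 3", "1 2 foo"), p)
  expect_error(read_geometry(p), "non-numeric")
})

test_that("cell-matrix reader is orientation invariant and validates contracts", {
  cells <- tiny_cells()
  p <- withr::local_tempfile(fileext = ".csv")
  write_cells(cells, p)
  back <- read_cells(p)
  expect_equal(back$genes, cells$genes)
  expect_equal(back$raw, cells$raw)

  # transposed file with cells_by_genes orientation gives the same object
  tp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(t(cells$raw), rownames = "barcode"), tp)
  back_t <- read_cells(tp, orientation = "cells_by_genes")
  expect_equal(back_t$raw, cells$raw)

  # duplicate barcodes and negative counts are rejected
  dup <- tibble::as_tibble(cells$raw, rownames = "gene")
  names(dup)[c(2, 3)] <- "cellX"
  readr::write_csv(dup, p)
  expect_error(read_cells(p), "uplicate")
  neg <- cells$raw; neg[1, 1] <- -1
  readr::write_csv(tibble::as_tibble(neg, rownames = "gene"), p)
  expect_error(read_cells(p), "egative")
})

test_that("prediction files are 1-based on disk and round-trip exactly", {
  preds <- tibble::tibble(barcode = c("cell1", "cell1"),
                          rank = 1:2, bin_id = c(0L, 5L), score = c(0.9, 0.4))
  p <- withr::local_tempfile(fileext = ".csv")
  write_predictions(preds, p)
  line2 <- readr::read_lines(p)[2]
  expect_match(line2, "^cell1,1,6,")   # 0-based 0/5 -> 1-based 1/6
  back <- read_predictions(p)
  expect_equal(back$bin_id, preds$bin_id)
  expect_equal(back$score, preds$score, tolerance = 1e-12)

  # empty prediction set -> header-only file
  write_predictions(preds[0, ], p)
  expect_equal(length(readr::read_lines(p)), 1)
  expect_equal(nrow(read_predictions(p)), 0)

  # ragged k across cells is rejected
  ragged <- dplyr::bind_rows(preds, tibble::tibble(
    barcode = "cell2", rank = 1L, bin_id = 3L, score = 0.5))
  expect_error(write_predictions(ragged, p), "same number")
})

test_that("pattern export carries coordinates and round-trips", {
  geom <- tiny_geometry(4)
  m <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("xg1", "xg2")))
  pat <- predicted_patterns(m)
  p <- withr::local_tempfile(fileext = ".csv")
  write_pattern(pat, geom, p)
  expect_equal(readr::read_lines(p)[1], "x,y,z,xg1,xg2")
  back <- read_pattern(p)
  expect_equal(back$values, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$geometry$x, geom$x)
  expect_error(write_pattern(pat, tiny_geometry(3), p), "bin count")
})

test_that("assembly validation reports gene overlap and enforces shared bin count", {
  atlas <- tiny_atlas()
  cells <- tiny_cells()
  rep4 <- validate_inputs(atlas, tiny_geometry(4), cells)
  expect_true(all(rep4$in_atlas & rep4$in_cells))
  expect_error(validate_inputs(atlas, tiny_geometry(3), cells), "bins")

  # non-overlapping gene is reported, not dropped silently
  cells2 <- cell_matrix(raw = rbind(cells$raw, gZ = c(1, 1, 1)))
  rep5 <- validate_inputs(atlas, tiny_geometry(4), cells2)
  expect_equal(rep5$in_atlas[rep5$gene == "gZ"], FALSE)
  expect_equal(rep5$in_cells[rep5$gene == "gZ"], TRUE)
})
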