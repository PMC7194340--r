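test_that("geometry lattice sits on the half-ellipsoid and is seed-deterministic", {
  g <- make_geometry(250, seed = 4)
  expect_equal(nrow(g), 250)
  expect_equal(g$bin_id, 0:249)
  expect_true(all(g$y >= 0))
  # points satisfy the ellipsoid equation with axes 2:1:1
  expect_equal((g$x / 2)^2 + g$y^2 + g$z^2, rep(1, 250), tolerance = 1e-9)
  expect_identical(make_geometry(250, seed = 4), g)
  expect_false(identical(make_geometry(250, seed = 5)$x, g$x))
  expect_error(make_geometry(0), ">= 1")
})

test_that("pattern families behave as designed", {
  g <- make_geometry(400, seed = 2)
  # pure AP gradient is monotone along x
  ap <- pattern_ap_gradient(g, midpoint = 0.5, steepness = 10)
  ord <- order(g$x)
  expect_true(all(diff(ap[ord]) >= -1e-12))
  # a 7-stripe gene has exactly 7 ON runs along a dense AP transect
  tg <- tibble::tibble(bin_id = 0:999, x = seq(-2, 2, length.out = 1000),
                       y = 0.5, z = 0)
  v <- pattern_stripes(tg, n_stripes = 7)
  on <- rle(as.integer(v > 0.5))
  expect_equal(sum(on$values == 1), 7)
})

test_that("synthetic atlases have valid binaries and honor redundancy", {
  g <- make_geometry(120, seed = 1)
  a <- make_atlas(g, 30, seed = 1)
  expect_true(all(a$binary %in% c(0, 1)))
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_identical(make_atlas(g, 30, seed = 1)$values, a$values)
  # archetype copies induce highly correlated gene pairs; independent
  # draws almost never do
  cors <- cor(make_atlas(g, 40, seed = 3, redundancy = 0.8)$values)
  expect_gt(sum(cors > 0.95 & upper.tri(cors)), 0)
})

test_that("simulated cells recover their bin profile in the noise-free limit", {
  g <- make_geometry(50, seed = 7)
  a <- make_atlas(g, 25, seed = 7)
  sim <- simulate_cells(a, NULL, n_cells = 30, dropout_prob = 0, noise_sd = 0,
                        depth_mean = 1e5, seed = 7, weak_fraction = 0,
                        amplitude_range = c(1, 1))
  cn <- normalize_cells(sim$cells)$normalized
  # in this limit normalized values converge to ln(pattern + baseline) + const
  rho <- vapply(seq_len(30), function(j) {
    cor(cn[, j], log(a$values[sim$truth$bin_id[j] + 1, a$genes] + 0.02))
  }, numeric(1))
  expect_gt(mean(rho), 0.98)
})

test_that("dropout produces the expected zero inflation", {
  g <- make_geometry(40, seed = 8)
  a <- make_atlas(g, 20, seed = 8)
  sim <- simulate_cells(a, NULL, n_cells = 50, dropout_prob = 0.9,
                        depth_mean = 2e4, seed = 8, weak_fraction = 0)
  zf <- mean(sim$cells$raw == 0)
  # at least the dropout mass, binomial 3-sigma slack
  n <- length(sim$cells$raw)
  expect_gt(zf, 0.9 - 3 * sqrt(0.9 * 0.1 / n))
  # same seed -> identical counts and truth
  sim2 <- simulate_cells(a, NULL, n_cells = 50, dropout_prob = 0.9,
                         depth_mean = 2e4, seed = 8, weak_fraction = 0)
  expect_identical(sim2$cells$raw, sim$cells$raw)
  expect_identical(sim2$truth, sim$truth)
  expect_error(simulate_cells(a, NULL, 10, dropout_prob = 1), "dropout")
})

test_that("simulated datasets round-trip through the challenge file formats", {
  e <- simulate_embryo(n_bins = 40, n_atlas_genes = 10, n_extra_genes = 6,
                       n_cells = 20, seed = 12)
  dir <- withr::local_tempdir()
  write_atlas(e$atlas, file.path(dir, "atlas.csv"), file.path(dir, "bin_atlas.csv"))
  write_geometry(e$geometry, file.path(dir, "geometry.txt"))
  write_cells(e$cells, file.path(dir, "counts.csv"))
  a <- read_atlas(file.path(dir, "atlas.csv"), file.path(dir, "bin_atlas.csv"))
  g <- read_geometry(file.path(dir, "geometry.txt"))
  cc <- read_cells(file.path(dir, "counts.csv"))
  expect_equal(a$values, e$atlas$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$x, e$geometry$x, tolerance = 1e-12)
  expect_equal(cc$raw, e$cells$raw, ignore_attr = TRUE)
  rep <- validate_inputs(a, g, cc)
  expect_equal(sum(rep$in_atlas), 10)
})

test_that("end-to-end recovery beats the analytic random-guess floor", {
  r <- end_to_end_recovery(n_bins = 100, n_atlas_genes = 25, n_extra_genes = 20,
                           n_cells = 60, n_reference = 10, n_outgroup = 20,
                           seed = 17, n_iterations = 2)
  floor_pct <- 100 * r$mapping$config$top_k_bins / 100
  expect_gt(r$performance, 3 * floor_pct)
  expect_equal(nrow(r$trace), 2)
})
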