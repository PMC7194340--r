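test_that("mcc matches hand-computed confusion cases and conventions", {
  u <- c(1, 1, 0, 0)
  expect_equal(mcc(u, u), 1)
  expect_equal(mcc(u, c(1, 0, 1, 0)), 0)            # (1*1 - 1*1)/sqrt(16)
  expect_equal(mcc(u, 1 - u), -1)
  expect_equal(mcc(c(1, 1, 1), c(1, 0, 1)), 0)      # constant u -> 0 by convention
  expect_equal(mcc(u, u), mcc(rev(u), rev(u)))
  expect_error(mcc(u, c(1, 0)), "length")
  expect_error(mcc(c(1, 2, 0, 0), u), "binary")
})

test_that("mcc equals the Pearson correlation of binary vectors", {
  withr::with_seed(100, {
    for (i in 1:200) {
      n <- sample(4:64, 1)
      u <- rand_binary(1, n)[1, ]; v <- rand_binary(1, n)[1, ]
      if (var(u) == 0 || var(v) == 0) next
      expect_equal(mcc(u, v), cor(u, v), tolerance = 1e-12)
    }
  })
})

test_that("mcc_matrix equals elementwise mcc and respects gene alignment", {
  withr::with_seed(7, {
    cellsb <- rand_binary(5, 8); atlasb <- rand_binary(6, 8)
    colnames(cellsb) <- colnames(atlasb) <- paste0("g", 1:8)
    m <- mcc_matrix(cellsb, atlasb)
    expect_equal(score_kind(m), "mcc")
    for (j in 1:5) for (i in 1:6)
      expect_equal(m[j, i], mcc(cellsb[j, ], atlasb[i, ]), tolerance = 1e-12)
    # consistent column permutation changes nothing
    perm <- sample(8)
    m2 <- mcc_matrix(cellsb[, perm], atlasb[, perm])
    expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
    expect_error(mcc_matrix(cellsb, atlasb[, c(2:8, 1)]), "gene order")
    expect_error(mcc_matrix(cellsb[, 1:7], atlasb), "gene axes")
  })

  # a cell matching one bin's profile exactly peaks there
  atlasb <- rand_binary(10, 12); colnames(atlasb) <- paste0("g", 1:12)
  cb <- atlasb[7, , drop = FALSE]
  m <- mcc_matrix(cb, atlasb)
  expect_equal(which.max(m[1, ]), 7L)
})

test_that("overlap is the cosine on the non-null subspace", {
  # third component null: v projected to (2,4,0); cos = 10/(sqrt5*sqrt20) = 1
  expect_equal(overlap(c(1, 2, 0), c(2, 4, 7), c(FALSE, FALSE, TRUE)), 1,
               tolerance = 1e-12)
  expect_equal(overlap(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  # support of u entirely absent from v -> 0 by convention
  expect_equal(overlap(c(1, 2, 0), c(0, 0, 5), c(FALSE, FALSE, TRUE)), 0)
  expect_error(overlap(1:3, 1:2), "length")
  # scale invariance in both arguments
  withr::with_seed(11, {
    u <- rnorm(20); v <- rnorm(20); mask <- runif(20) < 0.3
    expect_equal(overlap(3.7 * u, 0.2 * v, mask), overlap(u, v, mask),
                 tolerance = 1e-12)
  })
})

test_that("overlap_matrix masks each cell by its zero raw counts", {
  withr::with_seed(21, {
    genes <- paste0("og", 1:5)
    raw <- matrix(rpois(5 * 4, 2), 5, 4,
                  dimnames = list(genes, paste0("c", 1:4)))
    raw[2, 1] <- 0
    cells <- normalize_cells(cell_matrix(raw = raw))
    pat <- predicted_patterns(matrix(rnorm(3 * 5), 3, 5,
                                     dimnames = list(NULL, genes)))
    om <- overlap_matrix(cells, pat)
    expect_equal(score_kind(om), "overlap")
    for (j in 1:4) for (i in 1:3)
      expect_equal(unname(om[j, i]),
                   overlap(cells$normalized[genes, j], pat$values[i, ],
                           raw[genes, j] == 0),
                   tolerance = 1e-12)
    # identical pattern rows give constant score rows
    pat2 <- predicted_patterns(matrix(rep(rnorm(5), each = 3), 3, 5,
                                      dimnames = list(NULL, genes)))
    om2 <- overlap_matrix(cells, pat2)
    expect_true(all(apply(om2, 1, function(r) diff(range(r)) < 1e-12)))
    # a cell with no expressed pattern gene scores zero everywhere
    mask_all <- matrix(TRUE, 5, 4, dimnames = dimnames(raw))
    om3 <- overlap_matrix(cells, pat, null_mask = mask_all)
    expect_true(all(om3 == 0))
  })
})

test_that("composite score is the stated convex combination", {
  withr::with_seed(3, {
    c_m <- score_matrix(matrix(runif(12, -1, 1), 3, 4), "mcc")
    o_m <- score_matrix(matrix(runif(12, -1, 1), 3, 4), "overlap")
    s <- composite_score(c_m, o_m, 0.9, 0.1)
    expect_equal(unclass(s), 0.9 * unclass(c_m) + 0.1 * unclass(o_m),
                 ignore_attr = TRUE)
    expect_equal(score_kind(s), "composite")
    # with c = o any valid weights return c (subchallenge-3 weights)
    s2 <- composite_score(c_m, score_matrix(unclass(c_m), "overlap"), 0.7, 0.3)
    expect_equal(unclass(s2), unclass(c_m), ignore_attr = TRUE)
    # w1 = 1 is the identity on c
    expect_equal(unclass(composite_score(c_m, o_m, 1, 0)), unclass(c_m),
                 ignore_attr = TRUE)
    # worked arithmetic: 0.9 * 0.5 + 0.1 * 0.2
    one <- composite_score(score_matrix(matrix(0.5), "mcc"),
                           score_matrix(matrix(0.2), "overlap"), 0.9, 0.1)
    expect_equal(as.numeric(one), 0.47)
    expect_error(composite_score(c_m, score_matrix(matrix(0, 2, 2), "overlap"),
                                 0.5, 0.5), "shape")
    expect_error(composite_score(c_m, o_m, 0.5, 0.6), "sum to 1")
  })
})

test_that("composite is monotone in each component for non-negative weights", {
  withr::with_seed(13, {
    c_m <- matrix(runif(20, -1, 1), 4, 5)
    o_m <- matrix(runif(20, -1, 1), 4, 5)
    s0 <- composite_score(score_matrix(c_m, "mcc"),
                          score_matrix(o_m, "overlap"), 0.7, 0.3)
    bump <- o_m; bump[2, 3] <- bump[2, 3] + 0.5
    s1 <- composite_score(score_matrix(c_m, "mcc"),
                          score_matrix(bump, "overlap"), 0.7, 0.3)
    expect_gt(s1[2, 3], s0[2, 3])
    expect_equal(unclass(s1)[-c(10)], unclass(s0)[-c(10)])
  })
})

test_that("default weights follow the per-subchallenge settings", {
  expect_equal(default_weights(20), c(w1 = 0.7, w2 = 0.3))
  expect_equal(default_weights(60), c(w1 = 0.9, w2 = 0.1))
  expect_equal(default_weights(40), c(w1 = 0.9, w2 = 0.1))
})
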