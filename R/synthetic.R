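#' Synthetic embryo geometry: a half-ellipsoid bin lattice
#'
#' Quasi-uniform points on the `y >= 0` half of an ellipsoid surface with
#' axes in ratio 2:1:1 (anterior-posterior axis twice the other two),
#' emulating the shape of the reference atlas's bin cloud. Sampling is
#' seeded rejection: directions drawn isotropically, mapped to the
#' ellipsoid, and accepted proportionally to the local area element so
#' density is uniform over the surface.
#'
#' @param n_bins number of bins (>= 1).
#' @param seed RNG seed; the same seed always yields the same lattice.
#' @return geometry tibble `bin_id`, `x`, `y`, `z`.
#' @export
make_geometry <- function(n_bins, seed = 1L) {
  if (n_bins < 1) abort("n_bins must be >= 1")
  axes <- c(2, 1, 1)
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n_bins) {
      m <- max(4L * (n_bins - nrow(pts)), 32L)
      d <- matrix(rnorm(3 * m), m, 3)
      d <- d / sqrt(rowSums(d^2))
      # area-element weight of the sphere -> ellipsoid map, max-normalized
      w <- sqrt((axes[2] * axes[3] * d[, 1])^2 +
                (axes[1] * axes[3] * d[, 2])^2 +
                (axes[1] * axes[2] * d[, 3])^2)
      keep <- runif(m) < w / max(axes[1] * axes[2], axes[1] * axes[3], axes[2] * axes[3])
      d <- d[keep, , drop = FALSE]
      p <- sweep(d, 2, axes, "*")
      p[, 2] <- abs(p[, 2])     # fold onto the y >= 0 half
      pts <- rbind(pts, p)
    }
    pts <- pts[seq_len(n_bins), , drop = FALSE]
    tibble::tibble(bin_id = seq_len(n_bins) - 1L,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
}

# pattern families over geometry coordinates; all return values in [0, 1]
ap_frac <- function(geometry) {
  r <- range(geometry$x)
  (geometry$x - r[1]) / max(r[2] - r[1], .Machine$double.eps)
}

#' Spatial pattern generators
#'
#' Deterministic expression patterns over a geometry, each scaled to
#' `[0, 1]`: a logistic anterior-posterior gradient, periodic AP stripes
#' (`sin^2(pi * k * x)` gives exactly `k` ON runs along the axis when
#' `phase = 0`), a dorso-ventral logistic gradient, and a Gaussian patch
#' around one bin. [make_atlas()] mixes these families randomly.
#'
#' @param geometry geometry tibble.
#' @param midpoint,steepness logistic location (as an AP/DV fraction) and
#'   slope.
#' @param flip reverse the gradient direction.
#' @param n_stripes stripe count along the AP axis.
#' @param phase stripe phase shift in AP-fraction units.
#' @param center_bin 0-based bin id at the patch center.
#' @param width patch standard deviation in coordinate units.
#' @return numeric vector of length `nrow(geometry)` in `[0, 1]`.
#' @name patterns
NULL

#' @rdname patterns
#' @export
pattern_ap_gradient <- function(geometry, midpoint = 0.5, steepness = 8, flip = FALSE) {
  v <- stats::plogis(steepness * (ap_frac(geometry) - midpoint))
  scale01(if (flip) 1 - v else v)
}

#' @rdname patterns
#' @export
pattern_stripes <- function(geometry, n_stripes, phase = 0) {
  scale01(sin(pi * n_stripes * (ap_frac(geometry) - phase))^2)
}

#' @rdname patterns
#' @export
pattern_dv_gradient <- function(geometry, midpoint = 0.5, steepness = 8, flip = FALSE) {
  # transverse position as the circumferential angle around the AP axis,
  # so domains are angular sectors (dorsal / lateral / ventral) rather
  # than slabs in z, which compresses laterally
  ang <- atan2(geometry$z, geometry$y)            # [-pi, pi], y >= 0 half
  af <- (ang + pi) / (2 * pi)
  v <- stats::plogis(steepness * (af - midpoint))
  scale01(if (flip) 1 - v else v)
}

#' @rdname patterns
#' @export
pattern_patch <- function(geometry, center_bin, width) {
  ctr <- geometry[geometry$bin_id == center_bin, ]
  if (nrow(ctr) != 1) abort("center_bin not found in geometry")
  d2 <- (geometry$x - ctr$x)^2 + (geometry$y - ctr$y)^2 + (geometry$z - ctr$z)^2
  scale01(exp(-d2 / (2 * width^2)))
}

scale01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# switch-like contrast around the half-maximum: embryo patterning genes
# have sharp domain boundaries, which is what makes ON/OFF binarization
# of the atlas meaningful in the first place
sharpen <- function(v, gamma = 6) {
  v^gamma / (v^gamma + (1 - v)^gamma)
}

# one random raw (pre-contrast) pattern from the family mix
random_pattern <- function(geometry, scale) {
  fam <- sample(c("ap", "stripes", "dv", "patch", "combo"), 1,
                prob = c(0.2, 0.35, 0.2, 0.1, 0.15))
  switch(fam,
    ap = pattern_ap_gradient(geometry, midpoint = runif(1, 0.3, 0.7),
                             steepness = runif(1, 8, 15),
                             flip = runif(1) < 0.5),
    stripes = pattern_stripes(geometry, n_stripes = sample(3:8, 1),
                              phase = runif(1)),
    dv = pattern_dv_gradient(geometry, midpoint = runif(1, 0.3, 0.7),
                             steepness = runif(1, 5, 15),
                             flip = runif(1) < 0.5),
    patch = pattern_patch(geometry,
                          center_bin = sample(geometry$bin_id, 1),
                          width = runif(1, 0.35, 0.5) * scale),
    combo = scale01(pmax(
      pattern_stripes(geometry, n_stripes = sample(3:8, 1),
                      phase = runif(1)),
      pattern_dv_gradient(geometry, midpoint = runif(1, 0.55, 0.75),
                          steepness = runif(1, 8, 15),
                          flip = runif(1) < 0.5))))
}

#' Synthetic reference atlas with stripe/gradient/patch patterns
#'
#' Gene patterns are drawn from a seeded mix of the [patterns] families
#' (logistic AP gradients, 3-8 AP stripes with random phase, angular DV
#' gradients, Gaussian patches, and stripe-plus-DV combinations such as
#' real pair-rule genes show). To emulate the pervasive co-expression of
#' real patterning genes, a fraction `redundancy` of the genes are noisy
#' copies of a smaller set of archetype patterns rather than independent
#' draws — the redundancy that gene-set selection by clustering is meant
#' to collapse. All patterns pass through a switch-like contrast
#' transform (embryo expression domains have sharp boundaries, which is
#' what makes ON/OFF binarization of an atlas meaningful) and are scaled
#' to `[0, 1]`; the binary twin thresholds each gene at 0.5 on that
#' scale.
#'
#' @param geometry geometry tibble.
#' @param n_genes number of genes (>= 1).
#' @param seed RNG seed.
#' @param prefix gene-name prefix (`"g"` for atlas genes; use a different
#'   prefix for non-atlas genes so name sets are disjoint).
#' @param redundancy fraction of genes drawn as jittered archetype
#'   copies (default 0.3); the archetype pool has about `n_genes / 3`
#'   members.
#' @param jitter_sd spatial noise added to archetype copies before the
#'   contrast transform.
#' @return a [reference_atlas()].
#' @export
make_atlas <- function(geometry, n_genes, seed = 1L, prefix = "g",
                       redundancy = 0.3, jitter_sd = 0.06) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (redundancy < 0 || redundancy > 1) abort("redundancy must be in [0, 1]")
  scale <- max(geometry$x) - min(geometry$x)
  B <- nrow(geometry)
  withr::with_seed(seed, {
    n_arch <- max(2L, ceiling(n_genes / 3))
    archetypes <- replicate(n_arch, random_pattern(geometry, scale))
    vals <- vapply(seq_len(n_genes), function(i) {
      if (runif(1) < redundancy) {
        v <- archetypes[, sample.int(n_arch, 1)] + rnorm(B, 0, jitter_sd)
        pmin(pmax(v, 0), 1)
      } else {
        random_pattern(geometry, scale)
      }
    }, numeric(B))
    vals <- apply(vals, 2, sharpen)
    colnames(vals) <- sprintf("%s%03d", prefix, seq_len(n_genes))
    reference_atlas(vals, (vals > 0.5) + 0)
  })
}

#' Simulate dissociated single cells from a synthetic embryo
#'
#' Each cell is assigned a uniform random bin; its expected expression is
#' that bin's pattern value (atlas plus extra genes, plus a small
#' baseline so no gene is structurally absent). Counts are Poisson with
#' per-gene-per-cell multiplicative lognormal noise, scaled so the
#' expected cell depth is `depth_mean`, then zeroed independently with
#' probability `dropout_prob` — the excess technical zeros that motivate
#' the projected overlap score. Gene detectability is heterogeneous, as
#' in real scRNA-seq: most genes carry a fixed expression amplitude
#' drawn log-uniformly from `amplitude_range`, but a fraction
#' `weak_fraction` falls below the effective detection limit
#' (`weak_amplitude`), yielding the zero-heavy, nearly uninformative
#' profiles that informative gene selection exists to discard.
#'
#' @param atlas a [reference_atlas()] (the genes the atlas shares).
#' @param extra a second [reference_atlas()] of non-atlas genes (outgroup
#'   candidates), same geometry; or `NULL` for none.
#' @param n_cells number of cells.
#' @param dropout_prob technical-zero probability in `[0, 1)`.
#' @param noise_sd standard deviation of the log-scale multiplicative
#'   noise (`>= 0`).
#' @param depth_mean expected total counts per cell (> 0).
#' @param seed RNG seed.
#' @param baseline floor added to every pattern value (default 0.02).
#' @param amplitude_range log-uniform amplitude range of well-captured
#'   genes (default `c(0.3, 1)`).
#' @param weak_fraction fraction of genes below the detection limit
#'   (default 0.3).
#' @param weak_amplitude amplitude range of poorly captured genes
#'   (default `c(0.001, 0.005)`).
#' @return list with `cells` (a raw-count [cell_matrix()]) and `truth`
#'   (tibble `barcode`, `bin_id`).
#' @export
simulate_cells <- function(atlas, extra = NULL, n_cells,
                           dropout_prob = 0, noise_sd = 0,
                           depth_mean = 8000, seed = 1L, baseline = 0.02,
                           amplitude_range = c(0.3, 1),
                           weak_fraction = 0.3,
                           weak_amplitude = c(0.001, 0.005)) {
  if (dropout_prob < 0 || dropout_prob >= 1) abort("dropout_prob must be in [0, 1)")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (depth_mean <= 0) abort("depth_mean must be > 0")
  if (n_cells < 1) abort("n_cells must be >= 1")
  pat <- atlas$values
  if (!is.null(extra)) {
    if (nrow(extra$values) != nrow(pat)) abort("atlas and extra genes disagree on bins")
    if (length(intersect(atlas$genes, extra$genes)))
      abort("atlas and extra gene names must be disjoint")
    pat <- cbind(pat, extra$values)
  }
  pat <- pat + baseline
  B <- nrow(pat); G <- ncol(pat)
  for (rng in list(amplitude_range, weak_amplitude))
    if (length(rng) != 2 || any(rng <= 0) || diff(rng) < 0)
      abort("amplitude ranges must be increasing pairs of positive values")
  if (weak_fraction < 0 || weak_fraction >= 1)
    abort("weak_fraction must be in [0, 1)")
  withr::with_seed(seed, {
    amp <- 10^runif(G, log10(amplitude_range[1]), log10(amplitude_range[2]))
    weak <- runif(G) < weak_fraction
    amp[weak] <- 10^runif(sum(weak), log10(weak_amplitude[1]), log10(weak_amplitude[2]))
    pat <- sweep(pat, 2, amp, "*")
    bins <- sample.int(B, n_cells, replace = TRUE) - 1L
    counts <- vapply(seq_len(n_cells), function(j) {
      mu <- pat[bins[j] + 1L, ]
      if (noise_sd > 0) mu <- mu * exp(rnorm(G, 0, noise_sd))
      lam <- depth_mean * mu / sum(mu)
      x <- rpois(G, lam)
      if (dropout_prob > 0) x[runif(G) < dropout_prob] <- 0L
      x
    }, numeric(G))
    barcodes <- sprintf("cell_%04d", seq_len(n_cells))
    dimnames(counts) <- list(colnames(pat), barcodes)
    list(cells = cell_matrix(raw = counts),
         truth = tibble::tibble(barcode = barcodes, bin_id = bins))
  })
}

#' Simulate a complete ground-truthed embryo dataset
#'
#' Convenience wrapper: geometry, atlas (with binary twin), extra
#' (non-atlas) gene patterns, dissociated cells and true cell-to-bin
#' labels, all derived deterministically from one seed.
#'
#' @param n_bins,n_atlas_genes,n_extra_genes,n_cells dataset dimensions.
#' @param dropout_prob,noise_sd,depth_mean,baseline,amplitude_range,weak_fraction,weak_amplitude
#'   passed to [simulate_cells()].
#' @param seed master RNG seed (sub-seeds are derived from it).
#' @return list with `geometry`, `atlas`, `extra`, `cells`, `truth`.
#' @export
simulate_embryo <- function(n_bins = 300, n_atlas_genes = 50,
                            n_extra_genes = 100, n_cells = 200,
                            dropout_prob = 0, noise_sd = 0,
                            depth_mean = 8000, seed = 1L, baseline = 0.02,
                            amplitude_range = c(0.3, 1),
                            weak_fraction = 0.3,
                            weak_amplitude = c(0.001, 0.005)) {
  seeds <- derive_seeds(seed, 4)
  geometry <- make_geometry(n_bins, seed = seeds[1])
  atlas <- make_atlas(geometry, n_atlas_genes, seed = seeds[2], prefix = "ag")
  extra <- if (n_extra_genes > 0)
    make_atlas(geometry, n_extra_genes, seed = seeds[3], prefix = "xg")
  sim <- simulate_cells(atlas, extra, n_cells, dropout_prob, noise_sd,
                        depth_mean, seed = seeds[4], baseline = baseline,
                        amplitude_range = amplitude_range,
                        weak_fraction = weak_fraction,
                        weak_amplitude = weak_amplitude)
  list(geometry = geometry, atlas = atlas, extra = extra,
       cells = sim$cells, truth = sim$truth)
}

# small deterministic seed stream, kept within 32-bit integer range
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

#' End-to-end position recovery on a synthetic embryo
#'
#' Runs the whole pipeline against simulator ground truth: simulate,
#' normalize, binarize, select reference and outgroup genes, map cells
#' iteratively, and score the predictions against the true cell-to-bin
#' labels (not the full-atlas MCC surrogate).
#'
#' @inheritParams simulate_embryo
#' @param n_reference reference genes to select (default 20).
#' @param n_outgroup outgroup genes to select (default
#'   `min(100, n_extra_genes)`).
#' @param quantile binarization quantile, or `NULL` (default) to select
#'   it by the method's own distance-minimization calibration
#'   ([choose_quantile()]) over `quantile_grid` — the same procedure that
#'   fixed 0.23 on the challenge data.
#' @param quantile_grid candidate quantiles for the calibration.
#' @param w1,w2,n_iterations,top_k_bins,top_k_cells passed to
#'   [map_cells()].
#' @return list with `performance` (final %), `trace` (tibble
#'   `iteration`, `performance`), `selection`, `mapping`, `truth` and the
#'   simulated `embryo`.
#' @export
end_to_end_recovery <- function(n_bins = 300, n_atlas_genes = 50,
                                n_extra_genes = 100, n_cells = 200,
                                dropout_prob = 0, noise_sd = 0,
                                depth_mean = 8000, seed = 1L,
                                amplitude_range = c(0.3, 1),
                                weak_fraction = 0.3,
                                weak_amplitude = c(0.001, 0.005),
                                n_reference = 20, n_outgroup = NULL,
                                quantile = NULL,
                                quantile_grid = seq(0.1, 0.9, by = 0.05),
                                w1 = NULL, w2 = NULL,
                                n_iterations = 3, top_k_bins = 10,
                                top_k_cells = 10) {
  n_outgroup <- n_outgroup %||% min(100, n_extra_genes)
  embryo <- simulate_embryo(n_bins, n_atlas_genes, n_extra_genes, n_cells,
                            dropout_prob, noise_sd, depth_mean, seed,
                            amplitude_range = amplitude_range,
                            weak_fraction = weak_fraction,
                            weak_amplitude = weak_amplitude)
  cells <- normalize_cells(embryo$cells)
  quantile <- quantile %||% as.numeric(choose_quantile(cells, embryo$atlas, quantile_grid))
  cells <- binarize_cells(cells, quantile = quantile)
  selection <- select_genes(cells, embryo$atlas, n_reference, n_outgroup)
  mapping <- map_cells(cells, embryo$atlas, selection, w1 = w1, w2 = w2,
                       n_iterations = n_iterations, top_k_bins = top_k_bins,
                       top_k_cells = top_k_cells)
  trace <- performance_trace(mapping, embryo$truth)
  list(performance = trace$performance[nrow(trace)], trace = trace,
       quantile = quantile, selection = selection, mapping = mapping,
       truth = embryo$truth, embryo = embryo)
}
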