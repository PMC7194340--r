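# small in-code fixtures shared across test files

# tiny deterministic atlas: 4 bins x 3 genes
tiny_atlas <- function() {
  vals <- matrix(c(0.9, 0.1, 0.5,
                   0.8, 0.2, 0.1,
                   0.1, 0.9, 0.9,
                   0.2, 0.7, 0.3),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(NULL, c("gA", "gB", "gC")))
  reference_atlas(vals, (vals > 0.5) + 0)
}

tiny_geometry <- function(n = 4) {
  tibble::tibble(bin_id = seq_len(n) - 1L,
                 x = seq_len(n), y = rep(0.5, n), z = rep(0.1, n))
}

# counts with known structure: genes x cells
tiny_cells <- function() {
  raw <- matrix(c(5, 0, 2,
                  1, 4, 0,
                  0, 2, 6),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"),
                                c("cell1", "cell2", "cell3")))
  cell_matrix(raw = raw)
}

# random binary matrix helper
rand_binary <- function(n, m, p = 0.5) {
  matrix(as.numeric(runif(n * m) < p), n, m)
}

# brute-force UPGMA: average linkage on the original distance matrix,
# O(G^3); returns the flat partition at k clusters (membership vector)
bf_upgma_cut <- function(d, k) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(j, i) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(nrow(d))
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# are two flat partitions identical up to label permutation?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# direct confusion-matrix MCC, written independently of the package
mcc_by_confusion <- function(u, v) {
  tp <- sum(u & v); tn <- sum(!u & !v)
  fp <- sum(!u & v); fn <- sum(u & !v)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}
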