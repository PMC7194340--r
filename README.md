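# spatmap

Map dissociated single cells back onto the spatial positions of a
binarized in-situ reference atlas.

Single-cell RNA sequencing destroys spatial context: after dissociation,
nobody knows where in the tissue each sequenced cell sat. When an *in situ*
reference atlas exists — a panel of genes whose expression has been measured
and binarized over `B` discrete spatial bins with known coordinates, as for
the early fly embryo (84 driver genes over 3039 locations) — each cell's
origin can be recovered by matching expression profiles. `spatmap`
implements an iterative matching method built from three pieces:

1. **Informative gene selection.** Candidate genes are clustered with UPGMA
   (average linkage, Euclidean distance on normalized profiles), the tree is
   cut into `N` clusters, and each cluster contributes its maximum-entropy
   gene (histogram entropy, bin width 0.125) — removing both redundant
   co-expressed genes and zero-heavy, barely detected ones. The same
   procedure picks 100 non-atlas "outgroup" genes.

2. **Two similarity channels.** Cells are depth-normalized
   (`ln((count + 1) / T_c)`) and binarized at a per-gene quantile threshold
   (0.23 for the original challenge data; `choose_quantile()` calibrates it
   for any dataset by distance minimization). Channel one scores every cell
   against every bin with the Matthews correlation coefficient (MCC) of the
   binarized profiles over the `N` reference genes. Channel two reconstructs
   each outgroup gene's spatial pattern as a score-weighted average of the
   ten best cells per bin (`e_ig = Σ* c_ij e_jg`, normalized) and scores
   each cell by the cosine between its outgroup expression vector and the
   reconstructed pattern, projected onto the subspace of genes the cell
   actually expresses — so dropout zeros cannot corrupt the comparison.

3. **Iterative composite scoring.** Iteration 1 is pure MCC; later
   iterations rebuild the patterns from the previous scores and combine the
   channels as `S = w1·c + w2·o` (defaults 0.7/0.3 for 20 reference genes,
   0.9/0.1 for 40 or 60), with the MCC term held fixed. Each cell's
   predicted position is its ten best-scoring bins; performance is the
   percentage of cells whose true bin is among them.

Because the real data's true positions are unknowable, the package ships a
fully tested synthetic-embryo generator (half-ellipsoid bin lattice;
stripe, gradient, sector and patch expression patterns with co-expression
redundancy and detection-limit heterogeneity; Poisson counts with lognormal
noise and dropout; ground-truth cell-to-bin labels) so every stage is
verifiable end to end.

## Worked example

```r
library(spatmap)

embryo <- simulate_embryo(n_bins = 300, n_atlas_genes = 50, n_extra_genes = 100,
                          n_cells = 200, dropout_prob = 0.3, noise_sd = 0.3, seed = 1)
cells <- normalize_cells(embryo$cells)
q <- choose_quantile(cells, embryo$atlas, seq(0.1, 0.9, by = 0.05))
as.numeric(q)
#> [1] 0.65
cells <- binarize_cells(cells, quantile = q)

sel <- select_genes(cells, embryo$atlas, n_reference = 20, n_outgroup = 100)
glance(sel)
#> # A tibble: 1 × 4
#>   n_reference n_outgroup mean_reference_entropy mean_outgroup_entropy
#>         <int>      <int>                  <dbl>                 <dbl>
#> 1          20        100                   3.16                  2.74

mapping <- map_cells(cells, embryo$atlas, sel)
mapping
#> <cell_mapping> 200 cells x 300 bins, 3 iteration(s), w1=0.70 w2=0.30
tidy(mapping)
#> # A tibble: 2,000 × 4
#>   barcode    rank bin_id score
#>   <chr>     <int>  <int> <dbl>
#> 1 cell_0001     1    208 0.752
#> 2 cell_0001     2    255 0.752
#> 3 cell_0001     3    275 0.752
#> 4 cell_0001     4    162 0.718
#> # ℹ 1,996 more rows

performance_trace(mapping, embryo$truth)
#> # A tibble: 3 × 2
#>   iteration performance
#>       <int>       <dbl>
#> 1         1        84
#> 2         2        87
#> 3         3        87.5
evaluate_predictions(mapping$predictions, embryo$truth)
#> <position_eval> 87.50% of 200 cells well predicted
```

The calibration picked the ON threshold at the 0.65 quantile for this noisy
embryo; 84% of cells had their true bin among the top ten by MCC alone, and
the composite-score iterations raised that to 87.5%. `tidy(mapping)` gives
one row per (cell, rank): bin 208 is cell 1's best guess with composite
score 0.752. `plot_pattern()`, `plot_performance_trace()`,
`plot_baseline()` and `autoplot()` methods visualize patterns, the
refinement trace and the random-set baseline; `write_predictions()` exports
a challenge-style CSV (bin ids 1-based on disk).

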