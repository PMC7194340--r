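Package: spatmap
Title: Spatial Mapping of Single Cells onto a Binarized Reference Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps dissociated single cells from scRNA-seq back onto the
    spatial positions of a binarized in-situ reference atlas. Reference
    genes are chosen by UPGMA clustering of expression profiles followed
    by per-cluster maximum-entropy selection; each cell is scored against
    every spatial bin with the Matthews correlation coefficient of the
    binarized profiles; spatial patterns of held-out "outgroup" genes are
    reconstructed as score-weighted averages over the best-scoring cells;
    and positions are refined iteratively with a composite score that
    adds a projected-cosine overlap between each cell and the
    reconstructed patterns. Includes a ground-truthed synthetic embryo
    generator (half-ellipsoid bin lattice, stripe/gradient/patch
    expression patterns, Poisson-lognormal counts with dropout) so the
    whole pipeline can be exercised and evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
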