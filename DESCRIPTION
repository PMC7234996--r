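Package: pikw
Title: Phylogenetically Independent Kruskal-Wallis Tests with
    Brownian-Motion Empirical Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of a binary clade factor against
    continuous traits on a time-calibrated phylogeny.  Conventional
    tie-corrected Kruskal-Wallis screening is followed by a
    phylogenetically independent test whose null distribution of the H
    statistic is generated by simulating Brownian-motion trait evolution
    on the tree pruned to the species under test; significance uses the
    95th percentile of the empirical null.  Includes trait-table
    assembly (mass-specific basal metabolic rate, maximum lifespan,
    data-quality filtering), interval stratification with Mann-Whitney
    balance checks, degenerate-consensus (IUPAC) scanning of promoter
    windows for antioxidant response elements, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
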