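# pikw

Phylogenetically independent Kruskal–Wallis tests with Brownian-motion
empirical nulls — plus the trait-table assembly, interval stratification,
and antioxidant-response-element (ARE) promoter scanning that surround them.

## The problem

Comparative biologists often need to ask whether species in one clade differ
in a continuous trait from species outside it — for example, whether birds
whose KEAP1 repressor is non-functional (Neoaves, with constitutively active
NRF2 antioxidant signalling) have higher mass-specific basal metabolic rates
(MS-BMR = BMR/mass) or longer maximum lifespans than the basal lineages that
retain a working KEAP1.  Species are not independent observations: shared
ancestry makes conventional tests reject far too often, and the problem is
at its worst when the grouping factor *is* a clade.

## The method

For a stratum of species with a binary factor `g` and continuous response
`y` on a time-calibrated phylogeny:

1. compute the tie-corrected Kruskal–Wallis statistic

   H = [ 12/(N(N+1)) · Σᵢ Rᵢ²/nᵢ − 3(N+1) ] / C,
   C = 1 − Σ_g (t_g³ − t_g)/(N³ − N),

   and screen with its χ²(k−1) p-value;
2. prune the tree to exactly those species, simulate `n_sims` (default
   1000) replicate traits under Brownian motion — tip covariance
   σ² × (shared root-to-MRCA path length) — and compute each replicate's H
   against the *real* labels;
3. declare significance iff the stratum screened at α = 0.05 **and** the
   observed H exceeds the 95th nearest-rank percentile of this empirical
   null.  Add-one and raw empirical p-values are reported alongside.

Because H depends on ranks only and the simulator generates increments as
standard normals scaled by √(σ²·branch), the null is *exactly* invariant to
the Brownian rate and root state — they are not assumptions the user has to
defend.  Strata are bins of the other trait (compare metabolic rate at
equivalent lifespan, and vice versa), each checked for Mann–Whitney balance
of the stratifying variable between factor levels.

A companion module scans the ~1 kb windows upstream of gene loci for the
degenerate NRF2-binding consensus `TGASWMAKCN` (64 expansions, IUPAC codes,
both strands, BED coordinates), and a synthetic-data module generates
ultrametric trees, monophyletic factor labels, Brownian traits with known
clade shifts, and promoters with planted motifs, so the whole pipeline is
testable against ground truth.

## Worked example

```r
library(pikw)

sdat <- synth_comparative(n_tips = 120, clade_fraction = 0.8,
                          clade_shift = 3, seed = 11)   # planted effect
res <- pikw_pipeline(sdat$tree, sdat$table,
                     response = "ms_bmr", stratify_by = "max_lifespan",
                     bin_edges = c(10, 20, 30, 40, 50),
                     n_sims = 1000, seed = 11)
res
#> PI Kruskal-Wallis pipeline: ms_bmr by KEAP1 factor, stratified by max_lifespan
#>   stratum n0 n1      H   chisq_p screened balance_p    balance threshold_95
#> 1     <10 66 32 64.000 1.244e-15     TRUE   0.02374       fail       53.113
#> 2 [10,20)  3  7  5.727 1.670e-02     TRUE   0.18333       pass        5.727
#> 3 [20,30)  1  3  1.800 1.797e-01    FALSE   1.00000       pass           NA
#> 4 [30,40)  0  5     NA        NA       NA        NA untestable           NA
#> ...
#>   empirical_p empirical_p_raw significant
#> 1    0.003996           0.003        TRUE
#> 2    0.164835           0.164       FALSE
```

Reading the output: in the `<10`-year lifespan bin the observed H (64.0) far
exceeds the phylogenetic null's 95th percentile (53.1 — an order of
magnitude above the χ²(1) quantile 3.84, which is how much shared ancestry
inflates H here), so the planted clade effect is recovered with empirical
p ≈ 0.004.  In `[10,20)` the observed H exactly *ties* the threshold and is
conservatively not significant.  Strata lacking a factor level are reported
as untestable rather than silently dropped, and the failed balance check in
`<10` is carried into the record.

The motif scanner, on the consensus's own canonical instance:

```r
scan_motif("TGACTCAGCA", are_consensus())
#>   sequence_id start end strand matched_text
#> 1        <NA>     0  10      +   TGACTCAGCA
```

A shell entry point wrapping the same functions ships in
`inst/cli/pikw.R` (`run` and `synth` subcommands).

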