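---
title: "Rank tests against Brownian nulls: methods and design"
author: "pikw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank tests against Brownian nulls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Comparative questions of the form "do species with trait state X have higher
values of a continuous trait Y?" cannot be answered by treating species as
independent observations: close relatives inherit similar trait values from
common ancestors, so a handful of deep lineages can masquerade as dozens of
independent data points.  The situation `pikw` addresses is the extreme
version of this confound: the grouping factor itself is a single clade.  In
the motivating system, the repressor KEAP1 -- which holds the master
antioxidant transcription factor NRF2 inactive -- is non-functional in one
large clade of birds (Neoaves, roughly 95% of species) and functional in the
basal lineages (Palaeognathae and Galloanserae).  Asking whether
KEAP1-non-functional species have higher mass-specific basal metabolic rate
(MS-BMR = BMR in kJ/h divided by body mass) or longer maximum lifespan is
exactly the worst case for a conventional test: group membership and
phylogeny are perfectly collinear.

## The method

The pipeline is nonparametric by construction, because binned trait data of
this kind are non-normal under any reasonable transformation:

1. **Trait table.**  BMR/mass and maximum-lifespan sources are
   inner-joined on normalized binomial names, MS-BMR is derived as the raw
   ratio, and lifespan records carry AnAge-style quality labels
   (`acceptable`/`high`/`questionable`).  Questionable records are kept by
   default: in the source data they are conservative underestimates, so
   retaining them biases against the effect being tested.
2. **Stratification.**  To compare metabolic rate at equivalent lifespan
   (and vice versa), species are binned on the other trait with
   left-closed, right-open intervals plus open end bins (`<10`, `[10,20)`,
   ..., `>=50` years; MS-BMR edges `2..8`).  Within each bin a two-sided
   Mann-Whitney test checks that the stratifying variable is
   indistinguishable between factor levels; a bin "passes" when p >= 0.05.
   This accept-the-null criterion shows only that no imbalance is
   *detectable* at the available sample size, which is why the balance
   p-values are carried into every report rather than collapsed to a flag.
3. **Screening.**  Each testable stratum gets a conventional tie-corrected
   Kruskal-Wallis test of the response by the 0/1 factor; strata with
   chi-square p < 0.05 proceed to the phylogenetically independent stage.
4. **The PI-KW test.**  The time tree is pruned to exactly the stratum's
   species (preserving every root-to-tip depth), `n_sims` replicate traits
   are simulated under Brownian motion on the pruned tree, and each
   replicate's H is computed against the *real* factor labels.  The
   observed H is then referred to the 95th nearest-rank percentile of this
   empirical null.  Holding the labels fixed and resampling the trait from
   the tree is what makes the null "phylogenetically independent": the null
   distribution automatically widens by exactly the amount that shared
   ancestry could inflate H.

The decision rule is `significant = screened AND observed_H > threshold`,
with strict inequality (a tie with the threshold is not significant).  The
conjunction keeps the published two-stage logic intact and guarantees the
invariant that a significant stratum was also conventionally significant;
it makes the compound test slightly conservative, which the operating
characteristics below bear out.  Both an add-one empirical p-value,
`(1 + #{h >= H}) / (1 + n_sims)`, and the raw proportion are reported,
since either convention appears in practice; the headline decision uses the
percentile threshold, so the choice does not affect it.

## Why the null cannot depend on the Brownian parameters

The simulator draws, per replicate, one standard normal per edge, scales it
by `sqrt(sigma2 * branch_length)`, accumulates down the tree and adds the
root state.  Multiplying by a positive constant and adding a constant are
strictly monotone, so within a replicate the *ranks* of the tip values are
identical for any `sigma2 > 0` and any root state -- and H is a function of
ranks only.  The defaults `sigma2 = 1`, `root_state = 0` are therefore not
modelling assumptions; the test suite asserts bit-identity of the null H
vector across `sigma2` in {1, 100} and root states {0, 10}.  This matters
because the Brownian rate of a real trait is unknown: the construction
makes the question moot.

RNG streams are derived per replicate and per stratum from
`substream_seed(seed, key)`, so replicate r is the same whatever `n_reps`
is, and adding strata never perturbs existing nulls.  Every pipeline output
replays byte-identically from the same seed.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_sims` | 1000 | replicates | study-scale default; >= 100 enforced so the 95th percentile is an interior order statistic |
| percentile | 95 | % of null H | nearest-rank (no interpolation): the 950th order statistic of 1000 |
| `alpha` | 0.05 | — | screening and significance level |
| lifespan edges | 10, 20, 30, 40, 50 | years | the named interval groups of the motivating analysis |
| MS-BMR edges | 2, 3, ..., 8 | kJ h^-1 g^-1 ratio scale | idem; edges are configuration, not code |
| ARE window | 1000 | bp upstream | "~1 kb upstream" convention; truncated, never discarded, at contig edges |
| ARE strands | both | — | the consensus is orientation-independent; forward-only is a flag |

## Degenerate inputs and numerical choices

* All-tied responses make the tie correction vanish; H is defined as 0 with
  a warning ("no evidence against the null" is the correct semantic), and a
  fully tied Mann-Whitney comparison reports p = 1 for the same reason.
* Mann-Whitney p-values are exact (full enumeration) when `n1 + n2 <= 12`
  with no ties -- small strata demand exactness -- and otherwise use the
  tie-adjusted normal approximation with continuity correction.
* Polytomies are resolved deterministically into caterpillars of
  zero-length edges, children ordered by each subtree's smallest tip label.
  Zero-length resolution is the unique choice that leaves every pairwise
  MRCA depth, and hence the Brownian covariance, exactly unchanged; the
  literature-based dates that originally resolved these nodes are data the
  pipeline cannot ship, and the log notes whenever the rule fires.
* Pruning preserves absolute depths by keeping the pruned-away basal stem
  as a `root.edge`; the stem is ancestry shared by *all* retained tips, so
  it shifts whole replicates by a constant and cannot affect ranks -- it is
  carried anyway so that covariance bookkeeping stays exact.
* Ultrametricity is checked (relative spread of tip depths) and warned
  about, never enforced: the null is well defined on any clock tree.

## What the synthetic generator emulates -- and what it does not

`synth_comparative()` builds a pure-birth tree rescaled to a fixed depth
(default 100 time units, the order of the avian crown age in Myr), labels
the internal node closest to a target fraction of tips (default 0.87, the
Neoavian share of the motivating dataset of 206 species) as the level-0
clade, and evolves latent traits by Brownian motion (default rate
`1/depth`, so latent tip SD = 1) with an optional clade shift expressed in
those SD units.  Emitted traits are `exp(latent)` scaled to realistic
centres -- positive, right-skewed, rank-equivalent to the latent values.
Body mass is a power of two and BMR its exact product with MS-BMR, so the
stored ratio is floating-point exact.

The generator reproduces the *statistical structure* of the real analysis
-- a monophyletic binary factor, continuous traits with phylogenetic
signal, interval stratification -- and nothing else.  It does not emulate
avian taxonomy, measured BMR allometry, fossil-calibration uncertainty,
body-mass correlation with either trait, or missing-data patterns.
Passing tests therefore demonstrate that the machinery controls type-I
error and recovers planted effects *under its own model*; they cannot
certify conclusions about any real dataset.

## Operating characteristics the test suite verifies

With study-condition sizes chosen once (200 null datasets of 80 tips at
500 simulations; 100 datasets per power level; a 200-tip star tree; 10,000
replicates for moment checks), the suite verifies that:

* the pooled PI rejection rate on null data sits inside the binomial 99%
  band around the nominal 5%, while the conventional KW test on the same
  data rejects several times too often -- the inflation the method exists
  to remove;
* power is monotone over clade shifts {0, 0.5, 1, 2} latent SD and reaches
  at least 95% at a 3-SD shift.  A 2-SD shift is *not* reliably detected
  (power is near two thirds): a shift of that size is within the range of
  clade-level drift that Brownian evolution itself generates, so the null
  correctly absorbs much of it.  This ceiling is a property of the test,
  not an implementation artifact, and more species do not remove it --
  clade-level drift does not average out;
* on a star tree (no phylogenetic structure) the empirical threshold
  collapses to the chi-square(1) 0.95 quantile and to a label-permutation
  threshold, as it must where tips are exchangeable;
* the simulator's full tip covariance matches `sigma2 x` shared-path
  lengths entrywise at Monte-Carlo precision, cross-checked against an
  independent Brownian implementation, and the ARE scanner equals a
  brute-force 64-expansion oracle exactly while recovering 100% of planted
  motifs.

## The ARE scanner

The antioxidant response element consensus `TGASWMAKCN` (degeneracy 64) is
matched per position over IUPAC sets on both strands of the ~1 kb window
upstream of each locus (BED 0-based half-open coordinates throughout,
strand-aware: minus-strand windows are taken downstream of the interval end
and reverse-complemented).  An unknown base `N` in the genome matches only
pattern positions that accept any base -- an unknown base cannot be
credited against a constrained position.  Zero-hit loci stay in the output:
the *absence* of an ARE upstream of a gene is a finding, not missing data.
Which annotation anchor the window is measured from (TSS vs. CDS start) is
delegated to the supplied BED intervals, and no attempt is made to model
binding affinity: this is presence/absence scanning, not a PWM.

## Known limitations

* The Brownian model is the only null offered; Ornstein-Uhlenbeck, bounded
  or trending alternatives are out of scope by design.
* The balance check inherits the usual weakness of accept-the-null
  reasoning; strata failing it are reported and analysed, with exclusion
  left to the caller.
* Empirical p-values from 1000 simulations have a resolution floor of
  about 0.001 (add-one); claims below that require more simulations.
* Real bin edges and species lists of the motivating study are not
  shipped; edges are configuration, and reconstructed defaults follow the
  interval groups named in its text.
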