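---
title: "Methods: transgressive segregation, morphometrics and QTL mapping in an F2 cichlid cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transgressive segregation, morphometrics and QTL mapping in an F2 cichlid cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study system and what the package computes

Two generalist Lake Malawi cichlids — *Astatotilapia calliptera* ("CAL")
and *Protomelas taeniolatus* ("TAE") — were crossed to the F2 generation,
and the hybrids were assayed for a behaviour neither parent specializes
in: sifting sand for food. The package implements the three analysis arms
of that design as reusable, tested functions:

1. **Behaviour** — quantify turned-over sand from before/after photographs
   of a two-layer (beige-over-black) sand tray, correct for body scraping,
   divide by strike count to obtain an efficiency score, and test for
   transgressive segregation.
2. **Morphometrics** — 13-landmark geometric morphometrics (generalized
   Procrustes analysis with sliding semilandmarks), linear head distances,
   mouth angle, allometric size correction and shape PCA, with
   transgression per axis and projection of external specimens.
3. **Genetics** — hard-filter RADseq variants, select reciprocally fixed
   parental markers, build a Kosambi linkage map, and run single-QTL EM
   interval mapping with genome-wide permutation thresholds, Bayesian
   credible intervals and percent variance explained (PVE).

A synthetic-data module (`simulate_*`) generates crosses, phenotypes,
landmarks, sand images and VCFs with the statistical structure these
analyses assume, so the full pipeline can be exercised and validated
without the original field data. The numbered scripts under `analysis/`
run the three arms end to end on such data and write their tables under
`results/`.

# Transgression statistics

Transgression is assessed two ways. The *classical* criterion flags F2
values outside the pooled parental min–max range. The *conservative*
thresholds are the higher parental mean plus two standard deviations of
that parent (upper) and the lower parental mean minus two SDs of that
parent (lower). We use the extreme parent's **own** sample SD (n−1
denominator): the sentence structure of the published definition ties the
SD to the parent contributing the extreme mean, and small parental samples
then widen the thresholds appropriately. Ties at a threshold are not
transgressive (strict inequality). Under a null in which parents and F2
all come from the same normal distribution, the expected transgressive
fraction tends to `2 * pnorm(-2)` ≈ 4.55% — the acceptance suite verifies
this, and it is the benchmark against which elevated transgression under a
complementary (mixed-sign) QTL architecture is judged.

Class mean differences use a two-sided two-sample permutation test on the
difference in means: full enumeration of all `choose(n1+n2, n1)`
relabelings when that count is at most 10^6, otherwise Monte-Carlo with
the add-one estimator `p = (1 + #{|T*| >= |T|}) / (B + 1)`, which cannot
return zero.

# Behaviour scoring

Sand images are single-channel brightness matrices on the 0–255 scale;
colour is unnecessary because the published analysis reduces to a
brightness cut at 80. `quantify_sand_area()` reports the percentage of
pixels at or below the threshold. The before-trial percentage is
subtracted first, floored at zero, and the result multiplied by `(1 − e)`
where `e ∈ {0, 0.1, 0.25, 0.5, 0.75, 0.9}` is the scored fraction of
blackened area attributable to scraping. The source describes this as
multiplying by the "inverse value" of the scrape effect without defining
it; we read it as the complement, because multiplying by `1/e` would
inflate rather than remove the scraping contribution. The alternative
reading can be disabled via `scrape_mode = "off"`.

Efficiency is `area% / strikes + 0.001`; the offset keeps zero-area trials
log-transformable, and trials without a strike are marked not-computable
rather than zero (they still enter strike-count analyses). Trials with
zero strikes **and** a hiding or interaction score of 5 are excluded
outright. Female trials are scored per group of three shoaling fish:
strikes are summed across the group, and group SL is the member mean.
Latency and scraping counts are carried in the data model but drive no
statistic.

# Geometric morphometrics

Landmarks use ids 1–7, 10–15, with 11–14 as semilandmarks equally spaced
on the dorsal profile between the snout tip (10) and the dorsal head
margin (15). The y axis increases upward; TPS files digitized image-down
can be flipped on read (`flip_y`). Because preserved specimens differ in
jaw opening, landmark 4 is first rotated about the jaw hinge (3) so the
jaw–maxilla angle equals the cross-specimen mean; jaw length is preserved
exactly.

GPA centres each configuration, scales to unit centroid size, and rotates
optimally to the consensus, iterating the consensus to a squared-change
tolerance of 1e−10 (partial Procrustes; reflections disallowed). With
sliding enabled, each converged superimposition is followed by one
Gauss–Seidel pass per specimen in which each semilandmark moves along its
local curve tangent (estimated from its chain neighbours) to the exact
scalar minimiser of thin-plate-spline bending energy against the
consensus; the superimposition is then repeated, for at most five outer
iterations. Exact line minimization guarantees the bending energy of a
pass never increases, which the tests assert.

Allometry is removed by regressing every aligned coordinate on log10
standard length and adding the residuals back to the consensus. The
shape–size association is summarized by a Goodall-style F with a
permutation p value (999 permutations by default — the original analysis
reports the F but not its permutation count, so we chose a conventional
value and fixed it). Slope homogeneity between classes is tested by
residual randomization under the common-slope model; pooled correction is
used when homogeneity holds, class-wise otherwise (museum-type external
specimens with different allometry get their own regression via
`groups`).

Shape PCA signs follow a deterministic convention (largest-magnitude
loading positive); published axis orientations are arbitrary, so
comparisons are made up to sign. Scores are taken about the unit-size
consensus rather than the column mean — the two differ by a constant of
order 1e−5 — so that projecting the consensus yields exactly zero and
projecting an in-space specimen reproduces its scores exactly.
`project_shapes()` aligns new configurations to the consensus by ordinary
Procrustes (no consensus update, no sliding), matching predict-style
semantics.

# Variant filtering and the linkage map

`filter_variants()` applies, in order: site quality ≥ 30; genotype masking
at GQ < 30 or DP < 10; removal of indels, sites within 10 bp of an indel
start (inclusive), multiallelic and (post-masking) monomorphic sites;
sites with > 50% missing genotypes; mean genotype depth > 88 (paralog
enrichment); minor allele count ≤ 2; and thinning to one site per 200 bp,
keeping the lowest-position site of a cluster. A site failing several
rules is attributed to the first failing rule, making the report
reproducible and the counts sum exactly to the input. Whether the
published pipeline masked genotypes before or after the missingness filter
is not stated; masking-first is our declared choice. Individuals with mean
depth < 20 or > 50% missing data are dropped.

Reciprocally fixed markers stand in for the unavailable grandparents: all
non-missing panel-A genotypes homozygous for one allele, panel-B for the
other, with at most 3 of 6 (A) and 2 of 5 (B) missing. F2 genotypes are
recoded by counting parent-A alleles.

Pre-mapping QC drops markers with segregation-distortion χ² p < .01
against 1:2:1, > 20% missing data, then individuals with > 30% missing.
Grouping uses the likelihood-ratio G statistic of independence on the
3×3 genotype table, scaled to `LOD = G / (2 ln 10)`, with single-linkage
closure at LOD ≥ 7. Recombination fractions come from an EM estimator for
codominant F2 markers (the double-heterozygote class mixes parental and
recombinant gamete pairs), clamped at 0.4999 so Kosambi distances stay
finite. Positions accumulate adjacent-pair Kosambi distances. The
commercial mapping software's proprietary regression ordering, ripple,
"SCL" and nearest-neighbour-fit exclusions are deliberately not
reimplemented: ordering is either the known (simulated) order or a greedy
nearest-neighbour seriation, and the chosen mode is recorded in the map
object.

# QTL mapping

`calc_genoprob()` runs a forward–backward HMM per individual and linkage
group on a grid of marker positions plus pseudomarkers every 1 cM
(anchored at the group's first marker). Transitions come from the mapping
function's recombination fraction per interval, with the F2 transition
matrix assembled from two independent meioses (autosomal model only);
emissions are `1 − ε` for the observed genotype and `ε/2` otherwise
(ε = 0.05 by default), uniform for missing observations. The tests verify
the forward–backward recursion against exhaustive hidden-path enumeration
on short chains to 1e−10.

`scan_em()` fits, at each grid position, a three-component normal mixture
whose weights are the genotype probabilities, by EM (initialized from the
marginal phenotype mean and MLE SD; convergence |Δlog-lik| < 1e−8, at most
1,000 iterations), and reports `LOD = log10(L_alt/L_null)` against the
covariate-only null. Additive covariates shift all genotype means by a
common effect; interactive covariates give each genotype class its own
covariate effect, while the null always retains only the covariate main
effect (standard scan semantics). At a fully typed marker with ε → 0 the
scan collapses to `(n/2)·log10(RSS0/RSS1)` from the genotype-means
regression, which the tests assert to 1e−6. The EM core is compiled
(RcppArmadillo) because permutation thresholds re-run the genome scan
hundreds of times.

`scan_np()` extends the Kruskal–Wallis statistic to probabilistic
genotypes via probability-weighted rank sums (with the usual tie
correction), reported as `statistic / (2 ln 10)`; it ignores covariates,
as in the tool family it mirrors. Genome-wide thresholds permute the
phenotype (covariate rows travelling with it) and take empirical
`1 − α` quantiles of the per-permutation maximum LOD at α = .05 and .10;
the genome-wide p of a peak is `(1 + #{max* ≥ peak})/(B + 1)`. Bayesian
credible intervals normalize `10^LOD` over the peak's linkage group, take
the smallest contiguous set of grid positions containing the peak with
≥ 95% posterior mass, and widen the endpoints to the nearest flanking
genotyped markers. `pve()` is `100·(1 − 10^(−2·LOD/n))` with `n` the
number of phenotyped individuals in that scan (e.g. only the behavioural
males for strike counts).

# The synthetic-data generator

Gametes are simulated as a Markov chain along each chromosome: the allele
at the first marker is Bernoulli(1/2) and switches between adjacent
markers with probability `r(d)` from the inverse of the selected mapping
function. This honours the map function's adjacent-marker recombination
fractions exactly — which is what the mapping stages consume — without
modelling crossover interference; consequently, recombination between
*distant* marker pairs follows the Markov composition of the adjacent
fractions rather than the Kosambi value for the total distance, a known
and accepted simplification (map-length recovery is tested on dense maps
where the discrepancy is negligible). Parental panels are fully inbred
lines. Phenotypes follow `a·x + d·(1 − |x|)` per QTL (x ∈ {−1, 0, 1}) plus
optional pairwise epistasis and Normal(0, σ) noise; a complementary
architecture (mixed-sign `a`) makes both parental means equal while the
F2 segregates transgressively. Family structure is a single homogeneous
F2 — the published analyses pool families throughout.

Sand images are granular single-channel brightness fields: a beige
background (mean 190, SD 18) with dark disk-shaped patches (mean 35,
SD 12) added until the repainted fraction is as close to the target as
patch packing allows; the realized fraction is returned exactly as
repainted pixels over total pixels. Landmark specimens are class means
plus `(logSL − mean)·allometry` plus isotropic noise, then randomly
rotated, translated and scaled. What the generator does **not** emulate:
lighting gradients and shadows in real photographs, digitization error
correlated across landmarks, genotyping error correlated with depth, and
real linkage-disequilibrium structure — so passing tests demonstrate
correctness of the computations, not robustness to every artefact of real
field data.

# Numerical choices and problem sizes

- GPA convergence 1e−10 (squared consensus change), 200 iteration cap; a
  degenerate (all-coincident) configuration is an error.
- EM: tol 1e−8 on the log-likelihood, 1,000 iterations; recombination EM
  clamped to [0, 0.4999]; near-singular M-step systems fall back to a
  pseudoinverse.
- Permutation p values use the add-one estimator throughout.
- FDR adjustment is Benjamini–Hochberg.
- 200-bp thinning and first-failing-rule attribution are deterministic
  tie-breaks chosen for reproducibility.
- The validation suites use desk-scale study conditions chosen a priori:
  QTL-recovery replicates use n = 200 F2 on three 100-cM chromosomes with
  markers every 10 cM, a 5-cM scan grid, an additive QTL sized to 25% PVE
  (`a = sqrt(2/3)`, σ = 1) and B = 200 permutations over 100 replicates;
  null calibration uses 200 crosses of n = 100 on two such chromosomes.
  The demonstration scripts under `analysis/` use a 22-chromosome genome
  with 220 markers and 113 F2 individuals, mirroring the study's mapping
  panel.

# Known limitations

- Marker ordering is simplified (given or greedy seriation); multipoint
  maximum-likelihood ordering is out of scope, so simulated true orders
  are used where available and the ordering mode is reported.
- The nonparametric scan supports no covariates.
- Single-QTL scans only: no multiple-QTL or epistasis scans.
- X-chromosome inheritance is not modelled (autosomal F2 only).
- Sliding semilandmarks use tangent estimates from chain neighbours; with
  very sparse or highly curved profiles a spline-based tangent would be
  more faithful.
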