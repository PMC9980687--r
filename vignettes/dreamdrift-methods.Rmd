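---
title: "Methods: restriction-signature methylation quantification and drift analysis"
author: "dreamdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction-signature methylation quantification and drift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

DREAM (Digital Restriction Enzyme Analysis of Methylation) quantifies
CpG methylation at CCCGGG sites by sequential digestion with two
isoschizomers: SmaI cuts bluntly but is blocked by CpG methylation,
XmaI cuts the same site regardless of methylation but leaves a
staggered end. After sequencing, a read whose 5' end begins `GGG`
records an unmethylated site (SmaI signature) and a read beginning
`CCGGG` records a methylated one (XmaI signature). With $X$ methylated
and $S$ unmethylated reads at a site, the methylation estimate is

$$
\mathrm{meth} \;=\; 100 \cdot
\frac{c\,(X + 0.5)}{c\,(X + 0.5) + S + 0.5},
$$

where $c$ is a per-sample correction factor for digestion efficiency
($c = 1$ means no correction). The 0.5 pseudocounts keep estimates
strictly inside $(0, 100)$ and regularise low-coverage cells. The
formula is antisymmetric under $(X, S, c) \to (S, X, 1/c)$, reflected
about 50% — a property the test suite checks to $10^{-9}$.

## Spike-in calibration

Each library carries nine spike-in standards of known methylation
(defaults 0, 12.5, ..., 100%). `estimateCorrectionFactor()` chooses
$c$ to minimise the sum of squared differences between the calibrated
estimates at the standards and their known levels, searching
$\log c \in [\log 0.05, \log 20]$ with bounded 1-D minimisation. Least
squares on the percent scale over all nine standards is the simplest
symmetric estimator, and in simulation it is exactly invertible (see
below). Samples are accepted only when $\hat c \in [0.5, 2.0]$;
outside that band the digestion is considered too aberrant to correct
and the sample is dropped from the matrix with a logged reason. At the
default spike depth of 10,000 reads the estimator recovers
efficiencies across the acceptance band to within 0.05 in well over
95% of replicates.

## Filtering

`filterSites()` retains autosomal sites (chr1–chr19 by default; the
list is configurable) with at least `minDepth` reads in at least
`ceiling(minFraction * group size)` samples of *every* group under
comparison; defaults are 100 reads and 75%. Two conventions needed
fixing:

* **Depth boundary.** We treat the 100-read requirement as inclusive
  (depth = 100 passes); the flag is configurable for a strict reading.
* **Group-aware application.** The 75% rule is applied per comparison
  group rather than to the pooled cohort, so each pairwise comparison
  has its own "detectable sites" denominator; comparison-specific
  filtering is obtained by subsetting the `DreamSet` to the two groups
  and refiltering.

Cells that survive site-level filtering but individually sit below the
depth threshold are masked (`NA`) rather than imputed, and all
downstream statistics use row deletion.

# Differential methylation

## Pairwise volcano calls

`diffTest()` computes, per site, the difference in mean methylation
(exposed minus reference) and a two-sided p-value from the
equal-variance Student t statistic — the equal-variance form is
deliberate, matching the assay's original analysis convention, and an
independently coded `t.test(var.equal = TRUE)` oracle agrees to
$10^{-10}$. A site is *changed* when $p \le 0.05$ **and**
$|\Delta| \ge 5$ percentage points (`callChanged()`). No
multiple-testing correction is applied at this stage — only the
multivariate model below is FDR-corrected — so pairwise percentages
should be read as descriptive volcano summaries, not FDR-controlled
discoveries. Degenerate sites follow documented conventions: zero
pooled variance with equal means gives $p = 1$, with unequal means
$p = 0$; sites with fewer than two unmasked values in either group
drop out of the denominator.

## Compartment summaries

Sites are stratified two ways: by CGI class — *island* (hexamer start
inside a CGI interval), *shore* (within 2,000 bp of an island edge,
inclusive, measured start-base to nearest island base), *other* — and
by baseline compartment in a reference group: *low* (< 20%), *high*
(> 80%), *mid* otherwise, with both boundaries assigned to *mid*.
`compartmentSummary()` reports proportions over all analysed sites and
separately over island sites only (the two bar-chart conventions).

## Power

`sitePower()` gives the two-sided two-sample t-test power from the
noncentral t distribution with noncentrality
$|\Delta| / (\sigma\sqrt{2/n})$ and $2n - 2$ degrees of freedom;
`powerReport()` averages it over sites whose observed difference
exceeds 5 points, the design-adequacy summary used for the small
(3 vs 3) ageing comparison. A 100,000-replicate Monte-Carlo oracle
agrees within 0.01 at $(\Delta = 10, \sigma = 4, n = 3)$. On the
synthetic study the ageing design's average power is about 0.67 at the
generator's default noise; the corresponding animal experiment reports
0.90, which our generator does not reproduce because its per-site
variance model (binomial counting noise plus 2-point mouse-level
jitter) is deliberately simple.

# The factor model

For the 42 adult mice, `fitFactorModel()` fits per site

$$
y = b_m x_m + b_i x_i + b_a x_a + b_0 + \varepsilon,
$$

with binary covariates for microbiota, Il10 knockout and AOM. Because
the covariates are binary, each slope is directly the
percent-methylation change attributed to that exposure. Age class is
*not* a covariate: the ageing animals are a different strain analysed
separately through the pairwise route. Sites are batched by
missingness pattern and solved by QR for speed; an independent
pseudoinverse + t oracle agrees to $10^{-8}$. A site needs at least
$p + 2 = 6$ unmasked observations and a full-rank reduced design, else
it is skipped with a counted reason. Per-coefficient p-values are
Benjamini–Hochberg adjusted *separately per coefficient* across sites
(`fdrAdjust()` wraps `stats::p.adjust`), the reading consistent with
per-exposure volcano displays; `callFactorChanges()` defaults to
FDR-only calls ($q \le 0.05$) with an optional slope floor, since it
is not documented whether the original percentages used one — both
modes are provided.

# Overlap, drift and cancer concordance

* `overlapSets()` computes exact intersection-pattern counts (UpSet
  semantics: elements in exactly that combination) for any family of
  site or gene sets, plus pairwise shared fractions
  $|A \cap B| / |A|$.
* `driftScatter()` restricts to sites significantly changed with age
  ($|\Delta_{age}| \ge 5$ and $p \le 0.05$ — we apply the joint rule
  for consistency with every other call, with `alpha = 1` available to
  relax it to magnitude-only) and reports Pearson r, its p-value and
  the OLS slope of exposure change on age change.
* `enrichmentOR()` forms the 2×2 table of a gene universe by
  factor-changed and cancer-changed membership and reports
  OR $= ad/bc$ with a Woolf (log) 95% CI — chosen because a
  continuity-corrected estimator could never produce the degenerate
  OR 0 with CI [0, 0] that a zero overlap cell must yield. The
  p-value behind the family-wise BH q is a two-sided Fisher exact
  test. The universe is the matched gene set (genes measured on both
  the mouse and the cancer side), not all genes.
* Gene matching (`mapPromoters()` + `geneConcordance()`) uses the
  −1500..+500 TSS window (strand-oriented, endpoints inclusive; the
  symmetric ±1500 window is available for pathway-style promoter
  calling), takes the member site closest to the TSS (ties toward the
  lower coordinate), and converts tumour-minus-normal β differences to
  percentage points (×100). Thresholded sets use 5 points on both
  sides.

Coordinates are BED-convention 0-based half-open on disk, 1-based
closed in `GRanges` internally; site ids are `chrom:start` with
0-based starts.

# The synthetic study generator

`simulateDreamData()` produces a complete study with known truth so
every stage is testable end to end. Its defaults are the package's
fixed study conditions:

* **Census.** 22,000 CCCGGG sites — on the order of the detectable
  (≥ 100 reads) site count of a real colonic DREAM experiment — on 19
  autosomes plus 3% on chrX to exercise the autosome filter.
* **Classes and baselines.** island 25%, shore 15%, other 60%
  (detectable sites are CG-rich-enriched relative to the genome-wide
  census); baseline methylation fractions are Beta-distributed per
  class: island Beta(0.8, 15) (mostly unmethylated), shore Beta(2, 5)
  (low–intermediate), other Beta(5, 2) (intermediate–high).
* **Design.** Seven exposure groups of six mice crossing
  germ-free/SPF, Il10 genotype and AOM, plus young (n = 3) and old
  (n = 3) ageing groups.
* **Effects.** Additive ±10-point shifts (8 for island hyper rows) at
  per-factor, per-class fractions mirroring the direction and relative
  scale of colonic exposure studies: microbiota and Il10 loss each
  touch a few percent of open-sea sites, AOM is predominantly
  hypomethylating, ageing both loses methylation globally and gains it
  at islands and shores.
* **Shared susceptibility.** A small loss-prone and gain-prone pool
  (2% of sites each) receives 80% of every factor's effect budget in
  its direction, so exposures and ageing converge on partly shared
  sites — the structure behind overlap fractions and positive drift
  correlations in real colonic mucosa. Setting `labileFraction = 0`
  makes factor effects independent.
* **Counts.** Read depth is negative binomial (mean 300, size 5), so
  the ≥ 100-read filter removes a realistic minority of cells; mouse
  identity adds truncated Gaussian jitter (sd 2 points) to the group
  truth; the methylated read count is binomial with success
  probability $p' = m / (m + c_{true}(1 - m))$ — the exact inverse of
  the correction formula, so quantifying with the true $c$ is unbiased
  for the planted truth. Spike-ins are drawn identically at the nine
  known levels with fixed depth 10,000. Digestion efficiencies are
  log-uniform in [0.7, 1.4] unless supplied.
* **Determinism.** One seed fans out to fixed per-stage substreams;
  identical configurations give identical outputs byte for byte.

What the generator does *not* emulate: strain differences, spatially
correlated (regional) methylation, overdispersed biological variance
beyond the single jitter term, copy-number or mapping artefacts, and
any sequence-level read structure (no FASTQ emission). Passing tests
therefore demonstrate correctness of the statistics under the stated
measurement model, not robustness to every artefact of real
sequencing data.

# Problem sizes and numerical choices

The shipped tests run the generator at 200–10,000 sites and the
oracle comparisons at 1,000 sites; the acceptance script runs the full
default study (22,000 sites, 48 samples) in well under a minute on a
single core — sizes chosen so the whole suite iterates comfortably on
a laptop. Other conventions: calibration needs at least two standards
at distinct expected levels (otherwise unidentifiable); BH adjustment
is order-invariant and idempotent; empty read input yields an empty
count table rather than an error; malformed read records are skipped
and counted.

# Known limitations

Pairwise percentages are not FDR-controlled (by design); the linear
model assumes additive, homoscedastic effects on the percent scale,
which compresses near the 0/100 boundaries; clipping of truth at
[0, 100] slightly attenuates planted effects at extreme baselines; and
the synthetic cancer β-difference table used in examples is a labelled
stand-in, not TCGA data.
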