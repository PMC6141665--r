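---
title: "Quantifying perisynaptic glycogen from volume-EM annotations: models and methods"
author: "glycoPAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perisynaptic glycogen from volume-EM annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPAP)
```

# The measurement problem

Astrocytes store glucose as glycogen granules, and a disproportionate
share of those granules sits in the thin perisynaptic astrocytic
processes (PAPs) that wrap cortical synapses. Serial block-face
scanning electron microscopy (SBF-SEM) makes it possible to annotate,
synapse by synapse, every granule in the astrocytic compartment of a
small cuboid region of interest (ROI) drawn around the synapse: each
granule as a ball (center + diameter, in nm), the axon-spine interface
(ASI) as a triangulated surface, the astrocytic volume inside the ROI,
and presence flags for spine-head smooth endoplasmic reticulum (SER)
and a presynaptic mitochondrion.

glycoPAP takes such annotation tables — not raw images — and computes
the derived quantities used to compare experimental conditions:

* **normalized granule density**: granule count divided by the
  astrocytic volume within the ROI (granules per µm³ of astrocyte);
* **granule diameter** (nm) and the **estimated glucose residues** per
  granule;
* **granule-to-ASI distance**, with a 500 nm inclusion window and
  per-ROI averaging;
* **astrocytic coverage** of the ASI perimeter;
* non-parametric comparisons of all of these across four
  behavioural-state conditions — sleep (S), spontaneous wake (W), acute
  sleep deprivation (SD) and chronic sleep restriction (CSR) — using
  tie-corrected Kruskal–Wallis tests, Dunn's post hoc comparisons and
  Spearman correlations.

Because the underlying EM annotations of such studies are rarely
deposited, the package also ships a seeded synthetic-study generator
that emulates the study structure and its published per-condition
summary statistics, so the full pipeline is exercised end to end by the
test suite without any external data.

# Models and definitions

## Glucose residues per granule

Glycogen particles grow in concentric tiers of thickness
$L \approx 1.9$ nm; chains branch with degree $b = 2$ from tier to
tier and carry on average $c = 13$ glucose residues each. A granule of
diameter $d$ then stores approximately

$$\mathrm{GR}(d) = c\,\bigl(b^{\,d/(2L)} - 1\bigr)$$

glucose residues. `glucoseResidues()` implements exactly this closed
form; `grParams()` exposes $c$, $b$ and $L$ as parameters, with $L$
frozen at exactly 1.9 nm by default. Two consequences matter in
practice:

* $\mathrm{GR}$ is reported as a real number, never rounded: granule-level
  values enter condition averages unrounded, which is the only way
  published mean GR values in the thousands can arise from diameters
  around 27 nm.
* $\mathrm{GR}$ is convex in $d$, so a condition's mean GR depends on the whole
  diameter distribution, not just its mean (Jensen gap). Published mean
  GR values are therefore only approximately recoverable from published
  diameter means; the acceptance suite demonstrates this by recovering
  the sleep-condition GR mean to within 15% under a truncated-normal
  diameter model, while making no claim for the other conditions.

## Granule-to-synapse distance

The distance of a granule from the synapse is defined as the Euclidean
distance from the granule ball to the **nearest vertex of the ASI
mesh's unique-vertex set** — deliberately *not* the nearest point on a
triangle face, which mirrors how such distances are computed on
ball-and-mesh annotations in practice. Duplicate vertices are merged on
import so "nearest vertex" is well defined. Two modes are exposed,
because annotation tools anchor a ball at its center but the granule
surface is arguably the physically relevant boundary:

* `center` (default): distance from the ball center;
* `surface`: center distance minus the radius, floored at zero.

All distance-based acceptance properties are defined for `center`
mode. Granules farther than the inclusion window (default 500 nm,
boundary inclusive) from the ASI are excluded from distance analyses;
distances are then averaged within each ROI, and a ROI with no granule
inside the window has an undefined mean and is dropped from distance
statistics rather than imputed.

## Astrocytic coverage

The ASI boundary is an ordered closed polyline over mesh vertices, each
segment carrying a PAP-contact label produced upstream by segmentation
(the package never infers contact from geometry). Coverage is the
contacted fraction of the perimeter *length* — robust to uneven segment
lengths, and invariant to the traversal direction and starting vertex.

## Rank statistics

The statistical battery is implemented from the defining formulas on
mid-ranks:

* Kruskal–Wallis $H$ with the tie correction
  $H_c = H \big/ \bigl(1 - \sum_j (t_j^3 - t_j)/(N^3 - N)\bigr)$ and a
  $\chi^2_{k-1}$ upper-tail p-value. The $\chi^2$ approximation is
  appropriate at this package's intended group sizes (hundreds of ROIs
  or thousands of granules); no exact small-sample tables are provided.
* Dunn's pairwise $z$ with the matching tie-corrected variance; the
  family-wise adjustment defaults to Bonferroni over all
  $k(k-1)/2$ pairs, with Šidák and no adjustment selectable — the
  adjustment used is recorded in every output row, since published
  analyses rarely state it.
* Spearman's $\rho$ as the Pearson correlation of mid-ranks, p-value
  from the $t$ approximation on $n-2$ degrees of freedom.

All tests are two-sided. When every observation is identical the
omnibus statistic is defined as 0 with $p = 1$. Degenerate
correlations (constant margins) raise an error rather than returning a
value; the pipeline skips such correlation rows. Base R's
`kruskal.test()` and `cor.test()` are used in the test suite as
independent cross-checks of the same quantities, never as the
implementation.

## The analysis pipeline

`runFullAnalysis()` reproduces the full analysis battery in a fixed
order: ROI-volume comparability; density (summaries, omnibus, post
hoc); per-condition Spearman of log2 density vs ASI area; density
stratified by SER and by mitochondrion (between conditions within each
flag level, and flag-positive vs flag-negative within each condition,
the latter as a two-group Dunn test, which is equivalent to a
tie-corrected rank test); diameter and GR at granule grain; per-ROI
mean distances; granule-level diameter-vs-distance correlations in S
and CSR; and ROI-level coverage-vs-distance correlations in S and CSR.
Condition order is fixed to S, W, SD, CSR (increasing wake duration)
in every output.

Two design points were genuinely open and are fixed as follows:

* the density-vs-ASI correlation uses log2-transformed density (as the
  corresponding published panel does); ROIs with zero granules are then
  excluded from that correlation — the transform forces this — and
  their count is reported in the `n_excluded` column;
* with `skipMissingGeometry = TRUE`, a ROI whose mesh is missing fails
  only the distance/coverage stages (the ROI is dropped there and named
  in the report metadata); density/diameter/GR stages still cover it.
  By default a missing mesh aborts the run with an error naming the
  ROI, and no partial outputs are written.

# The synthetic-study generator

`generateStudy()` produces datasets with the schema of a real
annotation study and per-condition summary statistics calibrated to the
published values that `defaultStudyConfig()` encodes: ROI counts
308/268/339/339 (S/W/SD/CSR), density means 103.6/116.3/125.7/123.1 per
µm³ (SEM 5.4/5.2/3.8/4.7), diameter means 27.2/27.1/26.9/26.3 nm (SEM
0.1), per-ROI mean distances 357.2/368.7/366.5/334.9 nm (SEM
6.9/7.6/6.9/6.1), SER prevalences 57.5/35.9/47.2/48.6%, mitochondrion
prevalences 69.5/66.1/67.7/59.9%, and granule counts
3,248/3,718/5,399/4,289 backing the diameter SEMs. Population SDs are
derived as $\mathrm{SD} = \mathrm{SEM}\sqrt{n}$ with $n$ the ROI count
for ROI-level variables and the granule count for diameters.

Distributional choices, where the study conditions leave them open:

* **ROI geometry**: cuboid edges uniform in [2000, 4000] nm; astrocytic
  volume a uniform fraction in [0.05, 0.15] of the ROI volume. With the
  configured densities these fractions put a few hundred granules in a
  typical ROI — more than the published per-ROI totals, which would
  need astrocytic volumes around 0.1 µm³; the published totals still
  enter through the SEM-to-SD conversion, and no acceptance property
  depends on per-ROI counts. ROI-level summary recovery is unaffected.
* **Density / counts**: each ROI draws a density target $\lambda_i$
  from a gamma distribution with the configured mean and SD (gamma
  because densities are positive and strongly overdispersed:
  SD $\approx$ mean here), and the granule count is
  $\mathrm{round}(\lambda_i \cdot v_i^{\mathrm{astro}})$. Deterministic
  rounding (rather than Poisson mixing) keeps the realized density's
  mean and SD exactly at their targets and makes the zero-SD limit
  collapse to the mean exactly, up to integer rounding.
* **Diameters**: truncated normal at zero by default (the truncation is
  ~4.7 SD from the mean, so negligible), with a lognormal alternative
  selectable in the configuration; the truncated-normal location is
  moment-matched so the post-truncation mean is the target.
* **Distances**: each ROI gets a location $m_i$ from a normal truncated
  to (0, 500) nm whose location parameter is moment-matched (by
  univariate root-finding) so that the truncated mean equals the
  configured distance mean; a granule near the ASI draws its distance
  uniformly from $m_i \pm w_i$ with
  $w_i = \min(75, m_i, 500 - m_i)$ nm, a symmetric interval, so the
  per-ROI expected mean is exactly $m_i$. A fraction
  `pNear` = 0.15 of granules is near the ASI; the rest draw distances
  uniformly in [520, 950] nm, outside the window by construction.
* **Placement**: the ASI is a planar triangle-fan disc (32 perimeter
  segments) whose polygon area equals the ROI's ASI area, drawn from a
  truncated lognormal (mean ≈ 0.1 µm²). Each granule sits on the disc
  normal through a randomly chosen mesh vertex at exactly its drawn
  distance, so the pipeline's nearest-vertex computation recovers the
  generated distance bit for bit. This is deliberately stylized: real
  granules scatter through the PAP volume and real ASIs are curved.
  Only distances, not positions, feed the downstream statistics.
* **Coverage**: per-ROI coverage from a Beta(5, 5) marginal (no
  published coverage summaries exist for these data; a symmetric
  mid-range distribution is a neutral choice), discretised to a
  contiguous contacted arc of the 32 perimeter segments.
* **Correlation targets** are induced with a Gaussian copula
  (`induceRankCorrelation()`): latent Pearson correlation
  $r = 2\sin(\pi\rho/6)$, marginal multisets preserved exactly.
  Density–ASI targets are −0.16 (S), −0.16 (W), −0.1 (SD) and 0 (CSR)
  — the published CSR value ($r = 0.1$ with $p = 0.83$ at $n = 339$) is
  internally inconsistent, and the narrative claim is that the
  correlation disappears, so the generator targets zero and no
  acceptance check uses that pair. Diameter–distance couples
  within-window granules in S (−0.001) and CSR (−0.16);
  coverage–distance couples ROIs in S (−0.07) and CSR (−0.2).
* **Mice**: ROIs are assigned round-robin to 3 mice per condition with
  no mouse-level variance component, matching a pooled-ROI analysis; a
  hierarchical mouse effect is out of scope (see Limitations).
* **Synapse flags** are independent Bernoulli draws at the configured
  prevalences. The generator does *not* induce the within-condition
  flag-by-density differences reported for the sleep condition; the
  stratified machinery is exercised, but its synthetic within-condition
  contrasts are null.

Everything is driven by one `set.seed()` call, so a fixed seed gives a
bit-identical dataset; the seed is recorded in the dataset metadata.

# What the tests do and do not show

The acceptance suite runs the full pipeline on 20 seeded
full-size synthetic studies (~1,254 ROIs and ~390,000 granules each)
and checks that (i) every configured per-condition density, diameter
and distance mean is recovered within 3 configured SEM, and every
copula target within $3/\sqrt{n}$, in at least 19 of 20 seeds per
quantity, and (ii) the qualitative pattern of findings — higher wake
densities with omnibus rejection, diameter means ordered
S > W > SD > CSR, CSR closest granules, negative CSR size–distance and
coverage–distance correlations — reproduces in at least 18 of 20
seeds. Statistical calibration is checked separately: the empirical
type-I error of the implemented Kruskal–Wallis test over 10,000
4 × 80 continuous nulls must sit within 3 Monte-Carlo SE of 0.05.

Passing these tests shows the pipeline is a faithful, calibrated
implementation of the stated computations. It does **not** validate the
generator as a model of real tissue: synthetic granules are spheres on
stylized flat ASIs, margins are parametric stand-ins chosen from
summary statistics, within-condition flag effects and mouse-level
clustering are absent, and diameter distributions beyond mean/SD are
unconstrained — which is precisely why published mean GR values (a
convex functional of that distribution) carry only a soft 15%
tolerance for S and none elsewhere.

# Numerical choices

* Lengths are nm, volumes µm³, areas µm²; the nm³→µm³ factor (1e9)
  is applied in exactly one place (`nm3ToUm3()`), and unit tests pin a
  1000³ nm cube to 1 µm³.
* Nearest-vertex distances use direct coordinate differences, not the
  expanded inner-product form, so they equal an exhaustive per-vertex
  scan exactly.
* The 500 nm window boundary is inclusive (≤).
* Table round-trips print 15 significant digits, which makes
  decimal → binary → decimal reproduction exact and output files
  byte-reproducible.
* Ties in all rank statistics use mid-ranks; tie corrections are exact,
  and without ties the corrected statistics reduce to the uncorrected
  ones.
* Truncated-normal moment matching solves for the location parameter
  with `uniroot` at tolerance 1e-10.

# Problem sizes

The default generator reproduces the full study scale (1,254 ROIs,
~3.9e5 granules); one generate-and-analyze cycle takes a few seconds.
The recovery and reproduction checks use 20 seeds; the type-I-error
calibration uses 10,000 replicates; the permutation cross-check of the
chi-square approximation uses 1e5 sampled permutations at $N = 36$.
These sizes were chosen so that every Monte-Carlo tolerance in the
tests is at least 3 standard errors wide.

# Limitations

* Granules are spheres; eccentricity is not modeled.
* Distance is to the nearest mesh vertex, by definition — not to the
  nearest surface point; no point-to-triangle projection or geodesics.
* No mixed-effects / mouse-level clustering adjustment in the
  statistics, matching the pooled design the pipeline mirrors.
* PAP-contact labels are consumed as inputs, never computed from
  geometry.
* The generator targets first- and second-moment summaries plus rank
  correlations; it does not claim realism beyond that.
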