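---
title: "Shape analysis of the developing brain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape analysis of the developing brain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoshape)
```

neoshape quantifies the *shape* of brain structures — as opposed to their
*size* — from voxelized segmentations, and provides the statistical
machinery that turns regional shape profiles into developmental,
individual-level and genetic inferences. This vignette explains the
models and conventions the package implements, the parameters that
matter, and the design decisions taken where several reasonable choices
existed.

## Fractal dimensionality from voxel masks

For a self-similar object recoverable from $N$ copies of itself scaled
by a factor $x$, the scaling law $N(x) = x^{-D}$ defines the dimension

$$D = -\frac{\log N(x)}{\log x}.$$

A line halved gives $D = 1$, a square $D = 2$, a cube $D = 3$; the Koch
curve ($x = 1/3$, $N = 4$) gives the non-integer
$D = \log 4 / \log 3 \approx 1.26$. `theoretical_dimension()` evaluates
this law exactly.

Empirical masks cannot be downscaled indefinitely — the smallest
observable scale is the voxel — so fractal *dimensionality* (FD) is
estimated by box counting over a finite set of scales: the slope of
$\log N(\varepsilon)$ against $\log(1/\varepsilon)$, with box widths
$\varepsilon = 2^k$ voxels for $k = 0,\dots,4$ by default
(`scale_set()`).

`estimate_fd()` uses a dilation variant of box counting rather than a
single anchored grid: for each $\varepsilon$ the mask is padded by
$\varepsilon - 1$ background voxels on every side and convolved with an
all-ones $\varepsilon^3$ kernel, and
$N(\varepsilon) = |S \oplus B_\varepsilon| / \varepsilon^3$, the number
of strictly positive convolution outputs divided by the kernel volume.
This equals the *mean over all $\varepsilon^3$ grid offsets* of the
classical box count — a sliding-grid count — which removes the
dependence on where the grid happens to be anchored and is therefore
insensitive to object translation. The package realizes the dilation as
three separable binary dilations (a cube is the Minkowski sum of three
orthogonal segments), computed in C++; `box_count_oracle()` is a
deliberately brute-force enumeration kept solely so the test suite can
pin the equivalence exactly (relative agreement to $10^{-9}$ on
randomized masks).

Numerical conventions:

* The ordinary-least-squares fit runs in natural-log space over *all*
  provided scales; no scales are dropped. Finite scales bias the slope
  below the theoretical dimension — the $100^3$ cube measures about
  2.85 rather than 3, and the $100\times100$ plane about 1.90 rather
  than 2 — which is why endpoint checks carry a documented ±0.15
  allowance rather than a tight equality.
* Masks smaller than the largest kernel are allowed with a warning
  (their counts saturate at 1); empty masks are errors.
* FD is invariant to lattice axis permutation, flips and background
  padding (tested to $10^{-12}$), so stored volume orientation does not
  matter.

**Surface convention.** A surface voxel is a foreground voxel with at
least one of its six face-neighbours background, where voxels outside
the lattice count as background. This is the simplest convention under
which a one-voxel-thick plane is *all* surface (SVR = 1). The
surface-to-volume ratio of `morph_metrics()` and the shell of
`hollow()` both use it. The full $100^3$ cube has exactly
$100^3 - 98^3 = 58{,}808$ face-exposed voxels (SVR $0.058808 \approx
0.0588$); the package always reports the exact count.

## The plane-to-cube simulation

The morphological simulation gives FD its geometric interpretation as an
index of space-fillingness. A $100\times100\times1$ plane of foreground
voxels (theoretical FD 2, SVR 1) is seeded in the middle $z$-slice of a
$100^3$ lattice; each iteration draws one surface voxel uniformly and
sets the $5^3$ block centred there to foreground, until the lattice is
full (theoretical FD 3, SVR $\approx 0.0588$). The reverse run starts
from the full cube and removes blocks, with the seed plane protected so
the theoretical endpoint remains reachable. Blocks are clipped at the
lattice bounds, keeping the embedding space fixed — which the FD
interpretation requires. FD and SVR are evaluated at iteration 0, every
`eval_stride` iterations and at the final state; stride 1 reproduces a
per-iteration evaluation, while the desk-scale default used in the
acceptance script (stride 100, one run per direction) yields about 300
evaluation points in roughly ten seconds per run.

Along these trajectories FD and SVR are almost perfectly inversely
coupled (Pearson $r \approx -0.99$ in both directions): the object fills
space exactly as its relative surface collapses.

One practical note: because the outer one-voxel shell of the lattice
borders "outside" and therefore stays in the surface pool permanently,
draws concentrate on it as the object approaches the full cube, and the
last interior holes fill slowly. At the default 30,000-iteration budget
a growth run typically reaches ~95% fill rather than terminating; runs
on smaller lattices (as in the test suite) do terminate and reproduce
the cube's surface metrics exactly. The FD–SVR coupling is insensitive
to this tail.

## Synthetic cohorts

Real neonatal imaging cohorts of this kind are access-restricted, so the
package ships a two-level generator that reproduces the *structure* the
analyses rely on, making every downstream stage testable end to end.

**Voxel phenotypes** (`make_phenotype_mask()`). A "sheet" phenotype — a
constant-thickness surface $z = z_0 + A(a)\sin(\omega x)\sin(\omega y)$
— folds increasingly with a latent age parameter $a \in [0,1]$, raising
its FD; a "block" phenotype — a solid slab with pyramidal indentations
of depth $D(a)$ carved from one face — loses space-fillingness, lowering
FD. These emulate the opposite developmental trends of sheet-like
(cortical grey-matter-like) and block-like (white-matter-like)
compartments. Two geometric details matter and were fixed once after
exploration: the sheet is rasterized with slope-corrected thickness so
its voxel count tracks surface area, and the default fold frequency (8
cycles across a 48-voxel lattice) places fold wavelengths *inside* the
counting scales. With long-wavelength folds, a small amplitude enlarges
the coarse-scale bounding extent before it grows area, and measured FD
dips below the flat baseline — a real property of finite-scale box
counting, not an artifact. With the defaults, FD increases strictly
across the five default age levels.

**Feature cohorts** (`generate_feature_cohort()`). Regional values
follow

$$x_{ij} = \mu_j + \beta_j\,\mathrm{age}_i + s_j\,\mathrm{sex}_i +
g_j\,(L_j^\top \gamma_i) + \epsilon_{ij},$$

with sex coded $\pm 1/2$, age as post-menstrual age at scan centred at
40 weeks, and $\gamma_i$ a latent "genetic" vector shared exactly within
monozygotic pairs and correlated 0.5 within dizygotic pairs — the
standard identity/half-sharing semantics mapped onto a generative model.
Defaults mirror a realistic cohort: 780 subjects, 70 regions, ~11%
twins sharing birth and scan age, a longitudinal fraction with a
6-week follow-up, and a companion "volume-like" channel carrying the
same age structure with weaker genetic loading (so shape is more
individually specific than size, a contrast the twin analyses should —
and do — detect). An optional concave `age_profile` makes change
steeper at younger ages, which the longitudinal change-rate analyses
expect. Preterm "departure" offsets are expressed in units of the
term-group regional s.d. and are *signed by compartment* (positive on
the sheet-like half of regions, negative on the block-like half): a
uniform shift would leave the rank-based departure index untouched, so
a patterned offset is the only faithful way to emulate genuine profile
reordering.

What the generator does **not** emulate: scanner artefacts and motion,
spatially correlated residuals, biophysically realistic folding, or
region-to-region covariance beyond the latent genetic factor. Passing
tests therefore demonstrate the *machinery* is correct and calibrated,
not that real data would yield the same effect sizes.

## Individual comparisons and twin identification

Two scans are compared by the L1 norm (Manhattan distance) between
their regional profiles (`dissimilarity_matrix()`): every region weighs
equally and single-region deviations are not amplified by squaring.
Analyses are restricted to pairs scanned within 1 day of each other
(`age_matched_comparisons()`); twin pairs whose own members were
scanned further apart are excluded.

For each eligible twin pair and both directions, `identify_twins()`
predicts the most similar age-matched candidate to be the twin. A
prediction is correct only when the twin is the strict unique minimum;
ties count against identification (a conservative choice — with
continuous measures ties have measure zero). The rank loss is the
fraction of unrelated candidates at least as similar as the twin, and
the per-prediction chance level is $1/c_i$ with $c_i$ candidates (13
candidates give the familiar $1/13 \approx 7.7\%$). Because $c_i$
varies across predictions, overall chance is estimated by a permutation
null (`permutation_null()`): each prediction's twin receives a uniform
random rank among its candidates, 5,000 times by default, and the
p-value is the proportion of null accuracies at or above the empirical
one ("at or above" keeps the reported p conservative). The null mean
provably equals the mean of $1/c_i$, which the tests assert within
Monte-Carlo error. Twin z-scores use the sample (n−1) standard
deviation of the unrelated dissimilarities; the population variant
differs only by a factor irrelevant at the sizes involved.

## Normative reference and departure

The reference group contains infants both born and scanned within the
full-term window, 39+0 to 40+6 post-menstrual weeks (273–286 days,
configurable). `build_reference()` stores per-region means and sample
s.d.; `norm_z()` standardizes any scan against them, reporting
zero-s.d. regions as unscorable rather than scoring them. The departure
index $d = 1 - \varrho$ uses Spearman's rank correlation (average ranks
for ties) between a scan's profile and the reference means: rank-based,
hence invariant to any strictly monotone transform of the profile, with
$d = 0$ at rank identity, $d = 2$ at reversal, and $d \approx 1$ for
unrelated profiles.

`weekly_change()` reports per-region relative change per week between
two sessions. The "total" change aggregates the *absolute* per-region
rates by default: sheet-like regions gain complexity while block-like
regions lose it, and a signed mean would let the two cancel. Signed
mean and sum remain available as options.

## Bespoke inference

**Half-swap permutation test** (`half_swap_perm_test()`). To compare an
effect between two measures X and Y observed on the same individuals,
both are standardized to a common scale (z-scores, or ranks for
non-parametric statistics; X and Y pooled per column so they share one
scale), and each permutation replaces a random floor(n/2) of X's
observations with Y's corresponding observations — independently per
column for matrix input — before re-evaluating the statistic. The
p-value counts permuted statistics at or above the empirical one. With
odd n, floor(n/2) rows are swapped. The statistic is applied exactly as
supplied; callers who care only about magnitude wrap it in `abs()`.
Simulations in the test suite confirm the nominal type-I error
(0.05 ± 0.02 at 1,000 replicates) and usable power for effects confined
to one measure.

**Williams' test** (`williams_test()`). For H0 "two variables correlate
equally with a third", the package uses the Steiger-modified Williams
t with $n - 3$ degrees of freedom; the exact formula is pinned by an
independently transcribed oracle in the tests. The absolute-effect
variant reflects both correlations to be positive and propagates the
sign flips into $r_{12}$, which is the algebraically consistent way to
compare magnitudes of opposite-signed effects.

**Partial correlation, Fisher z, covariance networks.** Partial
correlation uses the closed form and is verified against residual
regression to $10^{-10}$. Region-by-region covariance networks retain
only off-diagonal correlations at or beyond the upper and lower
percentile (default 1) of the off-diagonal distribution; Fisher's
$z = \operatorname{atanh}(r)$ is exposed for scale harmonization.
Standard tests (Kruskal–Wallis, Dunn, Levene, signed-rank,
Benjamini–Hochberg) are called from base R and car, never re-derived.

## Age prediction

`fit_age_model()` implements a spline → principal components → sparse
regressor pipeline. Every stage is derived from training data only:
per-feature standardization; a natural cubic-spline basis per feature
(smoothing 0, i.e. near least squares; knots at training quantiles; 4
degrees of freedom per feature by default); principal components
retaining 95% of basis variance; and relevance vector regression — an
evidence-maximization sparse Bayesian linear model with per-weight
precision hyperpriors, fixed-point updates, pruning of weights whose
precision diverges past $10^8$, convergence tolerance $10^{-6}$ and a
1,000-iteration cap that warns (rather than errors) when reached.
Multiple linear regression and linear-kernel SVR are available as
control regressors, and the spline and reduction stages can be switched
off, so the claim that performance is insensitive to these internals is
itself testable. The exact ordering and knot policy of the original
toolchain cannot be recovered from its description; the pipeline above
is the package's fixed, documented realization, and all three stages
are config-switchable precisely so that this choice is inspectable.

`cross_validate()` runs seeded k-fold cross-validation (default 10
folds, unstratified, optionally repeated with re-drawn splits),
reporting per-fold MAE $= \mathrm{mean}\,|$predicted − true$|$ and
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ on the held-out fold. Rows must
be one scan per subject; duplicated keys are rejected rather than
silently averaged. The no-leakage property is tested directly:
corrupting a fold's labels leaves that fold's predictions bit-identical.
On cohorts whose features determine age up to Gaussian label noise of
s.d. $\tau$, cross-validated MAE lands at the analytic floor
$\tau\sqrt{2/\pi}$ (tested within ±20%). `compare_models()` pairs
fold-wise metrics between two channels with signed-rank tests and
compares variability with Levene's test.

## Problem sizes and limitations

The test suite runs the full default-geometry simulation only in the
acceptance checks (two runs, ~10 s each); elsewhere it uses 24-voxel
lattices, cohorts of 24–600 subjects and 6–20 regions, and 199–5,000
permutations — sizes chosen so the entire suite completes in about a
minute while keeping every assertion at its stated tolerance.

Known limitations: FD estimates are lattice-based and carry finite-scale
bias (comparisons are meaningful, absolute values are not dimensions);
intensity-based and surface-mesh FD are out of scope; affine headers
are recorded but never used for resampling; the twin machinery assumes
a simple unrelated/DZ/MZ structure (no half-siblings); and the
normative model is a mean/s.d. reference, not a centile growth chart.
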