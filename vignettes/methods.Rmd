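---
title: "Methods: hindcast niche models for fossil validation and assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hindcast niche models for fossil validation and assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleoSDM)
```

## The problem and the model

Fossils of living species carry two kinds of information this package
exploits. A fossil of a *securely identified* species is an out-of-sample
check on a species distribution model (SDM): if a model fitted to the
species' present-day occurrences, projected onto the climate of the
fossil's age, predicts the fossil's location as suitable, the model (and
the paleoclimate layers underneath it) gain credibility. Conversely, for
a fragmentary fossil whose identity is ambiguous among several candidate
species with *distinguishable climatic niches*, the same hindcast logic
can rank the candidates. This is explicitly a comparative aid — a way of
reducing taxonomic uncertainty, not a substitute for morphological
taxonomy — and it rests on the assumption of climatic niche conservatism
over the modelled span.

The decision rule is species-relative. For candidate species $i$ with
fitted suitability model $\hat p_i(\cdot) \in [0,1]$:

* $S_i = \max_k \hat p_i(x_f, k)$, the hindcast suitability at the
  fossil cell $x_f$ over the climate slices $k$ spanned by the fossil's
  calibrated age interval;
* $m_i = \min_{x \in \text{occurrences}_i} \hat p_i(x, 0)$, the minimum
  suitability at the species' occurrence points on the present-day
  (0 kyr) projection;
* the candidate is **plausible** iff $S_i \ge m_i$.

$m_i$ is an occurrence-derived operating point: the species is observed
living at suitability $m_i$, so a past location scoring at least $m_i$
cannot be dismissed on climatic grounds. Plausible candidates are ranked
by $S_i$; the headline is the top-ranked one, or "indeterminate" when no
candidate is plausible or the top two differ by less than a tie
tolerance (default 0.01). Candidates are evaluated independently, so
adding or removing one never changes another's evidence row.

### Age-to-slice rule

Calibrated age intervals rarely align with 1-kyr slices. The package
maps an interval $[a_{\min}, a_{\max}]$ (years BP) to the slices
$\lfloor a_{\min}/1000\rfloor$ through $\mathrm{round}(a_{\max}/1000)$,
intersected with the available ages, with a nearest-slice fallback so
the result is never empty. This reproduces the natural reading of
published case choices (an interval of 13,898–13,941 yr BP evaluates
slices 13 and 14; 11,068–11,211 yr BP evaluates slice 11) while
remaining a single deterministic rule; published practice itself is not
perfectly consistent, so the rule is documented rather than claimed to
replicate any particular study's rounding. Across the selected slices,
$S$ aggregates by maximum (configurable to mean): a fossil needed
suitable climate at *some* moment within its dating uncertainty, not at
every moment.

## The three suitability algorithms

All three predict in $[0,1]$, are deterministic after fitting (the
random forest stores its seed), and share one feature convention:
linear plus quadratic terms of each climate variable, z-scored against
the contrast sample (background or pseudo-absences) with the scaling
stored and replayed at prediction. Quadratic features give every
algorithm the capacity to represent a unimodal (bell-shaped) climatic
response, keeping the three comparable; product/hinge/threshold features
are deliberately omitted.

**Maximum entropy (presence–background).** A Gibbs density over the
background cells, $q_w(x) \propto \exp(w^\top f(x))$, fitted by
minimizing the convex penalized objective
$-\overline{w^\top f}_{\text{presence}} + \log \sum_{\text{bg}} e^{w^\top f}
+ \sum_j \lambda_j |w_j|$ with proximal gradient descent (soft
thresholding, backtracking line search). $\lambda_j$ scales with the
presence-sample SD of feature $j$ over $\sqrt{n_{\text{presence}}}$
times the regularization multiplier. Defaults mirror the conventional
run settings of this model family: 1000 iterations, 1000 background
points, regularization multiplier 1, convergence threshold $10^{-5}$.
Suitability is the logistic output
$\sigma(\eta - \log Z_{\text{bg}} + H)$, where $H$ is the entropy of the
fitted Gibbs distribution; a featureless fit therefore predicts 0.5
everywhere. Non-convergence within the iteration cap returns the model
with a flag and a warning, never silently.

**Binomial GLM (presence/pseudo-absence).** Maximum-likelihood logistic
regression on the same features. Complete separation triggers a
ridge-penalized IRLS refit (penalty $10^{-6}$ on standardized
coefficients, intercept unpenalized) with a warning.
`glmCoefficients(model, "original")` back-transforms to the raw-variable
parameterization, which is how simulation truth is written.

**Random forest (presence/pseudo-absence).** 500 classification trees
(the conventional stabilized choice; tests confirm 500 vs 1000 trees
changes mean predictions by < 0.05); suitability is the fraction of
trees voting presence.

**Contrast data.** Maxent uses 1000 background cells drawn uniformly
from valid cells; GLM and RF use 1000 pseudo-absence cells drawn
uniformly from valid cells *excluding* the species' occupied cells. The
published settings this package follows state the background size but
not the pseudo-absence size; we reuse 1000 for symmetry. Each algorithm
is evaluated against the contrast type it was fitted with.

## Evaluation

AUC is computed as the exact Mann–Whitney rank statistic (ties count
one half) — the probability a random presence outscores a random
absence — avoiding curve-integration ambiguity. TSS is
$\max_t [\text{sensitivity}(t) + \text{specificity}(t) - 1]$ over all
distinct observed scores plus midpoints, reporting the smallest argmax
threshold; the maximizing rule is fixed here because published usage
typically leaves the binarization unstated. Cross-validation resamples a
75/25 presence *and* contrast split, 50 repetitions by default, each
repetition seeded from the master seed; failed fits are skipped and
counted, with more than 20% skips an error. Inter-algorithm agreement is
the Pearson correlation of suitability maps over jointly valid cells.

## Transfer diagnostics

Projection onto past climates risks non-analogue conditions. Three
standard diagnostics are computed against a reference sample (the
model's training presences plus contrast points — which reference sample
published workflows use is typically unstated, so this default is
configurable): **clamping** truncates each variable to its training
range at prediction time (default on, matching the historical default of
the tools this mirrors; clamped and unclamped predictions agree exactly
off the clamping mask); **MESS** uses the piecewise percentile formula
with strictly-below counting, negative exactly outside the reference
hull; **MoD** is the variable attaining the minimum similarity (lowest
index on ties). A constant reference variable with an outside value
yields a $-\infty$ sentinel with a warning. Assignment reports attach
MESS and clamping status at the fossil cell per slice as caveats.

## The virtual-species simulator

The generator emulates the *structure* of real inputs — it makes no
claim about any real region's climate:

* **Climate fields.** Each variable is a linear spatial gradient with
  random orientation plus a low-frequency sinusoidal surface plus white
  noise. The latent fields are orthonormalised (QR) and mixed through
  the Cholesky factor of the target correlation matrix, so the realized
  inter-variable correlation equals the target exactly (default 0.4,
  safely below the 0.7 collinearity screen). Fields are scaled to
  realistic means and spatial SDs (defaults: warm-quarter temperature
  24 ± 3 °C, cold-quarter 12 ± 4 °C, wet-quarter precipitation
  900 ± 250 mm, dry-quarter 150 ± 60 mm).
* **Drift.** Slice $k$ (kyr BP) equals the slice-0 field plus
  $k \times$ a per-variable drift (defaults −0.6 and −0.7 °C/kyr,
  −30 and −12 mm/kyr: cooler and drier towards the glacial). Drift is a
  uniform shift, which keeps slice means exactly linear in $k$ and makes
  the zero-drift stack exactly stationary — deliberately simple; real
  paleoclimate fields also change shape. Precipitation is floored at 0.
* **Species.** Gaussian niches,
  $s(x) = s_{\max} \exp(-\tfrac12 \sum_j ((x_j - c_j)/w_j)^2)$ — the
  standard virtual-species choice, giving a known optimum for recovery
  tests. The four-species demonstration scenario separates niche centers
  by well over twice the combined widths pairwise, and places the first
  species' optimum at the oldest slice's climate so a fossil can be
  planted outside its present range.
* **Occurrences.** $n$ distinct cells (default 150 per species; 500 in
  the niche-recovery check) drawn without replacement with probability
  proportional to true suitability, returned as cell centers —
  deduplication at cell resolution mirrors what cleaning would do
  anyway.
* **Fossils.** Planted at a cell with true suitability ≥ 0.5 of the
  species' maximum at the target slice and, when requested, < 0.1 of
  the maximum at present; the age interval brackets the nominal slice by
  ±100 years, mimicking calibrated-date precision.

What passing tests on this simulator shows: the statistics are computed
correctly, the models can recover a known niche, and the assignment rule
recovers planted identities under niche separation and niche
conservatism. What it does not show: robustness to sampling bias,
spatial autocorrelation of occurrence effort, dating error beyond the
interval, niche drift, or paleoclimate reconstruction error — all real
phenomena the simulator intentionally omits.

## Numerical and design choices

* Coordinates are WGS84 lon/lat; grids use half-open cells with the
  origin at the north-west corner; all point lookups are
  containing-cell. Rasters are read and written as ESRI ASCII grids
  (`<var>_<age>kyr.asc`), a plain-text format with exact
  (`%.17g`) round-tripping.
* Occurrence cleaning: drop off-grid/nodata, optional range-polygon
  filter (even-odd ray casting), deduplicate to one record per cell
  keeping the first in input order; idempotent; counts audited in the
  provenance trail.
* Collinearity screening: greedy — repeatedly find the worst pair with
  $|r| \ge$ threshold and drop the member with the larger mean absolute
  correlation to the rest, ties dropping the later-listed variable; the
  criterion ($r < 0.7$) is conventional, the algorithm is ours and
  guarantees all surviving pairs satisfy the threshold.
* Seeds are explicit arguments everywhere; pipeline stages derive
  sub-seeds deterministically from the master seed, so a rerun
  reproduces every artifact checksum-identically.
* $m_i = 0$ (a degenerate model floor) is handled by deciding
  plausibility as $S_i > 0$ and reporting the ratio as a sentinel, with
  a prominent warning.
* Plausibility uses $\ge$, so a fossil exactly at the occurrence floor
  passes — the boundary case occurs in practice when suitabilities are
  reported at two decimals.

## Problem sizes

The test suite and acceptance script run on desk-scale scenarios chosen
to make the statistical checks sharp while staying quick: 40×40 to
60×60 grids, 4 climate variables, 6 slices, 150–500 occurrences, 1000
background/pseudo-absence points, 10–50 cross-validation repetitions,
and 10–20 replicate scenarios for the recovery-rate checks. These sizes
are the package's own choices; every quantity reported in the README or
this vignette is computed by the tests or the acceptance script at run
time.

## Known limitations

* The maximum-entropy implementation is feature-restricted (linear +
  quadratic) by design; it is not intended to reproduce any desktop
  tool's numeric output.
* Cross-validation splits are random, not spatially blocked; AUC/TSS on
  spatially autocorrelated data are optimistic.
* The assignment is comparative, not probabilistic: no posterior
  probability of identity is produced, and a headline should be read
  together with the plausibility flags, the ratio column and the
  MESS/clamping caveats.
* Random-forest models serialize as settings + seed (they are exactly
  refittable), not as portable weight documents.
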