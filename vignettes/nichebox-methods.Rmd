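---
title: "Envelope and similarity models for habitat suitability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope and similarity models for habitat suitability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebox)
```

# The problem

Presence-only species distribution modelling asks: given the places where a
species has been recorded and a stack of environmental rasters, which cells
of a landscape are climatically suitable, and how does that suitability shift
under a projected future climate? `nichebox` implements two classic,
transparent answers — a climatic percentile envelope (the BIOCLIM family) and
a range-standardised Gower similarity model (the DOMAIN family) — together
with the supporting pipeline a desk study needs: occurrence cleaning and
spatial thinning, collinearity pruning by variance inflation factor (VIF),
principal component analysis of the climatic drivers, replicated
presence-versus-background AUC validation, six-band suitability
classification, and current-versus-future change accounting.

Both models are deliberately simple. They fit in milliseconds, have no tuning
parameters beyond their classification thresholds, and their failure modes
are easy to reason about. That makes them a good scriptable baseline and a
good teaching vehicle, even where a modern study might add Maxent or an
ensemble.

# The models

## Percentile envelope (BIOCLIM)

Fitting stores, for each variable $v$, the sorted training values and the
observed range $[\min_v, \max_v]$. For a candidate site with value $x_v$, let

$$p_v = \frac{\#\{t_{v} < x_v\} + \tfrac12\,\#\{t_{v} = x_v\}}{n},$$

the mid-rank fraction of the $n$ training values below $x_v$. The per-variable
tail score is $s_v = \min(p_v,\, 1 - p_v)$ and the suitability index is

$$S = 100 \times \min_v s_v,$$

with $S = 0$ whenever any $x_v$ falls strictly outside $[\min_v, \max_v]$.
The index is maximal ($50$) at the joint training median and decreases toward
the climatic margins.

The classic envelope literature describes scoring by "percentile position"
without printing a formula, and the GUI tools that popularised the method do
not document theirs. The two-tailed mid-rank definition above is therefore
the one *inferential reconstruction* in this package. We chose it because it
(a) is maximal at the median and zero outside the envelope, as every verbal
description requires; (b) handles ties deterministically; and (c) naturally
produces observed maxima below the theoretical 50 on finite training samples,
which is consistent with published legends whose top band ends near 41 rather
than 50. No clamp is applied at any particular maximum.

A constant training variable needs no special case: its min and max coincide,
so a matching site has $p = 0.5$ (tail score $0.5$) and any other value is
out of envelope. `fit_bioclim()` still warns, because a zero-width axis
usually signals an extraction bug.

## Gower similarity (DOMAIN)

Fitting stores the training matrix and per-variable ranges
$r_v = \max_v - \min_v$ *over the training points only* (not the whole grid),
so the fitted object is self-contained. The distance from a site $x$ to a
training point $t$ is the equal-weight Gower distance

$$d(x, t) = \frac{1}{V} \sum_v \frac{|x_v - t_v|}{r_v},$$

and the reported score is the similarity to the *nearest* training point,
$100\,(1 - \min_t d(x, t))$. It equals 100 exactly when the site coincides
with a training record and is unbounded below; no flooring is applied — a
published lower bound like $-210$ is an observation of a particular run, not
part of the algorithm. When $r_v = 0$ the ratio is taken in its limit as a
match/mismatch indicator: 0 if $x_v$ equals the constant, else 1. The
single-nearest-point variant is implemented (not a mean over the $k$ best),
matching the method's standard description; the search is an exact scan,
which is entirely adequate at desk scale.

## Classification

Both continuous surfaces are cut into the same six ordered classes,
`unsuitable < low < medium < high < very_high < excellent`, with the
conventional thresholds:

* envelope index: $0$, $(0, 2.5]$, $(2.5, 5]$, $(5, 10]$, $(10, 20]$,
  $> 20$ — **upper-inclusive** edges, which is the only closure under which
  the printed chained ranges ("0.0–2.5, 2.5–5.0, ...") do not overlap;
* similarity: $(-\infty, 90)$, $[90, 92)$, $[92, 94)$, $[94, 96)$,
  $[96, 98)$, $[98, 100]$ — **lower-inclusive** edges, so a score of exactly
  90 is already (barely) suitable.

Each suitability grid carries a model tag and the classifiers refuse a grid
tagged for the other model, because applying similarity thresholds to a
percentile index is a category error that would fail silently otherwise.

# Variable selection and diagnostics

`vif_stepwise()` iterates: regress each remaining variable on all the others
by least squares, compute $\mathrm{VIF} = 1/(1 - R^2)$, and remove the
variable with the largest VIF while any VIF meets the threshold (default 5,
the conventional cutoff). Numerical choices: $R^2 \ge 1 - 10^{-12}$ (perfect
collinearity) maps to a sentinel VIF of $10^{12}$ so the greedy loop never
special-cases infinities, and ties at the maximum drop the *later* column so
the user-visible column order decides deterministically.

`pca_env()` eigen-decomposes the correlation matrix by default — bioclimatic
variables mix °C, mm and dimensionless seasonality, so covariance PCA would
be dominated by precipitation totals. Loading columns are sign-fixed so each
column's largest-magnitude entry is positive. The analysis takes whatever
variable subset it is given and makes no attempt to guess which subset a
particular publication used.

`descriptive_stats()` reports min, max, mean, sample sd ($n-1$),
$\mathrm{cv} = 100\,\mathrm{sd}/|\mathrm{mean}|$ and the normal-approximation
95% CI, $\bar x \mp 1.96\,s/\sqrt n$. The $z = 1.96$ choice (rather than
Student-t) reproduces published occurrence-summary tables computed at
$n \approx 600$, where the distinction is invisible at one decimal. A cv
computed across a sign change (mean near 0) is fragile; it is reported as
`NA` when the mean is exactly 0, and values from near-zero means should be
read with suspicion either way.

# Validation

Presence-only models need a background (pseudo-absence) sample to compute an
ROC curve. `replicate_evaluation()` repeats, $k$ times (default 10): a fresh
random 70/30 presence split (replicate $r$ reseeds at `seed + r`, so any
single replicate can be reproduced in isolation), a fit on the training
subset, a whole-grid prediction, and a rank-based (Mann–Whitney, mid-rank
ties) AUC of the test presences against a fresh uniform background sample
drawn from non-presence, non-nodata cells. The default background size is
10× the number of test presences, capped at the number of eligible cells;
the report records the size actually used. The $k$ prediction grids are
averaged cellwise into the final suitability surface — the replicated-split
averaging practice of the GUI workflow this package scripts. Mean AUC is
banded fail/bad/fair/good/excellent at 0.6/0.7/0.8/0.9 with lower-inclusive
edges (the chained published ranges do not state closure; a 0.9 counts as
excellent here), and the AUC spread is the sample sd over replicates.

# Change accounting

Cell areas use the spherical band formula
$A = R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$ with the
authalic radius $R = 6371.0072$ km — exact on the sphere for cells bounded by
meridians and parallels, and accurate to the sphere/ellipsoid discrepancy
(~0.1%) which is far below the classification uncertainty. Per-class areas
are reported in $10^4$ km²; percent change is rounded half away from zero
(the rounding that matches every printed change we cross-checked, e.g.
$17.4545 \to 17.5$, $-0.917 \to -0.9$; base R's banker's rounding does not).
A class absent now but present in the future has no defined percent change
and reports `NA` rather than a number.

`transition_map()` classifies each cell for a focal class (default
`excellent`) into retained / lost / new / other, and `patch_stats()` counts
connected components of a focal class under 4-connectivity (rook moves;
8-connectivity available) to quantify the fragmentation of what remains.
There is no built-in land mask: the nodata mask of the input stack is the
only masking, so absolute area totals on real data are only meaningful with
the user's own coastline/land mask applied upstream.

# The synthetic world

Because the real inputs (global bioclimatic rasters and a curated occurrence
compilation) are external downloads, the package ships a generator that makes
the whole pipeline testable from code alone. A stack is specified by
per-variable means/sds, a cross-variable correlation matrix, a smoothing
radius and a seed. Generation: i.i.d. standard normal cell noise is mixed
across variables by a symmetric square root of the correlation matrix,
smoothed with a uniform moving average of the given radius (edge-truncated,
separable), rescaled to unit sample variance, then scaled to `mean + sd * field`.
The rescaling step matters: without it, smoothing would shrink the marginal
sd by roughly the window size, and every quantity stated in sd units
(including the true envelope below) would silently depend on the smoothing
radius.

The default scenario (`default_climate_spec()`) is a 120×120 grid at 0.125°
over east-central Asia with the six variables a VIF-pruned continental
analysis typically retains — bio6, bio8, bio10, bio11, bio12, bio13 — using
published occurrence-region means/sds for the first five (e.g. bio12
= 1113.2 ± 369.4 mm) and a realistic monsoon-climate 190 ± 70 mm for bio13,
which such tables rarely print. Correlations come from a three-factor model
(winter temperature, summer temperature, precipitation), positive
semidefinite by construction. The default virtual species
(`default_envelope()`) occupies a ±1 sd box around the variable means with
weight 1 inside and 0 outside; occurrences are drawn without replacement,
proportional to weight, at cell centres (no jitter — extraction round-trips
exactly and tests stay deterministic). The default sample size is 604
records, a typical compiled national data set after county-level cleaning;
the default future scenario adds +2.5 °C to winter temperatures, +2 °C to
summer temperatures and +5% to precipitation, a mid-range doubled-CO₂
pattern for the region.

What the generator does **not** emulate: real geographic gradients (fields
are stationary), topography and coastlines (no nodata mask by default),
non-Gaussian climate marginals, and spatially biased sampling effort. A green
test on synthetic data therefore establishes that the algorithms are
implemented correctly and behave as theory predicts (envelope recovery,
self-similarity of 100, uninformative envelopes giving AUC ≈ 0.5) — it does
not establish that any particular real-world map or area total is
reproduced, which would require the original rasters, occurrence set and
land mask.

# Numerical and design choices

* Occurrence thinning is per raster grid cell (first record in input order
  wins; idempotent). County-level deduplication needs administrative
  polygons, which the package deliberately does not ship; cell size is the
  knob that approximates county scale.
* Altitude classes are half-open and lower-inclusive: 800 m is "mid". The
  split train size is $n \times f$ rounded half away from zero.
* Points exactly on a shared cell edge belong to the cell to the south/east;
  points on the grid's outer south/east edge belong to the last cell.
* Without-replacement occurrence sampling requires `n` ≤ the number of
  positive-weight cells; the error message reports both numbers.
* `run_pipeline()` aborts on the first failing stage, naming it; a missing
  future stack is not an error — the comparison stage is skipped and the
  manifest notes it.
* All randomness is seed-parameterised and RNG state is restored after every
  call, so library calls never perturb the caller's random stream.

# Known limitations

Single-nearest-point DOMAIN only; no kernel or weighted Gower. No ROC-curve
export or threshold metrics (kappa, TSS). No interpatch-distance or
centroid-shift statistics. ESRI ASCII is the only raster format (readable by
every GIS; no GeoTIFF without a raster dependency). Area totals are mask-naive
as discussed above. The percentile-index reconstruction, while principled, is
not guaranteed to match any specific GUI implementation bit for bit.
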