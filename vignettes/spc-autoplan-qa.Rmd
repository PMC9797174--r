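---
title: "Monitoring automated radiotherapy planning with individual control charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring automated radiotherapy planning with individual control charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtspc)
```

## The monitored statistic

An autoplanning service computes a plan on a reference beam model; the clinic
recalculates it locally with fixed monitor units inside the same contours.
For each structure $s$ of each case, `rtspc` monitors the percent mean-dose
difference

$$ d_s \;=\; 100 \cdot \frac{\bar{D}_{\mathrm{local}}(s) - \bar{D}_{\mathrm{ref}}(s)}{\bar{D}_{\mathrm{ref}}(s)} \quad [\%], $$

with the sign convention that differences are relative to the reference
(automated) plan: positive means the local system calculates a higher dose.
Mean dose was chosen as the monitored metric because it is robust to the
known, benign disagreements between planning systems near the skin surface;
it will not catch every error a DVH-point metric might, but it tracks gross,
systemic changes well. Maximum dose or hot-volume metrics are deliberately
out of scope.

The mean dose itself is the unweighted arithmetic mean of the dose at voxel
centers inside the structure. A voxel center belongs to a structure iff it
lies within half a slice spacing of the structure's nearest contour plane
and inside that plane's polygons under the even-odd rule (so concentric
contours form rings and holes). There is no partial-volume weighting: the
center-in/center-out rule is simple, fast, and checkable against an
independent point-in-polygon oracle, and the monitored statistic is a
*difference* of means on the same mask, where partial-volume refinements
largely cancel.

When the two plans live on different grids, the reference grid is
authoritative: the local grid is resampled onto it by trilinear
interpolation before masking, so each structure has exactly one mask per
case and any difference is attributable to dose, not geometry. Resampled
points outside the source grid's support become `NA` and are excluded from
means. Percent differences are only computed when the reference mean dose
exceeds `dose_floor` (default 0.01 Gy) — a ratio against a near-zero
denominator is noise, not signal — and skipped structures are reported with
a warning rather than silently dropped.

## Individual control charts

Each structure's ordered series $d_s^{(1)}, d_s^{(2)}, \dots$ is charted on
an individuals (I-) chart with the classical 3-sigma limits

$$ \mathrm{UCL} = \mu + 3\sigma, \qquad \mathrm{LCL} = \mu - 3\sigma. $$

Estimation excludes out-of-limit observations from $\mu$ and $\sigma$:
pass 0 uses all observations; every later pass recomputes $\mu,\sigma$ over
the observations inside the previous pass's limits, re-screening the *whole*
series each time. We iterate this to a fixed point (capped at `max_iter`,
default 10) rather than applying it once. The single removal rule by itself
does not say whether it repeats; the fixed point makes it well-defined and
idempotent — re-running estimation on the retained subset changes nothing —
and `max_iter = 1` recovers the single-pass variant for comparison. Both the
pass count and the exclusion set are recorded on the chart object.

Two $\sigma$ estimators are offered. The default is the sample standard
deviation with the $n-1$ denominator — the straightforward reading of
"mean and standard deviation" of the observations. The moving-range
estimator (mean absolute successive difference divided by $d_2 = 1.128$),
the textbook choice for individuals charts because it is insensitive to
slow drift, is available via `estimator = "moving-range"`.

Conventions for edge cases:

* **Boundary**: a value exactly on a limit is *in control* — flagging uses
  strict inequality. This is the conservative choice for an alerting tool.
* **Zero variance**: a constant series yields $\sigma = 0$ and limits that
  collapse onto the mean, with a warning; it is not an error.
* **Establishment floor**: `min_points` (default 20) observations are
  required both before and after exclusion; otherwise the chart is refused
  as not establishable. Twenty is a practical floor below the 30-ish
  cohorts that stabilize an I-chart; it is configurable because the right
  number is genuinely an open operational question.
* Human-readable output rounds chart statistics to two decimals, as chart
  tables conventionally print them; full precision is kept on the objects.

With iterated 3-sigma exclusion, an in-control Gaussian series retains
slightly less than the nominal $1 - 0.0027$: the fixed point of truncation
at $3\hat\sigma$ sits near $2.95\sigma$ of the original scale, so the
long-run excluded fraction is ≈ 0.003 rather than 0.0027. The acceptance
suite checks this at $n = 10^5$ with a ±0.001 band that covers both the
nominal and the truncation-corrected value.

## Machine-parameter sensitivity

To understand how the chart statistics depend on the local beam model, one
MLC parameter — dosimetric leaf gap (DLG, cm) or MLC transmission factor
(MLC-TF, dimensionless) — is varied over at least three levels while the
other is held constant (a mixed-level sweep is refused as confounded). At
each level a chart is estimated per structure; ordinary least squares is
then fit to each statistic (UCL, mean, LCL) against the parameter value.
The regression uses the per-level chart statistics (one point per level),
because control limits only exist at the level of a charted cohort; a
pooled per-case fit of the mean line would weight levels by cohort size and
is not what the chart statistics measure.

Rates of change are normalized to canonical steps — 0.1 cm of DLG and 0.01
of MLC-TF — which correspond to the clinically observed spread of these
parameters across institutions. The mean line's zero crossing,
$-\,\mathrm{intercept}/\mathrm{slope}$, estimates the parameter value at
which the local calculation matches the reference; a zero slope leaves it
flagged undefined rather than infinite.

Zero crossings are summarized across structures as mean ± sample SD, both
over all structures and after outlier exclusion. Small structures (eye,
lens, optic nerve) can produce wildly unphysical crossings because their
tiny volumes amplify relative dose changes; two explicit exclusion rules
stand in for that judgment call:

* **physical-range** (default): crossings outside a plausible interval are
  excluded — DLG $(0, 0.5]$ cm, MLC-TF $(0, 0.05]$. The DLG cut-off mirrors
  the scale at which reported crossings become physically meaningless; the
  MLC-TF interval is the analogous span around clinically used
  transmissions.
* **mad**: crossings beyond $k$ (default 3) scaled median absolute
  deviations from the median are excluded; `stats::mad()` with its default
  consistency constant 1.4826 is used so $k$ reads in sigma-equivalents.

Sweep layouts: the same cases may be recalculated at every level
("crossed") or split across levels; both produce valid per-level cohorts,
and the layout is declared in the run configuration so the bookkeeping is
explicit rather than guessed.

## Synthetic cohorts: what they do and do not emulate

All tests run without clinical data, on seeded generators that emulate the
*statistical* structure the method assumes:

* `generate_cohort()` draws $d_s \sim \mathcal{N}(\delta_s, \sigma_s^2)$
  per structure — Gaussian because monitored cohorts are well summarized by
  mean ± SD — with optional injected outliers that overwrite single cells,
  and an optional Student-$t$ noise mode (variance-matched, `df`
  configurable) to stress the exclusion rule against heavy tails.
* `generate_sweep()` draws
  $d_s \sim \mathcal{N}(\beta_s (x - x_{0,s}),\, \sigma_s^2)$ at each level
  $x$, anchoring each structure's response to vanish at its crossing
  $x_{0,s}$. Defaults anchor crossings at the reference machine's values
  (DLG 0.2 cm, MLC-TF 0.02); outlier structures are given deliberately
  extreme crossings to exercise the exclusion rules.
* `generate_grid_fixture()` builds paired dose grids (constant or linear in
  $x$) with rectangular structures, where a global scale factor $k$ gives a
  closed-form expected difference of exactly $100(k-1)\,\%$ for every
  structure, checkable end to end through rasterization and voxel means.

Every generator is a pure function of its spec, seed included, and leaves
the caller's RNG stream untouched. What the generators do **not** emulate:
dose-calculation physics (beam models, MLC sequencing, scatter), inter-
structure correlation within a case, autocontouring variability, and
longitudinal autocorrelation. Passing tests therefore demonstrate that the
charting, exclusion, fitting and flagging machinery is correct under the
stated statistical model — not that any particular clinic's differences are
Gaussian or linear in a beam parameter.

Cohort sizes used throughout the tests and the acceptance script mirror
realistic monitoring cohorts: around 30 cases per chart (30–51 in the
site cohorts this package is designed around), 5 DLG levels
(0.1, 0.155, 0.17, 0.19, 0.23 cm) and 4 MLC-TF levels
(0.0118, 0.0145, 0.0158, 0.0165) at 30 cases per level, coverage checks at
$10^5$ observations, and 100-replicate recovery checks for the sensitivity
fits.

## Data model and input formats

Dose grids are axis-aligned and uniformly spaced, with positions referring
to voxel centers in patient coordinates (mm), matching DICOM
ImagePositionPatient semantics; oblique orientations are rejected rather
than approximated. Structures are closed planar polygons on constant-axial
planes; degenerate contours (fewer than 3 vertices, zero area) are dropped
on read with a warning, self-intersecting ones are refused, and structure
names must be unique within a set. A frame-of-reference label ties a
structure set to the grids it may be evaluated against.

Three input routes exist: DICOM RT Dose / RT Structure Set (parsed by a
bundled pydicom-based converter, with `DoseGridScaling` applied so values
are always Gy), a plain JSON fixture format for both grids and structure
sets (used by the test suite so the repository stays text-only), and
per-structure mean-dose CSV tables for sites that already extract DVH
statistics. Readers never rescale doses beyond the declared scaling tag,
and summary tables round-trip losslessly.

## Known limitations

* Center-in-voxel rasterization biases masks for structures only a few
  voxels wide; for such structures the mean-dose *difference* remains
  meaningful but its variance grows, which is exactly why their crossings
  are candidates for exclusion.
* I-charts with estimated limits have inflated false-alarm rates at small
  $n$; `min_points` is a floor, not a guarantee of nominal coverage.
* No run rules (Western Electric / Nelson), EWMA or CUSUM: single-point
  3-sigma violations only, by design.
* The sensitivity model is strictly linear per parameter with the other
  held fixed; curvature or parameter interaction is out of scope.
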