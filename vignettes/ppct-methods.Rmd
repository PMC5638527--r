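---
title: "Methods: sector geometry, sine-fit disc tilt and the ppCT analysis battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sector geometry, sine-fit disc tilt and the ppCT analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppct)
```

## The measurement problem

The choroid immediately around the optic disc (the peripapillary choroid) is
thinned in myopia and implicated in glaucoma, but a single averaged thickness
hides focal change. This package quantifies *local* peripapillary choroidal
thickness (ppCT) in eight 45° sectors around the disc, together with two
geometric covariates of the optic nerve head that plausibly deform the
peripapillary tissue:

* **Optic disc tilt**, measured as the amplitude of a sinusoid fitted to the
  retinal pigment epithelium (RPE) trajectory on the unwrapped circumpapillary
  B-scan. A circular section of a tilted plane is exactly one period of a
  sinusoid, so the amplitude (in axial pixels) is a monotone proxy for the
  tilt angle of the peripapillary RPE plane relative to the optical axis.
* **Papillo-macular position (PMP)**, the signed angle between the horizontal
  and the disc-center-to-fovea line on the fundus photograph.

The package then relates sector ppCT to axial length, PMP and tilt with the
nonparametric battery described below.

## Coordinate conventions

Fundus landmarks use the screen convention of fundus photographs: y increases
inferiorly. PMP is positive when the fovea sits inferior to the horizontal
through the disc center, which is the anatomically typical configuration; a
healthy cohort therefore has a positive mean PMP.

Sector angles live in an *anatomical* frame on the scan circle: 0° at the
temporal horizontal direction, increasing toward superior. The temporal (T)
sector is anchored at the intersection of the disc-to-fovea line with the
circle, and the remaining sectors follow at 45° steps in TSNIT order
(T, ST, S, SN, N, IN, I, IT). Because the frame is anatomical, left eyes map
onto the same frame automatically (the nasal/temporal mirror flip is absorbed
by the frame definition); the cohort-level eligibility filter nevertheless
retains right eyes only, matching the study design the package emulates.
A-scan `i` of an `n`-scan circle sits at `i * 360 / n` degrees in this frame.

## The sine fit

The tilt metric is the least-squares fit of `y = a sin(bx - c)` to manually
marked RPE points, after recentering (x to the scan midpoint, y to its mean).
Rather than iterating from heuristic starts, the implementation exploits the
model's structure: for fixed `b` the model is linear in
`(A, B) = (a cos c, -a sin c)`, so the conditional problem is solved exactly
by its 2×2 normal equations; the profiled residual sum of squares is then
minimized over `b` with a coarse grid refined by golden-section search. The
fit is deterministic and globally optimal in `(a, c)` given `b`, which makes
multi-start schemes unnecessary. Amplitude is reported non-negative, the sign
being absorbed into the phase.

`b` is constrained to 0.5–2 times one period per scan width. The physical
model (plane section) has exactly one period; an unconstrained frequency lets
marking noise lock onto harmonics and inflate the amplitude. Degenerate input
(all depths equal) yields `a = 0` with `converged = TRUE`; a singular design
yields `converged = FALSE` with flagged parameters.

Two configuration defaults are assumptions rather than published facts: 64
marked points per eye and an axial pitch of 2.6 µm/px. Both are exposed in
`trace_config()`. Recentering uses the mean of y (not the midline of the
extremes); for a full-period sinusoid sampled evenly the two coincide.

## Thickness measurement

ppCT at a sector is the axial distance between the outer RPE boundary and the
sclerochoroidal interface, `(z_csi - z_rpe) * axial_scale`, evaluated at the
A-scan nearest the sector center (`window_deg = 0`, the single-position
convention of manual grading) or as the median over a ±`window_deg` window
for robustness to marking noise. Measuring along the A-scan approximates the
perpendicular distance; the two coincide where the boundaries run parallel to
the scan circle, and defining surface normals from a 1-D trace would add more
noise than it removes. Thickness is by construction invariant to the RPE's
absolute depth and to its sinusoidal undulation, and scales linearly with the
axial pixel pitch.

The per-eye **temporal ratio** is the T-sector ppCT divided by the mean of
the other seven sectors: an internally normalized asymmetry index that is
insensitive to global choroidal thickness.

## The statistical battery

All tests are two-sided at α = 0.05, and no multiple-testing correction is
applied across the 8-sector × 3-predictor grid; this mirrors the analysis
design the package reproduces and is deliberately preserved rather than
"fixed".

* **Spearman correlation**: Pearson correlation of mid-ranks; p from the t
  approximation with n − 2 degrees of freedom. The t approximation is the
  behavior of standard statistical packages at cohort sizes (n > 100); the
  exact enumeration route exists in the test oracles for small n.
* **Standardized regression**: OLS on z-scored outcome and predictors, all
  three predictors entered simultaneously; betas are comparable across
  predictors with different units.
* **Steel–Dwass**: for each group pair, the pair's pooled mid-rank Wilcoxon
  statistic standardized with tie-corrected variance; family-wise adjusted p
  from the studentized-range distribution with `k` groups and infinite
  degrees of freedom via `t = √2·|z|`. With k = 2 this reduces exactly to the
  two-sided normal-approximation Mann–Whitney p (without continuity
  correction). The sector comparison applies this test across the eight
  sectors even though they are within-eye repeated measures — again a
  fidelity choice, documented rather than corrected.
* **Mann–Whitney**: normal approximation with tie and continuity correction
  by default; exact enumeration of all `C(m+n, m)` assignments available for
  small samples.
* **Fisher-z comparison** of two independent correlations, used to compare
  the male and female correlation grids.

## The synthetic cohort generator

The generator is a linear-Gaussian forward model of the study conditions, not
a fit to any dataset:

* axial length ~ normal(25.46, 1.43²) mm truncated to [22.38, 30.42];
* PMP ~ normal(5.43, 3.47²) degrees;
* tilt = 53.08 + 1.5·(AL − 25.46) px + noise, total SD 23.93, clipped at 0.
  The coupling (longer eyes more tilted) is weak and positive, consistent
  with the mechanical picture of axial elongation dragging the disc; its
  strength is a free parameter;
* sector ppCT = baseline + linear effects of the centered predictors +
  residual, clipped at 1 µm. Baselines and total SDs equal the published
  sector summary (T 166.87 ± 62.45 µm … N 190.62 ± 47.66 µm).

Effect sizes are specified as **target marginal correlations** per sector
(axial length negative in all eight sectors, PMP positive in all eight, tilt
negative in T and IT only) and converted to regression coefficients through
the predictor covariance matrix, so the calibration constants live in the
config, not in the code. The targets are spread across the published ranges
(axial length 0.22–0.43, PMP 0.21–0.37, tilt 0.20–0.32); sampled Spearman
magnitudes at n = 114 land in those ranges on average.

A fraction (default 0.7) of each sector's residual variance is a shared
within-eye component. Real choroidal thickness is strongly correlated across
sectors of one eye, and this dependence matters for the joint behavior of the
24-cell grid: with independent sector residuals the eight tilt correlations
of a null sector would be nearly independent and some sector would cross
α = 0.05 in most cohorts.

Traces realize each eye: the RPE is a one-period sinusoid with amplitude
equal to the eye's tilt plus per-A-scan noise (default 2 px); the interface
lies below it by the eye's thickness profile, interpolated through its eight
sector values with a periodic cubic spline; marked points subsample the noisy
RPE at exactly periodic positions with additional marking noise (default
2 px). The interface shares the RPE's noise realization — boundary grading
error is modeled on the tilt pathway (marking noise), not on the thickness
difference — so round-trip recovery of sector values is limited only by
interpolation, while tilt recovery faces both noise sources.

What the generator does *not* emulate: non-sinusoidal RPE deformation
(peripapillary staphyloma, conus), scan decentration, segmentation failures,
non-Gaussian thickness distributions, and any joint structure beyond the
pairwise correlations programmed above. Passing round-trip and
pattern-recovery tests therefore demonstrates that the pipeline is correct
and well-calibrated under the stated model, not that the model captures every
property of clinical OCT data.

## Problem sizes and numerical choices

The test suite works at desk scale, chosen so each property is decisive
rather than exhaustive: 500 replicates for noisy amplitude recovery, 20
instances against the exhaustive grid-search oracle (amplitude step 0.5 px,
phase step 0.01 rad), 1000 small tied vectors against the brute-force
Spearman oracle, 10⁴ label shuffles for the Steel–Dwass permutation oracle,
2000 simulations for the family-wise type-I error (3 groups of 15), and 20
cohorts of 114 eyes for the qualitative grid-pattern check. The
pattern-recovery event for tilt is *confinement*: tilt significance occurs in
T/IT and nowhere else. Requiring both T and IT to reach p < 0.05 in the same
cohort would have roughly coin-flip probability at the lower end of the
published effect-size range (r ≈ 0.20 at n = 114), so confinement is the
reproducible signature of the published pattern.

Ties in ranks use mid-ranks throughout. The studentized-range adjustment uses
infinite degrees of freedom. Sine-fit frequency search tolerance is 10⁻¹⁰ of
the nominal frequency. The temporal ratio errors on a non-positive
denominator rather than returning an unbounded value.

## Known limitations

* The Steel–Dwass sector comparison ignores the within-eye pairing of
  sectors; a mixed-model or Friedman-type analysis would be more efficient
  but would not reproduce the published analysis.
* The regression battery assumes linear effects on the measured scale; the
  generator satisfies this by construction, real data need not.
* Tilt in pixels is device-specific; `expected_amplitude()` provides the
  geometric conversion but µm-scale tilt is not the default output.
* Exact reproduction of the published summary statistics requires the
  study's deposited per-eye raw-data table, which is not redistributable with
  the package; the pipeline reads it from `inst/extdata/s1_table_raw.csv`
  when the user supplies it in the documented cohort schema.
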