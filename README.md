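# ppct

Local peripapillary choroidal thickness (ppCT) morphometry and its sector
analysis, for researchers working with circumpapillary OCT circle scans of
the optic nerve head.

Averaged peripapillary choroidal thickness hides focal change. This package
quantifies ppCT in eight 45° sectors around the optic disc — temporal (T),
superotemporal (ST), superior (S), superonasal (SN), nasal (N), inferonasal
(IN), inferior (I), inferotemporal (IT) — anchored at the disc-to-fovea axis,
and relates each sector to three ocular covariates:

* **axial length** (mm),
* **papillo-macular position (PMP)**: the signed angle between the horizontal
  and the disc-center–fovea line on the fundus photograph (positive = fovea
  inferior),
* **optic disc tilt**: the amplitude *a* of the least-squares sinusoid
  *y = a·sin(bx − c)* fitted to the recentered retinal pigment epithelium
  trajectory of the unwrapped circle scan. A circular section of a tilted
  plane is exactly one period of a sinusoid, so *a* (axial pixels) grows
  monotonically with the tilt of the peripapillary RPE plane.

The analysis battery is implemented from definitions: Spearman rank
correlation (mid-ranks, t-approximation p), standardized multiple regression,
the Steel–Dwass all-pairs comparison (tie-corrected pairwise rank sums with
studentized-range adjustment), the Mann–Whitney U test (normal approximation
and exact enumeration), and the Fisher-z comparison of two correlations. A
seedable synthetic generator produces cohorts with calibrated effect
structure and the matching boundary traces, so the full pipeline is testable
without any external data.

## Worked example

```r
library(ppct)

cohort <- generate_cohort(cohort_config(n_eyes = 114), seed = 1)
report <- run_study(cohort)
print(report)
```

```
ppCT sector analysis report (n = 114 eyes, alpha = 0.05)

Sector ppCT (um):
 sector   mean     sd
      T 164.72 63.269
     ST 184.71 53.955
      S 187.77 50.030
     SN 191.74 50.585
      N 192.86 49.625
     IN 172.82 44.818
      I 150.59 41.830
     IT 157.17 48.342

Temporal ppCT ratio: 0.909 +/- 0.236 (range 0.015 to 1.469)

Significant Spearman correlations (14 of 24 grid cells):
 sector predictor spearman_r spearman_p
      T        al     -0.294   1.52e-03
      T       pmp      0.320   5.29e-04
      T      tilt     -0.258   5.65e-03
     ST        al     -0.289   1.84e-03
     ST       pmp      0.444   7.54e-07
      S       pmp      0.287   1.93e-03
     SN       pmp      0.380   3.06e-05
      N       pmp      0.310   7.74e-04
     IN       pmp      0.397   1.25e-05
      I        al     -0.216   2.10e-02
      I       pmp      0.335   2.69e-04
     IT        al     -0.379   3.25e-05
     IT       pmp      0.241   9.76e-03
     IT      tilt     -0.303   1.05e-03
```

The grid shows the characteristic pattern: sector ppCT thins with axial
length, thickens with PMP (inferior fovea), and the disc-tilt association is
confined to the temporal and inferotemporal sectors. The per-eye temporal
ratio (T / mean of the other seven sectors) summarizes the same asymmetry.

Tilt is recovered from a boundary trace by the sine fit:

```r
tr  <- generate_trace(cohort[1, ], trace_config(), seed = 2)
fit <- fit_sine(recenter(tr$marked))
print(fit)
#> Sine fit: a = 53.377 px, b = 0.00611496 rad/px, c = 4.7150 rad, rms = 2.907 px
cohort$tilt[1]   # true amplitude: 54.33 px
```

Sector thickness comes from the same trace via
`measure_ppct(tr$trace, tr$sectors)`, and `write_report(report, dir)`
serializes the grids as tidy CSVs plus a JSON summary. A thin CLI over these
functions lives at `inst/scripts/ppct.R` (subcommands `simulate`, `measure`,
`analyze`).

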