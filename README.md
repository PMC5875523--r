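# thoraxreg

Deformable registration of pre-treatment and follow-up thoracic CT with
landmark-based validation, registration-quality grouping, and Dice
overlap analysis of PET uptake contours.

## The problem

Follow-up PET/CT of lung-cancer patients is acquired months after
radiotherapy. Tumour shrinkage and anatomical change mean rigid
alignment leaves large residual mismatch, so any voxel-level comparison
of FDG uptake (e.g. relating pre-treatment hotspots to tumour residue)
first needs a *validated* nonrigid registration. `thoraxreg` provides
the whole chain for researchers in radiotherapy response assessment:

* **Registration.** Multi-resolution (factor-2 pyramid) deformable
  registration with two force models — *Demons*, driven by intensity
  differences, `u = (f − m_w)∇f / (‖∇f‖² + κ²(f − m_w)²)`, and
  *Morphons*, driven by local phase differences measured with six
  log-normal quadrature filters and fused by certainty-weighted least
  squares — each with weighted-sum or diffeomorphic (scaling-and-squaring)
  field accumulation and Gaussian regularization of 1.5× voxel size.
  Rigid pre-alignment by multi-scale mean-squared-difference search.
* **Validation.** Landmarks (vessel bifurcations, calcifications) are
  tracked through the backward deformation field; the mean absolute 3-D
  distance before/after deformable registration classifies each case:
  Group 1 (deformable < rigid/2 and < 6 mm), Group 3 (rigid > 7.5 mm and
  deformable > 6 mm), Group 2 otherwise.
* **PET overlap.** Fractional-SUVmax contours (pre: 34–70 %, post:
  70–90 % of SUVmax) are deformed — the contours, never the PET values —
  and compared by the Dice ratio `DR = 2·V(A∩B) / (V(A) + V(B))`, with
  Wilcoxon signed-rank statistics for rigid versus deformable.
* **Synthetic phantom.** A thorax phantom (CT + PET, known invertible
  ground-truth deformation, annotated landmarks) with four scenarios —
  `recoverable`, `small-motion`, `new-hotspot`, `large-mismatch` —
  exercises every stage without any patient data.

Volumes are NIfTI (`RNifti`), landmark tables are CSV, results are
tibbles with `tidy()`/`glance()` methods and ggplot2 figures.

## Worked example

```r
library(thoraxreg)

case <- generate_phantom(phantom_spec("recoverable", seed = 1))
report <- run_case(case)
print(report)
#> <case_report> Group 1; best variant 'morphons'
#>   rigid      9.94 +/- 1.92 mm
#>   demons     3.53 +/- 1.52 mm
#>   morphons   2.38 +/- 1.07 mm
#>   Dice table: 30 rows; Wilcoxon p = 6.104e-05
```

The phantom imposes a smooth 12 mm deformation with tumour shrinkage;
rigid alignment leaves a 9.9 mm mean landmark error. Both deformable
variants cut the error by far more than half (Demons 3.5 mm, Morphons
2.4 mm), so the case is classified **Group 1** (large improvement), and
the paired t-test on per-landmark distances is strongly significant.
Because registration succeeded, the pre-treatment 60 %-of-SUVmax uptake
contour, deformed into the follow-up frame, overlaps the 70 % residual
uptake contour far better than under rigid alignment:

```r
dplyr::filter(report$dice, pre_fraction == 0.6, post_fraction == 0.7)
#>   pre_fraction post_fraction registration VA_mm3 VB_mm3 Vint_mm3     DR
#> 1          0.6           0.7        rigid  3371.   983.     140. 0.0645
#> 2          0.6           0.7   deformable  2388.   983.     983. 0.583
```

A `small-motion` phantom lands in Group 2 (little to improve over the
annotation floor), and a `large-mismatch` phantom — deformation beyond
the capture range — stays above 6 mm and lands in Group 3, where the
overlap analysis is skipped by default. `run_study()` aggregates many
cases per group with the corresponding paired statistics;
`plot_dice_pairs()` and `plot_landmark_distances()` draw the paired
before/after figures. A command-line wrapper with `simulate`,
`register`, `validate`, `dice`, `run-case` and `run-study` subcommands
lives in `inst/cli/thoraxreg.R`.

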