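# diaphragmr

Quantification of diaphragmatic motion and curvature from paired
end-expiration / end-inspiration 3D lung MRI segmentations, with the
longitudinal cohort statistics used to monitor respiratory muscle
involvement in Pompe disease (a lysosomal glycogen-storage myopathy in
which diaphragm weakness drives respiratory insufficiency). It is aimed at
imaging researchers who have breath-hold lung masks (e.g. from an external
segmenter) and want reproducible, operator-independent outcome measures —
plus a fully synthetic thorax phantom with closed-form ground truth to
validate every step.

## Outcomes

All outcomes are dimensionless inspiration/expiration ratios, which
normalises for sex, age and body size. With `V` the segmented lung volume
and all 2D quantities taken on the sagittal slice through the middle of the
right lung's right–left extent (the right mid hemi-diaphragm):

1. **Lung volume ratio** `V_insp / V_exp` — overall inspiratory capacity.
2. **Diaphragm volume ratio** — the fraction of the volume gain displaced
   by the diaphragm: `Σ_columns max(0, z_exp − z_insp) · ΔxΔy / (V_insp −
   V_exp)`, where `z` is the caudal-most lung voxel per (x, y) column
   (the discrete diaphragm surface).
3. **Lung area ratio** — slice lung area, inspiration over expiration.
4. **Cranial–caudal (CC) ratio** — slice head–foot extent ratio; proxy for
   diaphragm descent.
5. **Anterior–posterior (AP) ratio** — slice front–back extent ratio;
   proxy for thoracic-wall motion.
6. **CC–AP ratio** — `CC ratio / AP ratio`; diaphragm motion normalised to
   chest-wall motion.
7. **Diaphragm height ratio** — dome height = maximum perpendicular
   distance from the diaphragm contour to the chord joining its
   anterior-most and posterior-most points.
8. **Diaphragm area ratio** — shoelace area enclosed by the contour and
   the chord.

Outcomes 7–8 measure diaphragmatic *curvature*: in healthy inspiration the
dome flattens (ratio tends below ~1.1); an **increasing** curvature ratio
over time signals insufficient diaphragmatic contraction
(`classify_change()` labels a positive one-year change in the height ratio
as deterioration, a negative one as improvement).

Across visits one year apart, sagittal levels are matched automatically by
exhaustive integer-shift search (±10 voxels per axis) maximising the Dice
overlap of the expiratory right-lung masks (`match_visits()`); change
scores are follow-up minus initial. Group and subgroup comparisons use the
two-sided Mann-Whitney test (exact when both groups have ≤ 25 observations
and no ties) and Pearson's chi-square for sex, significance at p ≤ 0.05,
no multiplicity correction. Subgroups: enzyme-replacement-therapy duration
(untreated / ≤ 3 y / > 3 y at the initial visit) and initial diaphragmatic
weakness (CC ratio < 1.4, the lowest value recorded in healthy controls).

## Worked example

```r
library(diaphragmr)

# A voxel phantom at the 3 mm acquisition spacing: two elliptic-cylinder
# lungs floored by a paraboloid diaphragm dome, descending on inspiration.
params <- phantom_params()          # defaults: adult thorax, reduced motion
pair   <- build_phantom_pair(params)
res    <- compute_measures(pair)
round(res$ratios, 3)
#>        lung_volume_ratio   diaphragm_volume_ratio          lung_area_ratio
#>                    1.839                    0.357                    1.881
#>     cranial_caudal_ratio anterior_posterior_ratio              cc_ap_ratio
#>                    1.400                    1.255                    1.115
#>   diaphragm_height_ratio     diaphragm_area_ratio
#>                    1.100                    1.085

round(analytic_truth(params)$ratios, 3)   # closed-form ground truth
#>        lung_volume_ratio   diaphragm_volume_ratio          lung_area_ratio
#>                    1.847                    0.357                    1.885
#>     cranial_caudal_ratio anterior_posterior_ratio              cc_ap_ratio
#>                    1.417                    1.257                    1.127
#>   diaphragm_height_ratio     diaphragm_area_ratio
#>                    1.200                    1.200
```

The CC ratio of 1.42 marks this phantom as a typical patient (the healthy
cut-off is 1.4); the height/area ratios of 1.2 mean the dome bulges
*further* during inspiration — the curvature signature of a weak
diaphragm. The curvature ratios carry the largest voxelization error at
3 mm (here ≈ 0.1, about one voxel of dome-height quantization); at 1 mm
all eight measures agree with truth to < 1%.

Real data enter through `load_mask()` (NIfTI, any stored orientation;
binarized at > 0) and `breath_pair()`, per-subject longitudinal results
through `compute_subject()`, and per-subject outcome tables (e.g. a study
supplement converted to CSV — see `table_schemas()`) through
`load_supplementary_outcomes()`; `reproduce_tables()` then builds the
baseline / pulmonary-function / MRI-outcome reports and the
deterioration–improvement classification. A full synthetic end-to-end run
is one call:

```r
run_demo("demo_out", seed = 1)   # simulate -> rasterize -> measure -> report
```

A thin CLI with `phantom | segment | measure | cohort | demo | schema`
subcommands is installed at `inst/scripts/diaphragm-mri.R`.

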