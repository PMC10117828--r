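# immunoscape

Spatial immune profiling of tumors from serial-section immunohistochemistry
(IHC). The package is aimed at computational pathology groups who have
per-slide cell-detection tables (e.g. QuPath exports) for a marker panel —
CD3, CD4, CD8, CD19, CD163 and cytokeratin (CK) — plus pathologist
annotations of the tumor core (TC) and invasive front (IF), and want
per-patient spatial immune parameters and their prognostic statistics.

## What it computes

For each patient with one slide per marker:

1. **Registration.** Each marker slide is aligned to the middle slide of the
   serial-section stack. Slides are rasterized to ~500 × 500 working-scale
   density images; a rigid step (normalized cross-correlation over
   rotation × translation) is followed by diffusion-regularized demons
   non-rigid registration, and the displacement field is interpolated back
   to full resolution to transfer every cell coordinate.
2. **Regions.** The invasive margin (IM) is the band within 100 µm of the
   IF; densities are reported for TC, IM and TC+IM (cells/mm²).
3. **Hotspots.** Slides are tiled into 1000 × 1000 pixel tiles (200 µm at
   0.2 µm/pixel); a tile is *effective* if at least half its area lies in
   the TC. The top three effective-tile densities are Hotspot1–3.
4. **Colocalization.** For markers *l* and *c* with tile proportions
   *p<sub>i</sub><sup>l</sup>* and *p<sub>i</sub><sup>c</sup>* over *R*
   tiles, the Morisita–Horn index

   MH = 2 Σᵢ pᵢˡ pᵢᶜ / (Σᵢ (pᵢˡ)² + Σᵢ (pᵢᶜ)²) ∈ [0, 1]

   is computed for all immune-marker pairs, CK against each immune marker,
   and CK against the pooled immune cells.
5. **Immunoscore.** CD3 and CD8 densities in TC and IM are converted to
   within-cohort percentiles; the Immunoscore is the mean of the four
   percentiles, dichotomized low (≤ 25) / high (> 25).
6. **Cohort statistics.** Student's t-tests between recurrence (ER/LR) and
   metastasis (DM/non-DM) groups for all 47 parameters; ROC (Youden)
   cutoffs; Kaplan–Meier/log-rank survival for DFS and OS; multivariate Cox
   models; and a rerun on the stage IIB/III subset.

A synthetic-cohort generator (Thomas-cluster point patterns with 2×
invasive-margin enrichment of lymphocyte markers, planted slide
misalignments, proportional-hazards survival) emulates a 68-patient cohort
so the whole pipeline is testable without patient data.

## Worked example

```r
library(immunoscape)

co  <- simulate_cohort(cohort_spec(n_patients = 20, seed = 7))
res <- run_pipeline(co, pipeline_config(registration = FALSE), stage_subset_run = FALSE)
res
#> Patients quantified: 20 (of 20; 0 failed)
#> Parameters per patient: 47
#> Group comparisons significant at p < 0.05: 9 of 47 (ER/LR), 4 of 47 (DM/non-DM)
#> Log-rank significant at p < 0.05: 6 (DFS), 2 (OS)

res$parameters[1:3, c("TC_CD3", "IM_CD3", "Hotspot1_CD3", "MH_CK_Immune", "Immunoscore")]
#> # A tibble: 3 × 5
#>   TC_CD3 IM_CD3 Hotspot1_CD3 MH_CK_Immune Immunoscore
#>    <dbl>  <dbl>        <dbl>        <dbl>       <dbl>
#> 1   611.   938.         2375        0.840        50
#> 2   577.   852.         1575        0.810        51.2
#> 3   587.   856.         1700        0.847        67.5
```

`TC_CD3`/`IM_CD3` are CD3⁺ densities in cells/mm² — note the ≈2× enrichment
in the invasive margin the generator plants; `Hotspot1_CD3` is the densest
effective tile; `MH_CK_Immune` is the tumor-versus-pooled-immune
colocalization (near 1 here because immune and tumor cells share the same
tumor region); `Immunoscore` is the averaged percentile (0–100).

With registration enabled (the default), each patient's six marker slides
are first aligned to the middle slide; on synthetic patients with planted
misalignments (≤10°, ≤50 µm translation, 20 µm smooth warp) the median
post-registration point-transfer error is ~1 µm at the default 500-pixel
working scale.

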