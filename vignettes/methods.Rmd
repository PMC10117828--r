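---
title: "Methods: spatial immune profiling of serial-section IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune profiling of serial-section IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its models and the design choices
behind them: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and the numerical decisions
that fix otherwise ambiguous behavior.

## The analysis model

The package consumes, per patient, one cell-detection table per marker
slide (positive-cell coordinates in micrometres, the shape of a QuPath
export scaled at 0.2 µm/pixel), a tumor-core (TC) polygon and an
invasive-front (IF) polyline. From these it derives 47 per-patient
parameters: 15 region densities (5 immune markers × TC, IM, TC+IM), 15
hotspot densities (5 markers × top-3 tiles), 16 Morisita–Horn (MH)
colocalization indices (10 immune pairs, 5 CK-versus-marker, 1
CK-versus-pooled-immune) and the Immunoscore.

### Registration

Serial sections are physically distinct slices, so each slide is misplaced
relative to its neighbours by a small rigid motion plus a smooth tissue
deformation. Slides are aligned to the *middle* slide of the stack (the
4th of 7), which minimizes the average section distance to the reference.
Because the package works from coordinate tables rather than stained
pixels, each slide is rasterized to a working-scale (default 500 × 500)
Gaussian-smoothed density image; the raster stands in for the scanned
image that image-based pipelines downsample to approximately the same
size.

Registration is two-step, both steps estimated at working scale:

* **Rigid**: exhaustive coarse-to-fine search over rotation (default
  ±12°, 1° coarse grid on 4×-downsampled images, 0.25° refinement with
  parabolic interpolation) with the translation obtained by FFT
  cross-correlation at each candidate angle, scored by normalized
  cross-correlation (NCC). If no candidate beats the identity, the
  identity is kept — registration never worsens similarity.
* **Non-rigid**: Thirion-style demons iterations with diffusion-like
  regularization (the displacement field is smoothed with a Gaussian of
  sd 8 working pixels each iteration, approximated by three iterated box
  filters). Iterations stop on relative-improvement tolerance 1e-4 with
  patience 5, keeping the best-so-far field, so the final dissimilarity
  never exceeds the initial one.

The estimated transform is *pull-back*: the reference raster plays the
moving image against the slide's raster, so the fitted map sends slide
coordinates into the reference frame and applies directly to the
full-resolution cell coordinates (bilinear interpolation of the
displacement grid; points outside the grid are clamped to the nearest
edge and counted). Composition is fixed: a point is first offset by the
interpolated demons displacement, then passed through the rigid
transform. Displacement grids are stored in micrometres internally;
constructors accept full-resolution pixels (converted at the configured
µm/pixel) because deformation fields are conventionally expressed at the
original image scale.

The similarity metric, the demons algorithm and the convergence rules are
this package's own choices; the two-step rigid-then-non-rigid order, the
~500-pixel working scale and the middle-slide reference are protocol
constants.

### Regions

The invasive margin is the set of points within 100 µm of the IF. The
band is symmetric by default — the protocol wording does not fix a side —
with `inner`/`outer` one-sided modes available. Likewise TC is the full
annotated polygon by default, so TC and IM overlap in the inner band; a
`disjoint_regions` switch excludes the inner band from TC. Neither choice
is claimed as the original intent; both are configuration.

Boundary conventions are fixed and documented: the TC polygon is closed
(a point on the boundary is inside), a point exactly on the IF is in both
TC and IM (distance 0), and tiles are half-open so every point belongs to
exactly one tile.

The TC area is exact (shoelace). The IM band of an arbitrary polygon has
no convenient exact polygonal representation without a computational
geometry library, so its area is integrated on a regular 4 µm grid
restricted to the band's bounding box; at the default geometry this is
accurate to well under 1% — negligible against the Poisson noise of the
counts it divides.

### Tiles, hotspots, Morisita–Horn

Tiles are 1000 × 1000 pixels (200 µm at 0.2 µm/pixel), anchored at the
slide-extent minimum, 0-based indices. A tile is *effective* when at
least half its area lies in the region; the tie at exactly one half
counts as effective. For the TC the tile∩polygon area is exact
(Sutherland–Hodgman clipping); for band-including regions it is a
deterministic 20 × 20 lattice estimate per tile. Hotspot densities use
the *nominal* tile area as denominator — the simplest reading of
"density per effective region" — and the top three are reported with
ties broken by ascending tile index; with fewer than three effective
tiles the missing ranks are NA rather than repeats.

The MH index is computed on per-tile proportions over the effective tiles
of TC+IM (configurable to TC): hotspot tiling is the only tiling the
protocol defines, so it is reused for colocalization. Multi-marker
colocalization is implemented as the pooled-class index (all immune cells
pooled, then MH against CK); no claim is made that this equals the
original multi-input expansion, which is not printed.

### Immunoscore

Percentiles are within-cohort, `100·rank/n` with mid-rank ties (the
cohort maximum maps to 100); a Hazen variant `100·(rank−0.5)/n` is
available. The Immunoscore is the mean of the four percentiles (CD3, CD8
× TC, IM), and the two-category rule applies to the averaged score:
low when ≤ 25, high above. The boundary is read as low-inclusive.

### Cohort statistics

Group comparisons are Student's t-tests (pooled variance by default,
Welch by option) between recurrence (ER/LR) and distant-metastasis
(DM/non-DM) groups, flagged at raw p < 0.05 with no multiplicity
correction by default — mirroring common practice of reporting raw
p-values across the 47 parameters — and Benjamini–Hochberg adjustment
behind a flag (recommended).

"Most discriminating threshold" is operationalized as the Youden point:
every midpoint between sorted unique values is evaluated in both
directions and the threshold maximizing sensitivity + specificity − 1 is
kept (ties toward the lower threshold); a closest-to-corner criterion is
available. DFS cutoffs are computed against the DFS event, OS cutoffs
against the OS event.

Survival is Kaplan–Meier with the two-sample log-rank test, and Cox
partial likelihood with Efron tie handling (monthly times produce ties).
Cox fits refuse rank-deficient designs and require more events than
covariates. Optimizing a cutpoint on the same endpoint that is then
tested is known to inflate the log-rank type-I error; the test suite
asserts this inflation on null cohorts, and a permutation-corrected
p-value (stratum labels permuted) is available via `permutation_p`.

The advanced-stage reanalysis retains stages IIB, IIIA, IIIB and IIIC and
reruns the identical statistical layer.

## The synthetic-cohort generator

The generator is first-class, tested code that defines the study
conditions for every downstream check:

* **Cohort**: 68 patients, six marker slides each (CD3, CD4, CD8, CD19,
  CD163, CK), 4 × 4 mm slide extent, tumor polygon a radially perturbed
  ellipse (~3–4 mm²) whose boundary is the IF.
* **Point process**: Thomas clusters — Poisson parents, Poisson(µ = 15)
  offspring scattered N(0, 50 µm) — thinned to the target intensity
  surface. Lymphocyte markers run at 2× intensity inside the IM band
  relative to the core (CD3 500, CD4 300, CD8 250, CD19 100 cells/mm² in
  the TC); CD163 (150/mm²) and CK (1500/mm²) are evenly distributed.
  The 2× band enrichment and the even CD163 distribution reproduce the
  reported cohort-level contrast; absolute densities and cluster scales
  are order-of-magnitude choices (none are published for this setting)
  and stay configurable.
* **Misalignment**: per non-reference slide, rotation uniform within
  ±10°, translation within ±50 µm, plus a smooth warp of three
  low-frequency sinusoidal components per axis totalling 20 µm — the
  bounds registration is expected to undo. The exact forward transform is
  retained so transfer error is measurable.
* **Survival**: exponential proportional hazards (Weibull by config) with
  linear predictor Σ log-HR × standardized true density (default −0.7 on
  TC CD3), death lagging relapse, independent exponential censoring
  calibrated to the configured censoring fraction plus a 120-month
  administrative cap. ER/DM flags derive from the observed events.

What the generator does **not** emulate: raster IHC pixel data, nuclear
morphology or segmentation error, batch staining variability,
marker-specific spatial interactions beyond shared geometry (each
marker's pattern is an independent realization given the intensity
surface), or non-proportional hazards. Passing tests therefore validate
the estimators' correctness under these assumptions — not the biological
claims on any real cohort.

## Problem sizes and numerical choices

The test suite and examples use problem sizes the package's own checks
set: a 68-patient structural run at full defaults, 50 seeded
registration-recovery trials (median point-transfer error < 10 µm is the
pass bound; typical medians are ~1 µm), 200-replicate Monte-Carlo checks
of the generator contract, 10,000 random distribution pairs for the MH
bounds, and 1000-instance brute-force oracles for hotspot ranking.
Numerical tie-breaks and degenerate-input behavior are fixed throughout:
empty patterns rasterize to zero images with a warning, flat images
return identity transforms, an empty-side MH index is NA with a warning,
regenerated geometry fails after 20 attempts, and a cohort with fewer
than two evaluable patients skips statistics with a recorded error.

## Known limitations

* Registration assumes the density rasters of two slides share structure;
  markers with very few cells (or disjoint spatial supports) give weak
  NCC signals, and the rigid fallback to identity is then the safe
  behavior.
* The IM area is numerically integrated; sub-percent area bias is
  possible for extremely tortuous fronts at the default 4 µm step.
* The MH tiling reuses the hotspot grid; indices are comparable across
  patients only at a fixed tile side (200 µm default).
* Cox models here record convergence but perform no proportionality
  diagnostics; competing risks and covariate imputation are out of scope.
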