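---
title: "Quantifying tissue tension from laser-ablation recoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue tension from laser-ablation recoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RecoilQuant)
```

## The measurement

When a line of epithelial tissue is vaporized by a pulsed laser, the tissue
on either side of the cut retracts. The speed of that retraction immediately
after the cut — before viscous dissipation damps it — is proportional to the
tension the tissue carried across the cut line, so the *initial recoil
velocity* (IRV) is a standard proxy for in-plane tissue tension. Cutting
along one embryonic axis reports tension along the orthogonal axis: a cut
along the rostral-caudal (RC) axis measures medial-lateral (ML) tension and
vice versa. Throughout this package the `orientation` label of a recording
refers to the axis of the *measured recoil*, not of the cut.

The measurement protocol implemented in `measureRecording()` is:

1. extract the pre-ablation frame (frame 2) and the first post-ablation
   frame (frame 3) of a 20-frame stack acquired every 0.416 s;
2. denoise both frames;
3. bring them into rigid-body register, so that whole-embryo motion
   (dominated by the heartbeat) is removed;
4. select three point pairs that are clearly visible in both frames
   (cell vertices), abut opposite edges of the ablation, and lie near the
   centre of the ablation path; plus control pairs *adjacent but parallel*
   to the cut (orthogonal controls) and *outside* the cut path (parallel
   controls);
5. measure the straight-line distance between the members of each pair
   perpendicular to the ablation path, in triplicate, before and after
   ablation;
6. average the three post-minus-pre changes and divide by the frame
   interval.

The controls estimate residual artifactual motion: their IRVs should
scatter around zero, and a recording is discarded as having severe movement
artifact when the absolute value of either control IRV exceeds the measured
IRV (`severeMovementCheck()`).

## The synthetic-data generator

No raw movies are publicly available for this assay, so the package ships a
first-class simulator whose output feeds every downstream stage. A
recording is generated as follows.

**Tissue.** `buildCellMesh()` tessellates the field into polygonal cells of
~6 μm mean equivalent diameter (the 36 μm ablation line spans six cell
diameters). We use a jittered hexagonal tessellation rather than a Voronoi
diagram: vertices of a calibrated hexagonal lattice are perturbed by a
small Gaussian jitter, giving irregular but simple polygons with
tricellular junctions, which is the property the vertex-detection step
relies on. No additional realism (cell-size dispersion, topology defects)
is attempted.

**Recoil.** The two cut margins retract with a saturating exponential
displacement per margin, \(d(t) = A\,(1 - e^{-t/\tau})\), an overdamped
Kelvin–Voigt-like response with default \(\tau = 1.5\) s. No relaxation
time is constrained by the assay itself, so \(\tau\) is a free simulation
knob; what *is* pinned down is the ground truth: the amplitude \(A\) is
solved so that the margin-to-margin separation increase over the first
post-ablation interval, divided by that interval, equals the configured
`v0` exactly. Ground truth is therefore defined on precisely the quantity
the estimator measures, which makes recovery tests independent of the
kinetic law chosen.

**Spatial profile.** The displacement field is uniform (a plateau, default
half-width 6 μm) on either side of the cut and decays exponentially
beyond; along the cut it is uniform over the cut length and attenuates to
zero beyond the ends. The plateau means any vertex pair abutting the cut
margins separates at exactly `v0`, and the along-cut uniformity means
orthogonal control pairs (same side, 2–6 μm offset) and parallel control
pairs (beyond the cut ends) carry *no* recoil signal by construction —
the property the control measurements assume. A field with an along-cut
gradient inside the cut would make the orthogonal controls recoil and
would put a kinetics-dependent bias into every recovery test; we
deliberately traded that realism away.

**Artifact.** Heartbeat motion is modelled as whole-frame rigid motion:
sinusoidal translation (default period 0.9 s, amplitude 1 μm, random phase
and direction per recording) plus a small sinusoidal rotation (default
0.2°) and optional linear drift. This matches the correction applied
downstream (rigid-body registration); non-rigid deformation is out of
scope.

**Imaging.** Frames are rendered at 0.21 μm/pixel: membrane edges are
drawn with a Gaussian point-spread (σ = 0.3 μm), tricellular junctions get
a modest intensity enrichment, the vaporized band (default 2 μm wide)
appears dark from frame 3 onward, and Poisson shot noise (gain 1 a.u.)
plus Gaussian read noise (σ = 2 a.u.) are added over a constant background
(10 a.u.) with membrane intensity 100 a.u. These are ordinary confocal
orders of magnitude; none of them is fitted to data.

**Cohorts.** `simulateCohort()` draws embryos (default 70% female,
matching the reported cohort imbalance), assigns each up to five ablations
across regions and orientations, and sets each ablation's ground truth to
the group mean plus a between-embryo random effect (`embryoSd`) plus
within-embryo noise (`withinSd`), truncated at zero — tension magnitudes
cannot be negative, though *measured* IRVs still can be. The default group
means are the reported ones: lateral folds anisotropic (female ML 3.77,
RC 2.73; male ML 3.45, RC 2.19 μm/s), midline isotropic (female 2.30,
male 2.57 μm/s).

What passing recovery tests on these simulations shows is that the
*measurement pipeline* is unbiased and well-calibrated under the stated
artifact and noise model. It does not validate the biological model, and
real recordings differ in ways the generator does not emulate: non-rigid
tissue motion, intensity inhomogeneity, bleaching, out-of-plane movement,
and recoil fields with genuine spatial gradients.

## Image processing choices

*Denoising* is Gaussian smoothing (σ = 1 px by default) behind a
documented contract — dimensions preserved, large-scale intensity order
preserved, exact shift-equivariance, no edge displacement. The original
protocol used a Poisson-wavelet denoiser as a black box; any filter
meeting the contract is acceptable here, and the downstream steps
(registration and normalized cross-correlation tracking) are deliberately
insensitive to the choice.

*Registration* estimates a rotation + translation by phase correlation
over a coarse rotation grid (±6°) on a 3-level image pyramid, refined by
masked Gauss–Newton least squares on intensities. By default the ablation
band dilated by 5 μm is masked out of the refinement so the recoil itself
cannot be "corrected away"; whether the original analysis masked the cut
region is unknown, so the mask can be disabled (`registerMask = "none"`).
Images are resampled bilinearly exactly once (when the post frame is
aligned); measurement points are always transformed analytically. In
tracks-only mode registration is a least-squares rigid fit (Kabsch) on the
parallel-control landmarks, which is exact for rigid artifact.

*Point selection* automates a manual, blinded step, so determinism matters
more than cleverness: candidate vertices are local intensity maxima with
quadratic subpixel refinement, tracked from pre to post frame by
normalized cross-correlation (template half-width 1.5 μm, search radius
2.5 μm) with quadratic subpixel peak interpolation; candidates with NCC
confidence below 0.4 are rejected. "Near the centre" is operationalized as
pair midpoint within the central third of the path; "adjacent but
parallel" as a 2–6 μm lateral offset. Pairs are ranked by match
confidence, then proximity to the path centre, then lexicographic
position, and the triplicate uses three *distinct* pairs when available
(controls with fewer candidates re-measure the same pair). Fewer than
three valid recoil pairs is a flagged error, never a silent drop.

*Δt convention.* The ablation occurs at an unknown instant between frames
2 and 3; following the stated protocol we divide by the full frame
interval (0.416 s). The generator defines ground truth under the same
convention, so the choice cancels in recovery tests; on real data it makes
IRV a slight underestimate of the instantaneous post-cut velocity.

## QC and statistics

Exclusion reasons are: ablation outside the admissible regions, unknown
sex or somite stage, bubbles in the ablation path (an upstream annotation;
no detector is implemented), severe movement (|control| strictly greater
than the signed IRV; exact ties are kept), and insufficient landmarks.
Severe movement is evaluated per ablation by default; the stricter
per-embryo reading (`severeMovementScope = "embryo"`) is available because
the protocol wording supports either.

Comparisons use an F-test gate at p = 0.05: variance homogeneity not
rejected → pooled-variance Student t; rejected → Welch t with
Welch–Satterthwaite df. The F-test is two-sided (larger variance in the
numerator, upper tail doubled, capped at 1); with one degenerate
zero-variance sample the gate goes to the Welch branch (p → 0), with both
degenerate it stays pooled (p = 1). All t-tests are two-sided. No
multiple-testing correction is applied, matching per-comparison reporting
(`fdr = TRUE` adds Benjamini–Hochberg columns). Significance classes:
p > 0.05 `n.s`, p < 0.05 `*`, p < 0.01 `**`. Percent differences are
always larger-vs-smaller mean, displayed rounded to the nearest integer
and stored at full precision. The sex-ratio balance test is a df = 1
goodness-of-fit chi-square against 50:50 without continuity correction
(Yates correction available via `correct = TRUE`). Somite stages are
binned ≤7, 8–9, ≥10 (embryos beyond 10 somites cannot be ablated in this
mounting) and compared pairwise. Ablations are treated as independent
units, as in the source analysis; a mixed-effects treatment of the
embryo-level correlation is an explicit non-goal.

## Problem sizes and numerical tolerances

The default cohort field is 64 μm (≈ 305 px at 0.21 μm/px), which
contains the 36 μm cut, both control bands and registration margin; the
standalone rasterizer default is 512×512 px. Test-suite recovery runs use
100 recordings per group mean (50 embryos × 2 ablations, `embryoSd` 0,
`withinSd` 0.3), where the measurement pipeline's per-recording error is
≈ 0.04 μm/s (sd) with negligible bias, against a ±5% acceptance band.
Registration is required to recover random rigid motions within 0.2° and
0.3 px in ≥95% of noisy trials. Point transforms invert to < 1e-6 px;
statistical branches match textbook formulas to 1e-10. Degenerate inputs
(featureless frames, blank fields, empty cohorts, n < 2 groups) raise
classed errors rather than propagating NaNs; a planned comparison with an
undersized group is emitted with status `insufficient-data` instead of
failing the run.

## A worked cohort

```{r, eval = FALSE}
cfg <- simulationConfig(nEmbryos = 20, ablationsPerEmbryo = 3,
                        renderImages = FALSE, seed = 7)
out <- runAll(cfg, "run1")          # simulate -> measure -> qc -> stats
read.csv(file.path("run1", "comparisons.csv"))
```

`runAll()` writes every intermediate table as CSV plus a JSON manifest of
md5 digests; re-running with the same config and seed reproduces identical
digests for all non-image outputs. Measurement is blinded by default: the
recordings are processed in shuffled order with group labels stripped, and
labels are re-joined only afterwards.

## Known limitations

- The recoil spatial profile is idealized (plateau + exponential decay);
  real strain fields have gradients that make control placement a genuine
  experimental skill rather than a geometric rule.
- Tracks-only mode is exact by construction and is used to test the
  arithmetic of the pipeline, not its robustness; image mode carries all
  the realism the generator has.
- Full 20-frame registration and recoil-curve fitting (estimating τ) are
  out of scope; only the frame-2/3 pair feeds the IRV.
- Real-mode ingestion (`readRecording()`) accepts TIFF stacks plus a
  geometry table but has only been exercised on simulated stacks.
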