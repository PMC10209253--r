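---
title: "Bone-metastasis auto-segmentation from FDG-PET/CT: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-metastasis auto-segmentation from FDG-PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoseg)
```

## The procedure and its assumptions

`osteoseg` automates a simple but clinically motivated idea: PET-avid bone
metastases can be found by an *absolute* SUV threshold, provided the search
is restricted to the skeleton so that physiologically hot organs (bladder,
kidneys, liver, brain, myocardium) cannot masquerade as lesions. The
pipeline is deterministic end to end — same inputs and configuration give
byte-identical outputs — which is the property that makes it useful as a
research instrument for threshold studies.

The stages and their assumptions:

1. **Body-weight SUV.** We assume the PET volume is reconstructed activity
   concentration in Bq/ml, decay-corrected to scan acquisition start (the
   common vendor convention; the `DecayCorrection` tag is honoured when
   present and assumed `START` otherwise — whether any given dataset was
   corrected to series time instead cannot be decided by this package and
   is deliberately left to the tag). The conversion is the universal
   single-exponential body-weight form
   $\mathrm{SUV}_{bw} = C \cdot 1000\,W / (D\,2^{-\Delta t/T_{1/2}})$
   with $\Delta t$ the injection→acquisition interval. Times crossing
   midnight are wrapped once (+24 h); a residual negative interval is an
   error, not a silent fix. The 1 g/ml tissue-density convention makes
   SUV dimensionless; lean-body-mass and body-surface-area variants are
   out of scope.
2. **CT on the PET grid.** PET and CT are co-acquired on one scanner, so no
   registration is performed — only resampling. The kernel is cubic
   convolution with $a=-0.5$ (the classic "bicubic"), applied separably
   in-plane. Two index conventions are provided: `physical` maps voxel
   centres through `origin + index·spacing` (the correct general choice,
   and the default), `matrix` reproduces plain matrix resizing as an
   `imresize`-style compatibility mode. When slice counts differ, linear
   interpolation onto the PET slice positions is applied along z first —
   a generalisation of the matched-slice-count assumption rather than an
   error, since nothing else is physically sensible for co-acquired data.
   Bicubic overshoot at bone/air edges is clamped to the input range by
   default so it cannot leak voxels into the bone mask.
3. **Bone mask.** Threshold at 110 HU by default: low enough to include
   marrow, high enough to exclude soft tissue. Because a thresholded mask
   has a jagged, noise-sensitive boundary, the *binary mask* is blurred
   with a Gaussian (σ = 1 voxel per axis by default, configurable in mm)
   and re-binarised at 0.5 — this regularises the edge without biasing it,
   since 0.5 is the level-set midpoint. Hole filling then claims marrow
   cavities enclosed by cortical shell; it runs per axial slice by default
   (a 2-D cavity in a vertebral cross-section is a hole even when the 3-D
   cavity opens through the end plates), with a 3-D option. A utility
   (`suggest_hu_threshold()`) picks the threshold of maximal mask-volume
   stability across 90–300 HU as a reproducible surrogate for visual
   tuning; it is a convenience, not a validated substitute.
4. **Lesions.** `SUV ≥ SUV-Th` within bone, 26-connected components.
   The comparison is inclusive: whether a boundary voxel exactly at the
   threshold belongs to the lesion is otherwise undefined, and an explicit
   convention keeps the matcher deterministic. 26-connectivity merges
   diagonally touching uptake, the usual PET practice; 6-connectivity is
   available. No minimum lesion size is imposed by default (min_voxels = 1);
   real noisy data may warrant 2–3 voxels. SUVmax ties resolve to the
   smallest column-major voxel index.

## Validation design

- **Matching.** The requirement "minimum SUVmax difference and minimum
  Euclidean distance" does not by itself define a matcher (two minima can
  disagree). We implement a greedy one-to-one matching on the weighted cost
  `d/10 mm + |ΔSUVmax|/1 SUV`, with a 20 mm distance gate; ties break to
  the lower reference label, then the lower auto label. The scales mean
  "1 SUV of difference costs as much as 10 mm of displacement" — sensible
  for 2–3 mm PET voxels — and the gate stops absurd cross-body pairings.
  This is a documented design choice, not a verified reconstruction of the
  reference procedure.
- **Specificity domain.** True negatives counted over the whole image
  saturate specificity trivially (the body is mostly not lesion). The
  default evaluation domain is therefore the bone mask — the stricter and
  more informative choice — with `domain = "whole"` available.
- **Concordance** is Pearson r ("regression analysis" semantics). With
  fewer than two matched pairs, or degenerate variance, it is reported as
  `NA` — a single-lesion patient has no defined correlation — rather than
  a silent `NaN`; `concordance_r()` errors loudly in that case.
- **DSC aggregation** per threshold is median + IQR over matched pairs,
  matching boxplot semantics; `dice()` returns 1 for two empty masks (two
  raters who both found nothing agree perfectly).
- **Optimum threshold** is the argmax of sensitivity + specificity over the
  sweep grid {2.0, 2.5, 3.0, 3.5, 4, 6}; ties break toward higher median
  DSC, then toward the lower threshold (prefer sensitivity when the ROC
  cannot distinguish).
- **Audit.** Unmatched lesions are reported per side (`auto_only` /
  `ref_only`) with volume, SUVmean and SUVmax, reproducing the typical
  missed-lesion analysis: ref-only lesions with SUVmean below the threshold
  are *structurally* undetectable by an absolute-threshold algorithm, and
  ref-only lesions outside the bone mask point at the HU threshold, not at
  the SUV threshold.

## What the phantom emulates — and what it does not

The generator builds a scaled-down whole-body study: a 64×64×48 PET grid at
the clinical voxel size 2.7344×2.7344×3.27 mm (voxel volume 0.02445 ml) and
a CT at twice the in-plane resolution (the clinical 512→256 ratio), a
soft-tissue body (40 HU), a spine-like bone cylinder (cortical 700 HU,
marrow 50 HU), hot organs outside bone (SUV 5–8), spherical lesions with
uniform SUV plateaus planted inside bone, and additive Gaussian noise
(defaults σ = 0.1 SUV, 10 HU). PET is stored as activity back-converted
through the same SUV factors the reader extracts, so the DICOM round trip
is self-consistent. A fixed seed makes every volume bit-reproducible, and
the session RNG state is restored afterwards.

It deliberately does **not** model scanner physics: no point-spread
function, scatter, reconstruction artefacts, Poisson count statistics,
respiratory motion, or heterogeneous lesion texture. Consequently a green
phantom test establishes *algorithmic* correctness — geometry, bookkeeping,
formulas, determinism, threshold logic — but not clinical performance:
partial-volume effects at real lesion boundaries, marrow-uptake confounds
and inter-patient HU variability are all absent. The headline clinical
metrics (volume concordance ≈ 0.99, DSC ≈ 0.6–0.7, sensitivity ≈ 65 %)
cannot be reproduced without the patient cohort and are not asserted
anywhere in the test suite; on the phantom, where lesions are uniform
plateaus strictly above threshold, perfect recovery is the *expected*
outcome and is what the acceptance criteria check.

## Numerical choices and degenerate inputs

- Voxel indices are 0-based in all physical-coordinate formulas
  (`mm = origin + index · spacing`); lesion tables report both.
- The contour rasteriser uses the voxel-centre-in-polygon even-odd rule;
  overlapping structures resolve later-structure-wins. Polygons are
  assigned to the nearest slice.
- DICOM: only Explicit VR Little Endian is read and written. PET pixel
  data use the standard Double Float Pixel Data element, making PET
  write→read bitwise exact; CT uses signed 16-bit with rescale tags (HU
  rounded to integers on write). The codec covers the tag subset this
  pipeline needs and is not a general DICOM implementation.
- NIfTI volumes are stored as float64 (lossless); units and SUV factors
  travel in a JSON sidecar because the NIfTI-1 header has no such fields.
  A missing sidecar degrades to declared default units with a warning.
- Empty label maps quantify to an empty table; empty lesion lists match to
  empty pairings; an empty threshold list is a parameter error.
- The 64×64×48 default grid keeps the full test suite around ten seconds;
  clinical-scale grids (256×256×311) are supported by the same code paths —
  nothing in the implementation assumes the small size.

## Known limitations

- Lesions infiltrating beyond the bone mask are invisible by construction
  (region growing from SUVmax seeds would be the natural extension and is
  intentionally out of scope).
- Percentage-of-SUVmax thresholding is not implemented.
- The matcher's cost scales (10 mm, 1 SUV, 20 mm gate) are package
  defaults, not empirically optimised values.
- The DICOM reader expects one series per directory and uniform slice
  spacing; it refuses mixed or gapped series rather than guessing.
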