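---
title: "Methods: per-cell γH2AX/CC3-blebbing quantitation"
author: "blebquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell γH2AX/CC3-blebbing quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay model

The pipeline quantifies, per image field, the fraction of cells positive
for four per-cell calls on three-channel fluorescence fields
(DAPI / CC3 / γH2AX):

* **cytoplasmic CC3⁺** — mean CC3 intensity over the cell's perinuclear
  ring mask strictly above a threshold;
* **CC3(bleb)⁺** — at least 2 CC3 puncta (thresholded 8-connected spots
  with area in [0.2, 5] µm²) inside the ring mask; this is the
  high-specificity apoptosis call, because punctate (not diffuse) CC3
  accompanies apoptotic membrane blebbing;
* **γH2AX⁺** — mean nuclear γH2AX intensity strictly above an automatic
  threshold; positivity marks DNA double-strand breaks;
* **colocalization⁺** — γH2AX⁺ ∧ CC3(bleb)⁺, interpreting the cell's
  γH2AX as apoptosis-associated DNA fragmentation rather than direct
  drug-induced damage.

Group contrasts use two-sided Mann-Whitney U tests on the per-field
percentages. Fields (not animals or specimens) are the default
statistical unit; any grouping key can be substituted upstream by
relabelling the summaries. No multiple-testing correction is applied:
contrasts are reported per comparison, as is conventional for
pharmacodynamic assay readouts, and the caller is responsible for
family-wise interpretation.

### Mean- vs integrated-intensity positivity

Both nuclear and ring calls use *mean* intensity, not integrated
intensity, so a call does not depend on nuclear size within the 50–200
µm² retention window.

## Geometry

**Segmentation** (`segment_nuclei`) is deliberately classical and
deterministic: Gaussian smoothing (`smooth_sigma`, default 1 px), Otsu's
global threshold on the smoothed DAPI raster, hole filling, Euclidean
distance transform, watershed with tolerance `watershed_tolerance`
(default 2 distance-map units) to split touching nuclei, 8-connected
labelling. A flat or empty raster yields zero nuclei rather than an
error. Area filtering (`filter_nuclei_by_area`) retains nuclei with
`min ≤ area ≤ max` (inclusive bounds, defaults 50 and 200 µm²) and only
removes labels — it never reassigns pixels — so it is idempotent and
order-independent.

**Ring masks** (`make_cytoplasm_rings`) simulate cytoplasm: for each
retained nucleus, the background pixels whose centre-to-centre Euclidean
distance to that nucleus is at most the ring width, and for which that
nucleus is the nearest one. Distances are computed in *exact integer
squared pixel units* (compiled routine), which makes width cutoffs and
ties reproducible: a pixel equidistant from two nuclei goes to the lower
label. Rings are therefore pairwise disjoint, never overlap any nucleus,
and are monotone in width for isolated cells. Cells whose ring is empty
(e.g. a nucleus filling the frame) are flagged unevaluable and excluded
from denominators with an auditable count, rather than silently scored.

**Automatic ring width** (`auto_select_ring_width`): the assay
prescribes a 1–5 µm dilation chosen per specimen. The rule implemented
here selects the *largest* width w ∈ {1, …, 5} µm such that the median
per-cell fraction of ring pixels contested by a neighbouring nucleus
(within w of two nuclei) stays below 20 %. Wide rings maximise
cytoplasmic sampling; the contested bound limits cross-cell
contamination, so the width shrinks automatically as nuclei crowd
together. If no candidate width satisfies the bound the minimum (1 µm)
is used.

## Spot detection

`detect_cc3_puncta` thresholds the CC3 raster (strict `>`), restricts
the mask to the union of ring masks, labels 8-connected components, and
retains components with area in `[min_spot_area_um2, max_spot_area_um2]`
(defaults 0.2 and 5 µm²; `expected_spot_area_um2 = 0.9` µm² documents
the characteristic punctum size). Each punctum is assigned to the cell
whose ring contains its rounded centroid, with a majority-overlap
fallback. Detection defaults to direct thresholding so that its output
is *exactly* the threshold → connected-components → area-filter
computation, which the test suite verifies against an independent
brute-force oracle; a difference-of-Gaussians band-pass tuned to the
expected spot area is available (`spot_params(bandpass = TRUE)`) for
noisy material, at the cost of that exact equivalence.

A consequence of the upper area bound worth knowing: the number of
detected puncta is **not** globally monotone in the intensity threshold.
At a threshold below the diffuse cytoplasmic level the whole diffuse
region forms one giant component that the 5 µm² bound rejects; raising
the threshold fragments it into countable spots. Mean-intensity calls
and the `min_puncta` rule are monotone unconditionally; spot-count
monotonicity holds (and is tested) on puncta-only signal at thresholds
at or above background. Operationally the spot threshold must sit above
the diffuse cytoplasmic CC3 level — the automatic background rule
(`median + k·MAD` of pixels outside nuclei and rings, k = 6) is
appropriate only when diffuse CC3 is absent.

## Thresholds

Intensity thresholds are applied on the native integer scale (no
normalisation at I/O time), so configured values are directly
interpretable against the camera's 16-bit range.

The automatic γH2AX threshold (`auto_threshold_gh2ax`) performs a
deterministic two-class, within-class-variance-minimising split of the
per-nucleus means (an Otsu-style rule on the means, evaluated at every
sorted split point; ties resolve to the earliest split). The split is
accepted only when the between-class separation is at least
`min_separation = 4` pooled within-class standard deviations. The factor
4 is chosen because the optimal cut of a *pure Gaussian background*
already produces a separation near 2.6 pooled SDs — a factor of 2 would
accept almost any unimodal sample and call roughly half the cells
positive — while genuinely bimodal samples at the signal-to-background
ratios this assay needs (≥ 10×) produce ratios an order of magnitude
larger. When the split is rejected the threshold falls back to the
sample maximum, so an all-negative field reports exactly 0 % positive
instead of a spurious percentile tail.

## Statistics

`mann_whitney` uses the exact permutation null when the smaller group
has ≤ 8 observations and the pooled data are tie-free, and the tie- and
continuity-corrected normal approximation otherwise; the boundary is
pinned because typical designs (6–13 fields per group) straddle
exactness feasibility. The U statistic satisfies U + U′ = n₁n₂ and the
p-value is symmetric in the group order. Star annotations use strict
inequalities (ns at exactly p = 0.05). With n = 6 vs 6 and complete
separation the exact two-sided p is 2/924 ≈ 0.00216 — the floor for that
design — which is why at least six fields per specimen are analysed.

## The synthetic-field generator

`generate_field` renders fields that emulate the assay's phenotypes
with exact ground truth:

* **Nuclei**: non-overlapping ellipses (aspect ratio 1–1.3, uniform
  orientation) with areas uniform in 50–200 µm², placed on a jittered
  grid whose pitch guarantees a ≥ 3 µm border gap; requesting more cells
  than the grid holds is an explicit "unplaceable density" error.
* **Classes**: exact counts (`round(frac · n)`), with the colocalized
  set contained in both the γH2AX⁺ and bleb⁺ sets by construction;
  diffuse-CC3 positivity is sampled independently.
* **Signals**: pan-nuclear γH2AX and nuclear DAPI at
  `signal_to_background` (default 20) times the background level
  (default 500); diffuse CC3 over a 0–5 µm perinuclear band; puncta as
  uniform-intensity blobs of exactly `round(area/pixel-area)` pixels at
  3× the diffuse amplitude, centred 0.8–2.2 µm outside the nuclear
  border, mutually separated by a guard halo so connected-component
  counts equal the truth. Diffuse signal and puncta are rendered only on
  pixels whose *nearest* nucleus is the owning cell, so neighbouring
  cells' ring measurements are not contaminated.
* **Decoys**: distractor spots of 0.1 and 6.0 µm² (outside the filter
  window) in a configurable fraction of cells.
* **Noise**: additive Gaussian noise (default SD 50), then clipping to
  the 16-bit range.

The default calibration is 0.4 µm/px: at that pitch a single pixel is
0.16 µm², so the sub-resolution 0.1 µm² decoy renders as a one-pixel
spot that the 0.2 µm² bound always rejects, and the 6.0 µm² decoy
rounds to 6.08 µm² above the upper bound. Uniform-intensity (flat-top)
puncta were chosen over soft-edged profiles so the true spot area is
exact under any threshold between background and amplitude — with a soft
skirt, detected area would depend on the threshold and the ground truth
would no longer be sharp.

What the generator does **not** emulate: tissue autofluorescence and
texture, out-of-focus light, stain spectral bleed-through, macrophage
("starry-sky") morphology, nuclear crowding beyond the guaranteed-gap
regime, and focal (as opposed to pan-nuclear) γH2AX patterns. Passing
recovery tests on these fields therefore demonstrates correctness of
the *measurement chain*, not robustness to every property of real
tissue; on tissue, thresholds and segmentation parameters still require
specimen-level review.

## Conventions and degenerate inputs

* Coordinates are 1-based `(row, column)` with inclusive extents,
  matching R's matrix idiom; `extract_tile` takes a 1-based origin and a
  size and refuses out-of-bounds rectangles instead of clipping.
* The reference instrument's printed scan resolution ("0.4622
  µm²/pixel") is ambiguous between pixel area and linear pitch; the run
  configuration accepts either (`calibration_unit: linear` (default) or
  `area`, the latter taking the square root), and nothing is guessed
  silently.
* Zero evaluable cells in a field is an error in `summarize_field` and
  an excluded-and-logged field in `run_assay` — never a silent 0 %.
* A zero γH2AX⁺ count makes the conditional "% of γH2AX⁺ cells that are
  bleb⁺" `NA`, not 0.
* All randomness flows from explicit seeds; per-field seeds in a study
  derive deterministically from the master seed, and repeated runs are
  bit-identical (the tests compare output file checksums).

## Problem sizes used by the test suite

Unit tests run on 600–760 px fields with 20–120 cells. The
ground-truth recovery checks use 500-cell fields (1230² px at 0.4
µm/px) at marker fractions of 5, 10 and 20 %, asserting per-field
recovery within 2 percentage points for all four calls. The packaged
full-scale study (`inst/extdata/study_demo.yaml`) is 2 groups × 6
fields × 1350 cells (> 15,000 analysed cells), mirroring the assay's
per-specimen analysis scale, and is checked for bit-identical re-runs
and a significant (p < 0.01) 1 % vs 20 % colocalization contrast.

## Known limitations

* The nuclear segmentation recipe and the automated ring-width rule are
  declared substitutes for proprietary tooling used in the assay's
  original deployment, not reconstructions of it.
* Global Otsu thresholding assumes reasonably uniform illumination;
  strongly vignetted fields need flat-field correction upstream.
* Puncta ownership by centroid can, in principle, assign a spot
  straddling two rings to either cell; with the ≥ 3 µm border gaps the
  generator guarantees this is not exercised, but densely packed tissue
  may behave differently.
* Field-level statistics treat fields as exchangeable; animal- or
  specimen-level nesting (mixed models) is out of scope.
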