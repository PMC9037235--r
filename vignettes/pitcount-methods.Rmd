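---
title: "Automated pitted red blood cell counting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pitted red blood cell counting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pitcount)
```

## The biomarker

Pits are membrane-bound vacuoles of red blood cells (RBCs) that a
working spleen removes from circulation; under differential interference
contrast (DIC) microscopy they appear as rounded, crater-like surface
depressions. The percentage of RBCs bearing at least one pit — the PIT
count, or %PIT — is a validated surrogate of splenic filtration
function: classically, %PIT ≥ 3.5 indicates loss of splenic function,
and in sickle cell anaemia %PIT < 1.2 predicts normal and %PIT > 4.5
absent splenic function. Manual counting (at least 500 consecutive RBCs
per sample) is laborious and observer-dependent; `pitcount` implements
an automated workflow:

1. pixel classification of a DIC image into background / cell / pit;
2. macro-style object analysis (hole filling, distance-transform
   watershed, size / edge / solidity gates, per-cell pit counting);
3. sample-level aggregation (%PIT, pit morphometrics, splenic-function
   call);
4. method-comparison statistics to judge automated counts against
   manual ones.

Because no public image set accompanies this problem, the package ships
a synthetic DIC scene simulator with exhaustive ground truth, and every
stage is validated against it.

## The simulator

`sample_scene()` places `n_cells` biconcave discs (Evans–Fung thickness
profile, radii uniform in `cell_radius_um_range`, default 3–4 µm) in a
frame without mask overlap, except a configurable fraction (default
10%) placed tangent to a neighbour to exercise watershed separation.
Each cell is pitted with probability `pitted_fraction`; a pitted cell
receives `1 + Poisson(mean − 1)` pits — hemispherical craters with radii
uniform in `pit_radius_um_range`, centres kept at least one pit radius
inside the rim, pairwise separated so every pit is its own connected
component. The default pit radii (0.2–0.4 µm) put the mean pit size
around 0.6–0.8% of the parent cell's area, matching the size class
reported for clinical material (0.21–0.76%).

Confounders are opt-in through `artefact_rates` (expected counts per
scene, Poisson-distributed), emulating the failure modes seen in real
preparations: platelets adjoining a cell, fused platelet aggregates
(low solidity), large textured white blood cells, wrinkled cells with
ridged relief, and small debris specks abutting cells. In the truth
label map all object pixels are coded `cell` and pit pixels `pit`:
confounders are deliberately *not* given their own class, reproducing
the situation in which the pixel classifier cannot distinguish them and
the downstream object filters must.

`render_dic()` converts the scene's physical height map (µm) into a
DIC-like image: `intensity = 0.5 + gain × ∂h/∂s` along the shear axis
(default 45°), with the gain fixed so a default cell rim spans roughly
0.3 intensity units, followed by isotropic defocus blur
(`defocus_sigma_px`, default 1 px) and additive Gaussian noise
(`noise_sigma`, default 0.02). This reproduces the shadow-cast relief
appearance that the classifier must learn; it is *not* a physical
optics model (no polarisation or prism modelling), and passing tests on
it demonstrates the pipeline's correctness and internal consistency,
not performance on any particular microscope.

## Pixel classification

The segmentation contract is only "pixel → {background, cell, pit}".
`pit_classifier()` fills it with a classical, fully reproducible stack:
a multi-scale filter bank (Gaussian-smoothed intensity, gradient
magnitude, Laplacian, both Hessian eigenvalues, local variance at
scales {1, 2, 4, 8} px — 24 planes) feeding a random forest
(`ranger`; defaults 80 trees, depth ≤ 24, single-threaded for exact
reproducibility). A pretrained-CNN feature extractor would fit the same
contract and is an extension point, not a default.

Class imbalance is handled by a stratified per-class pixel cap (default
10,000 px/class/image) rather than weighting. Within the cell class,
half of the cap is reserved for the *rim band* (cell pixels within 2 px
of background): the steep rim relief is the feature signature most
easily confused with pit crater rims, and sampling it densely as a hard
negative removes most rim false-positive pits. Out-of-bag per-class
accuracy is stored in the fitted object as a training diagnostic.

Prediction takes the posterior argmax per pixel; ties break towards the
fixed class order background < cell < pit. Defocused images degrade
gracefully — the simulator's `defocus_sigma_px` exists precisely to
characterise the known failure mode in which pits vanish from
out-of-focus images; no special handling is attempted.

## Macro-style object analysis

`analyze_labels()` mirrors the classical ImageJ treatment of a
three-channel segmentation:

* **split** — the cell mask is the union of codes 1 and 2 (pits are
  part of their cell), the pit mask is code 2 alone;
* **fill holes** — interior background components become foreground
  (pit pixels were merged into the cell mask first, so pits never read
  as holes);
* **separate** — Euclidean distance transform, peaks shallower than
  `watershed_h` (default 2 px) suppressed, watershed of the inverted
  distance map restricted to the mask; instances renumbered by centroid
  for deterministic output;
* **measure** — per instance: area (µm² via the squared pixel size),
  solidity (pixel area over the pixel count of the filled convex hull
  of pixel centres, tolerance 1e-9 on the ≤ 1 invariant), centroid
  (0-based, row-major), border contact, and pits (connected components
  of the pit mask inside the instance with ≥ `min_pit_area_px` pixels,
  8-connected by default);
* **filter** — statuses assigned with precedence size → edge →
  solidity; records are flagged, never deleted.

Defaults and their reasoning:

| parameter | default | rationale |
|---|---|---|
| size gate | 20–80 µm² | brackets a 6–8 µm disc (≈28–50 µm²) with margin for segmentation bleed; removes platelets (<5 µm²) and most white cells (>90 µm²) |
| `min_solidity` | 0.90 | separates convex cells (≈1.0) from fused aggregates and debris-carrying cells; the filter's *direction* (it can only lower %PIT on pit-free scenes) is what the acceptance suite checks, not the constant |
| `min_pit_area_px` | 8 | below the smallest genuine pit at both 0.065 µm/px (≥30 px) and 0.1 µm/px (≥13 px) working resolutions, above typical noise specks |
| `watershed_h` | 2 px | merges distance-map peaks produced by rim roughness while keeping genuinely adjoining cells separable |
| connectivity | 8 | the classical particle-analysis default |

"Counting maxima of the segmented pits" is implemented as connected
-component counting of the binary pit mask (components *are* the maxima
of a binary segmentation); an intensity-maxima variant with a noise
tolerance would be a faithful alternative reading and remains open.

## Sample metrics and diagnosis rules

The %PIT denominator is the *included* cells only; a cell is pitted iff
it has ≥ 1 counted pit. Empty denominators yield an explicit `NA`
rather than a silent zero. The `sufficient_count` flag compares the
denominator against the classical minimum of 500 cells. "Average pit
size as % of the affected cell" is averaged **per pit** by default
(each pit contributes its own area fraction); `pit_size_average =
"per_cell"` switches to first averaging within each pitted cell —
either reading matches the phrase, and the choice is a configuration
switch, not a constant.

`classify_splenic_function()` implements both published threshold rules
verbatim, with boundary values sitting exactly where the printed
inequality signs put them: Rogers (≥ 3.5 → loss of function) and
El Hoss (< 1.2 normal, > 4.5 absent, otherwise indeterminate). The
rules are not refitted to automated counts, although automated counts
run slightly high at low %PIT and normal ranges may eventually deserve
re-evaluation.

## Agreement statistics

`bland_altman()` takes differences as automated − manual, so a positive
bias means the automated method counts higher. Limits of agreement are
bias ± 1.96 SD; the bias CI uses `t(n−1)·sd/√n` and each LOA CI the
classical approximation `t(n−1)·sd·√(3/n)` (the exact-variance
alternative is known but not the default). Acceptance bounds are
stratified as in the validation study design: ±5 percentage points
overall, ±1.5 for samples with manual %PIT < 5. `paired_t_test()` and
`pearson_r()` delegate to `stats::t.test()`/`stats::cor.test()`;
`consensus_map()` sums observer masks pixel-wise (0..k).

## Numerical and design choices

* **Determinism.** Every stochastic step flows from one integer seed:
  scene draws, noise, pixel sampling, forest growth (single-threaded
  `ranger` with a fixed seed). Re-running a pipeline at a fixed seed is
  byte-identical, which the test suite asserts on output files.
* **Tie-breaks.** Posterior argmax ties go to the lower class code;
  watershed ridge pixels follow the flooding order of the seeded
  watershed; instance ids are assigned by centroid (row, then column).
* **Degenerate inputs.** Zero-cell scenes, all-background maps, empty
  tables, zero-variance differences and constant correlation inputs all
  return explicit markers or named errors rather than propagating NaN.
* **Connected components.** Written in-package (label propagation to a
  fixed point) because the available labelling routine is 4-connected
  only and the macro contract defaults to 8-connectivity.
* **Hole filling and watershed** are delegated to EBImage (`fillHull`,
  `distmap`, `watershed` with its tolerance as the merge depth), the
  same contract as the MorphoLibJ distance-transform watershed; both
  are cross-checked against brute-force oracles in the tests.

## Problem sizes used by the test suite

The packaged experiments run at 0.1 µm/px (cells ≈ 60–80 px across,
pits ≥ 13 px), a resolution at which every structure keeps a faithful
pixel footprint while scenes stay desk-scale; the default configuration
is 0.065 µm/px, the physical pixel size of a ×100/1.46 oil objective
with a typical sCMOS camera. The end-to-end recovery experiment trains
on six 800×800 px scenes of 50 cells (30% pitted) and counts six
held-out scenes (300 RBCs), requiring pooled automated %PIT within ±3
percentage points of the simulated truth, held-out cell IoU ≥ 0.85 and
pit IoU ≥ 0.4 — package acceptance floors, not literature values.
The truth-passthrough experiment feeds five 50-cell truth label maps
through the macro and requires exact recovery of every per-cell pit
count.

## Known limitations

* The rendered images are a geometric caricature of DIC; absolute
  classifier performance on real micrographs requires training on real
  annotated images (the training interface accepts any image/label
  pairs).
* Pit-size and cell-size defaults are plausible for the cited clinical
  ranges but not fitted to calibrated measurements — no µm calibration
  of pits is published.
* At the simulated artefact geometries, platelet aggregates are usually
  removed by the *size* gate (watershed fragments of a few µm²) before
  the solidity gate acts; the solidity filter's distinctive victims are
  merged platelet-on-cell and debris-on-cell objects. The acceptance
  suite therefore checks the filter's direction, not a specific
  magnitude.
* Observer-consensus tooling operates on provided annotation masks; the
  package does not model annotator behaviour.
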