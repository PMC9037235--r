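# pitcount

Automated counting of pitted red blood cells (RBCs) in differential
interference contrast (DIC) microscopy images.

## The problem

The spleen grooms circulating RBCs, removing membrane-bound vacuoles
("pits"). When splenic filtration fails — after splenectomy, or early in
life in sickle cell anaemia — pitted RBCs accumulate, and the percentage
of RBCs carrying at least one pit (**%PIT**) is a well-validated
surrogate biomarker of splenic function: classically %PIT ≥ 3.5
indicates loss of splenic function, and in sickle cell anaemia
%PIT < 1.2 predicts normal and %PIT > 4.5 absent splenic function.
Manual counts (≥ 500 consecutive RBCs per sample under DIC) are slow and
observer-dependent.

`pitcount` is an automated, fully reproducible replacement for the
manual count, aimed at haematology labs and method-comparison studies:

* **segment** — a trainable pixel classifier (multi-scale filter bank +
  random forest) labels every pixel *background*, *cell* or *pit*;
* **postprocess** — the macro-style object analysis splits the three
  channels, fills holes, separates adjoining cells with a
  distance-transform watershed, and filters objects by size, border
  contact and solidity (area / convex area);
* **metrics** — per-sample %PIT, pit morphometrics (pits per pitted
  cell, maximum pits in one cell, mean pit size as % of the affected
  cell) and the splenic-function call;
* **agreement** — Bland–Altman bias and limits of agreement
  (LOA = bias ± 1.96 SD of automated − manual) with stratified
  acceptance bounds (±5% overall, ±1.5% when manual %PIT < 5%),
  observer-consensus maps, paired *t*-test, Pearson correlation;
* **simulate** — a synthetic DIC scene generator (biconcave cells,
  crater-like pits, platelet/WBC/debris confounders) with exhaustive
  ground truth, so the whole pipeline is testable without real data.

## Worked example

```r
library(pitcount)

# a small synthetic experiment: train on two scenes, count a third
cfg <- run_config(
  scene = scene_config(image_height_px = 400, image_width_px = 400,
                       pixel_size_um = 0.1, n_cells = 12,
                       pitted_fraction = 0.4),
  n_train_images = 2, n_count_images = 1,
  n_trees = 40, pixel_cap = 4000, min_cells = 10, seed = 7)
run <- run_pipeline(cfg)
print(run$samples$image_01)
#> sample_result
#>   cells counted: 12 (pitted: 5)
#>   %PIT: 41.67%
#>   pits/pitted cell: 1.80 (max 2); mean pit size 0.932% of cell
#>   excluded: excluded_size=80
#>   splenic function (el_hoss_2018): absent
run$truth[[1]]$percent_pit
#> [1] 50
```

All 12 simulated cells were recovered; five of the six truly pitted
cells were detected (%PIT 41.7 vs a simulated truth of 50 on this tiny
12-cell scene). The `excluded_size=80` tally counts sub-cellular noise
specks that the RBC size gate (20–80 µm²) removed before counting; at
the package's working scale (hundreds of cells pooled over several
images) the automated count tracks the simulated truth to within a few
percentage points.

Comparing paired manual and automated measurements:

```r
manual    <- c(0.6, 1.1, 2.4, 3.9, 12.0, 25.3, 33.8, 41.2)
automated <- c(0.9, 1.6, 2.6, 4.5, 12.8, 24.1, 35.0, 42.4)
print(bland_altman(manual, automated))
#> Bland-Altman agreement, n = 8 pairs (automated - manual)
#>   bias: 0.45% (-0.19 to 1.09)
#>   upper LOA: 1.95% (0.84 to 3.05)
#>   lower LOA: -1.05% (-2.15 to 0.06)
#>   1 pair(s) outside the LOAs
```

The positive bias says the automated method counts slightly higher than
the manual one; `check_loa_acceptance()` then compares the LOAs against
the stratified bounds.

A thin command-line front end over the same functions lives at
`inst/cli/pitcount` (subcommands `simulate`, `train`, `segment`,
`count`, `agree`, `pipeline`).

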