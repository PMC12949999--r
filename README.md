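# evspot

Quantitative 3D live-cell imaging analysis of extracellular vesicle (EV)
binding, uptake and membrane fusion.

## The problem

EVs are 50-500 nm particles that deliver protein, RNA and lipid cargo
between cells. Binding to a target cell, endocytic uptake, and actual
fusion with a cellular membrane are distinct steps, and separating them
requires imaging: recipient cells carrying a cytosolic green
antibody-based fusion reporter and a blue nuclear label are dosed with
red-labelled EVs and imaged as multi-channel confocal Z-stacks over
time. Red puncta report binding/uptake; a fusion event concentrates the
green reporter into a bright green punctum at the fusion site.

`evspot` turns such stacks into numbers, for cell biologists and
imaging scientists quantifying EV-cell interactions:

* FIJI-style preprocessing (outlier removal, intensity rescaling from
  twice the frame minimum to a 5000-unit ceiling, in-plane median
  filter);
* 3D cell and nucleus segmentation with exact voxel-count volumes,
  bright-cell exclusion, and an anisotropic signed distance field to
  the cell surface;
* Laplacian-of-Gaussian punctum detection with sub-voxel centroids;
* the classification cascade: cell-associated filtering (signed
  distance <= 1 um), membrane-proximal vs -distal red spots (binding vs
  uptake, 500 nm cutoff), and fractional-voxel-overlap localization of
  fusion spots against organelle masks -- a spot is compartment-positive
  when >= 25% of the dataset-mean spot footprint (1.96 um^3 = 928
  voxels at 0.065 x 0.065 x 0.5 um; threshold 232 voxels) lies inside
  the mask;
* cell-volume-corrected counting (`raw * reference / fov_volume`) and
  the max-over-time-lapse summary statistic per field of view;
* a ground-truthed synthetic time-lapse generator (`simulate_fov()`)
  emulating confluent reporter monolayers, EV binding/uptake/fusion
  kinetics, anisotropic PSF and sCMOS noise, so the whole pipeline is
  testable without real data.

## Worked example

```r
library(evspot)
run_demo(seed = 1)
```

```
mean spot volume 1.96 um^3 / voxel 0.0021125 um^3 -> 928 voxels
25% overlap threshold -> 232 voxels
dose bookkeeping: 1e8/4e4 = 2500, 5e8/4e4 = 12500 EVs/cell

per-timepoint counts:
 timepoint_min n_green n_red_total n_red_proximal n_red_distal sum_cell_volume_um3
             0       0           0              0            0            846.8590
            30       3          19              3           16            838.6456
            60      12          19              1           18            804.3724
max corrected red count 19.6 at t=60 min
cell volume recovery error: 1.9%
demo: all checks passed
```

The demo simulates a miniature 2-cell field dosed with fusogenic EVs and
runs the full pipeline. The printed voxel arithmetic is the localization
rule's worked example (a 1.96 um^3 mean fusion spot is 928 voxels at
localization-grade voxel size; 25% overlap = 232 voxels). In the count
table, red spots accumulate and shift from membrane-proximal (bound) to
distal (internalized) while green fusion spots appear from 30 min; the
summed segmented cell volume per timepoint is the normalization
denominator, here recovered within 1.9% of the simulated ground truth.

A full analysis of one simulated field of view:

```r
cfg <- sim_preset("fusogenic-default", seed = 1)
sim <- simulate_fov(cfg, seed = 1)          # stack + ground truth
res <- run_quantify(sim$stack, condition = "fusogenic")
res$results                                  # per-timepoint counts, corrected
summarize_max_counts(res$results, "corrected_n_green")
```

For real data, read a stack with `read_stack()` (TIFF plus a JSON
sidecar carrying geometry and channel roles) and pass it to
`run_quantify()`; localization analyses use `make_dye_mask()`,
`classify_spot_overlaps()`, `fraction_positive()` and
`subclassify_positive_by_surface()`.

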