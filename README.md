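# vesicoloc

Quantifies co-trafficking of fluorescently labelled cargo in
multi-channel fluorescence microscopy — e.g. how much internalized,
cholesterol-conjugated self-delivering siRNA shares endosomes with EGF
(degradative route) versus transferrin (recycling route), or with
GFP-tagged endosomal markers such as EEA1 and rabenosyn-5.

The core measurement is object-free pixel overlap on binary detection
masks. Each 2D plane (or 500 nm optical slab of a z-stack) is convolved
with a difference-of-Gaussians vesicle-matched filter — a unit-area
Gaussian spot detector (σ = 150 nm) minus a negative-unit-area
local-background Gaussian (σ = 300 nm) — then globally thresholded and
binarized. For binary images A and B at time *t*, the percent
co-localization of "B with A" is

```
100 · Σ_x Σ_y [ A(x,y,t) · B(x,y,t) ]  /  Σ_x Σ_y B(x,y,t)
```

i.e. the fraction of B's detected pixels that also carry A (note the
asymmetric normalization; both directions are always computed).
Non-specific overlap is controlled by rotating one binary channel by
180° and re-evaluating the same equation; at realistic detection
densities this null stays below 1%. Pixel counts are pooled over all
slabs of a cell before the ratio is formed ("integrated for the whole
cell"), and per-cell percentages are summarized per time point as
mean ± SEM with two-tailed two-sample t-tests between label pairs.

A calibrated synthetic-scene simulator (Gaussian puncta over
membrane-like background, Poisson shot noise + Gaussian read noise,
known ground-truth co-location fraction) makes every stage testable
without microscope data.

## Worked example

Simulate one two-channel scene in which half of the EGF puncta truly
share positions with the siRNA puncta, then run the full measurement:

```r
library(vesicoloc)

spec <- scene_spec(coloc_fraction = 0.5, seed = 7, time_min = 30,
                   cell_id = "demo",
                   channel_labels = c("sd-rxRNA-Cy3", "EGF-Alexa488"))
scene <- simulate_scene(spec)
res <- cell_coloc(scene$stack, "sd-rxRNA-Cy3", "EGF-Alexa488")
res
#> coloc_result [B_with_A]: EGF-Alexa488 with sd-rxRNA-Cy3 = 48.366% (444 / 918 px)
#>   180-degree rotation null: 0.545%
#>   pooled over 1 slab(s)
```

Reading the output: of the 918 pixels detected in the EGF channel, 444
also lie on detected siRNA pixels — 48.4%, recovering the simulated
co-location fraction of 0.5 — while the 180°-rotation control reports
only 0.5% overlap expected by chance at this mask density, so the
measured overlap is genuine. `coloc_results_df(res)` flattens results
into the tidy per-cell table that `summarize_timecourse()` and
`compare_pairs()` consume; `run_pipeline(config, manifest, out_dir)`
does all of this over a manifest of TIFF stacks and writes
`per_cell.csv`, `summary.csv`, `run.log` and a config snapshot.

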