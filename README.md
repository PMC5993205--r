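# scopeflow

Resumable two-phase slide-imaging workflows with a simulated microscope.

High-content screening of whole-mount specimens (embryos, sections,
organoids) cannot be done in one pass: at analysis magnification a slide is
thousands of fields, almost all empty glass. The standard strategy is
**two-phase imaging** — survey the slide at low magnification, detect the
specimens, then reload the slide and re-image only the detected regions of
interest (ROIs) at high magnification. `scopeflow` implements that entire
workflow *hardware-free*: a virtual microscope renders synthetic slides with
known ground truth, and every stage of the pipeline — resumable task
execution, slide reload re-calibration, autofocus, detection, stitching,
dataset storage and reporting — runs and is scored against it.

## What's inside

| Stage | What it does |
|---|---|
| `slide_spec()` / `make_slide()` / `render_field()` | Synthetic 75 × 25 mm slides (frosted band, coverslip, textured embryo-scale ellipses) and a seeded camera renderer with defocus blur, read noise and 8-bit quantisation |
| `wf_persist()` / `wf_dispatch()` / `wf_resume()` | Dependency-resolving task engine with a single-file persistent store: hardware tasks serialised behind a lock, compute tasks concurrent, interrupted runs resume without repeating completed work |
| `edge_profile()` / `find_edge()` / `estimate_offset()` | Re-localise a reloaded slide from the frosted-band/glass boundary and convert the displacement into an offset correction for stored ROI coordinates |
| `focus_score()` / `autofocus_search()` | Brenner / Laplacian-variance focus metrics and a coarse-to-fine z search (≤ 22 renders over ±50 µm) |
| `segment_objects()` / `components_to_rois()` / `merge_rois()` | Otsu threshold → closing → 8-connected components → area filter, µm-denominated, with padded, merged, reading-order ROIs and a pluggable user detector |
| `phase_correlate()` / `pairwise_offsets()` / `global_place()` / `render_mosaic()` | Phase-correlation stitching on overlap strips with top-peak disambiguation and translation-only global least squares |
| `run_phase1()` / `run_phase2()` / `run_two_phase_study()` | The composed two-phase experiment over a slide pool, with per-ROI 20× tiling, stitched composites and ground-truth scoring |
| `write_dataset()` / `read_dataset()` / `generate_report()` | Per-pass TIFF + JSON-sidecar dataset layout and a self-contained HTML run report (overview with ROI boxes, per-ROI low/high-mag panels) |

The key quantity the strategy optimises is the **imaging economy**: a region
covered by $n_1$ low-magnification tiles would need $n_1 (M_2/M_1)^2$
high-magnification fields to image exhaustively, whereas the two-phase
workflow acquires only $n_2$ targeted fields, giving

$$\mathrm{economy} = \frac{n_1 \, (M_2/M_1)^2}{\,n_2 + n_1 (M_1/M_2)^2\,}$$

with a low-magnification frame weighted as $(M_1/M_2)^2$ of a
high-magnification one. For 250 tiles at 5× and ~300 detected objects at
20×, the exhaustive baseline is 4,000 fields and the economy exceeds
ten-fold.

## Worked example

```r
library(scopeflow)
cfg <- default_config()
cfg$slide$n_objects <- 25L
cfg$slide$coverslip <- list(x_um = 30000, y_um = 8000, w_um = 8000, h_um = 8000)
cfg$seed <- 42L

st <- wf_store("demo_run")
simulate_slide_pool(st, 1, cfg)          # synthetic slide with ground truth
r1 <- run_phase1(st, cfg)                # load -> live-view survey -> detect
rois <- read.csv(file.path(st$path, "rois", "slide001.csv"))
head(rois[, c("label", "x_um", "y_um", "w_um", "h_um", "source")], 3)
#>   label    x_um   y_um  w_um  h_um source
#> 1 R0001 37018.4 7980.0 307.2 288.0 survey
#> 2 R0002 31602.4 8032.8 595.2 326.4 survey
#> 3 R0003 36309.6 8799.2 460.8 441.6 survey

r2 <- run_phase2(st, cfg)                # reload -> calibrate -> 20x re-image
phase2_capture(st, "slide001")
#> $captured
#> [1] 25
#> $total
#> [1] 25

imaging_cost(250, 300, 5, 20)
#> <imaging cost: 250 low-res + 300 high-res acquired;
#>  exhaustive high-res baseline 4000; economy 12.7-fold>

generate_report(st)                      # self-contained HTML under demo_run/
```

The ROI table is in stage micrometres: each box is a padded bounding box of
one detected object (or a merged cluster), carried from the phase-1 survey
to phase-2 re-imaging through the reload calibration. `phase2_capture()`
scores the run against the simulator's ground truth: an object counts as
captured when its true (posed) center lies inside at least one acquired
20× field.

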