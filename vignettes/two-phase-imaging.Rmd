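---
title: "Two-phase slide imaging with a simulated microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase slide imaging with a simulated microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scopeflow)
```

## The problem

High-content screening of whole-mount specimens — embryos, histological
sections, organoids — cannot image slides in a single pass: at the
magnification needed for analysis a slide takes thousands of fields, most of
them empty glass. The classical remedy is a two-phase strategy: survey the
slide quickly at low magnification, detect the specimens, then reload the
slide and re-image only the detected regions of interest (ROIs) at high
magnification. With roughly 300 specimens per slide this replaces an
exhaustive pass of several thousand 20x fields by a few hundred targeted
ones — better than a ten-fold reduction in acquired images.

Two things make the strategy non-trivial in practice, and both are the core
of this package. First, acquisition is a *workflow*: hardware steps (stage,
loader, camera) must be serialised, computational steps can run
concurrently, multi-hour runs fail midway and must resume without
repeating completed work. Second, reloading a slide perturbs its seating on
the stage, so ROI coordinates recorded in phase 1 are stale in phase 2
until the slide is re-localised against a landmark that does not move
relative to the specimens — the edge between the frosted labelling band and
the clear glass.

`scopeflow` implements the full pipeline against a *simulated* microscope,
so every stage is testable to ground truth on a desk: a slide generator
with known object positions, a renderer standing in for the camera, a
persistent workflow engine, edge-based re-calibration, autofocus, a simple
generalisable object detector, and phase-correlation stitching.

## The virtual slide and microscope

A synthetic slide follows the standard 75 x 25 mm format with a 19 mm
frosted band at the left end and a 22 x 22 mm coverslip region centered on
the clear glass (`slide_spec()`). Objects are embryo-scale ellipses,
400–550 um long with aspect ratios 2.2–3, placed by rejection sampling with
a minimum clearance of 80 um so that morphological closing in the detector
cannot fuse neighbours. The default of 300 objects per slide reflects a
densely populated specimen slide. All ground truth — object table, frosted
edge position, per-load pose — is retained and exportable as JSON.

The renderer (`render_field()`) produces what the camera would see at a
given stage position, objective and focus: constant bright glass
(intensity 0.85), the frosted band as a dark high-variance texture
(mean about 0.38), and objects as darkened ellipses carrying two-octave
value-noise texture (granularity 15 um with a finer 3 um octave, matching
cell-scale detail -- broadband enough that phase correlation has signal at
high magnification). Texture is a pure function of
intrinsic slide coordinates, so overlapping fields, different
magnifications and reloads all see consistent content — a prerequisite for
testing stitching and calibration honestly. Boundaries (frosted edge, slide
edges, object rims) are anti-aliased over one pixel, which is what makes
sub-pixel edge localisation and shift recovery meaningful. Defocus applies
a Gaussian blur whose sigma grows at 0.5 px per um of distance from the
focal plane; Gaussian read noise (sd 0.01) is added and the image is
quantised to 8 bits, mirroring a consumer camera. Every operation is a pure
function of its inputs and a seed.

The camera model defaults to a 1024 x 768 sensor with a reference pitch of
10 um per pixel at 1x, i.e. 2 um/px and a 2048 x 1536 um field at 5x, and
0.5 um/px at 20x. With these optics the coverslip is covered by roughly
190 tiles at 5x with 10% overlap (about 180 live-view frames at 5%
overlap), and each detected object needs one to four 20x fields — the same
order of magnitude as a real survey-and-revisit microscope, which keeps the
economy arithmetic meaningful.

What the simulator deliberately does *not* model: differential interference
contrast optics (rendering is generic bright-field-like; the pipeline logic
does not depend on the contrast mechanism), photorealistic morphology,
staining patterns, illumination shading, or stage backlash. Tests passing
against this generator therefore demonstrate the correctness of the
*pipeline* — coordinate bookkeeping, persistence, calibration, detection
and stitching logic — not detector performance on real specimens.

## The workflow engine

Workflows are acyclic graphs of named modules, each `"acquisition"` or
`"compute"`. The engine (`wf_dispatch()`, `wf_resume()`) creates one task
per (module, slide), runs them in dependency order, and persists every
status transition in a single-file JSON store written atomically via
rename (schema: workflows, modules, tasks, task parents, runs). A
relational engine would serve equally; a transparent single-file store was
chosen because it is inspectable with any text editor and needs no
driver. The task lifecycle is `NEW -> IN_PROGRESS -> {SUCCESS, ERROR,
DEFER}`; `DEFER` parks operator-prompt tasks (semi-automatic loading) until
acknowledged, and `SUCCESS` is terminal.

R is single-threaded, so concurrency is modelled rather than threaded: the
dispatcher executes deterministic scheduling waves, each holding at most
one acquisition task — the hardware lock — plus up to `workers` compute
tasks, and records the schedule. The serialisation invariant and the
compute-overlap property are asserted on that recorded schedule. Crash
recovery is by run-id ownership, not timeouts: a resumed store resets
`IN_PROGRESS` tasks owned by a dead run to `NEW`, never re-executes
`SUCCESS` tasks (verified with side-effect counters), and reaches the same
SUCCESS set as an uninterrupted run. Acquisition passes are additionally
resumable at tile granularity through the dataset journal: a tile already
listed is never re-acquired.

## Calibration after reload

Reloading draws a fresh seating pose: translations `N(0, 200 um)` on both
axes by default and a small rotation `N(0, 5e-4 rad)` about the slide
center. The magnitude is a modelling choice — published descriptions of
slide loaders note that offsets occur without quantifying them — and is
exercised as a parameter up to 500 um in the tests.

Phase 1 records where the frosted-band edge *appears* in stage coordinates;
phase 2 re-measures it and the mean displacement is the x-correction
mapping stored ROI coordinates onto the new seating. The per-column edge
score is the row-mean absolute central gradient plus the column variance,
smoothed with a fixed 5-column moving mean; `find_edge()` takes the argmax
with 3-point parabolic refinement and a scale-free confidence
`(peak - median)/(max - min)`. Two numerical details matter. The boxcar
smoothing flattens the peak into a plateau, which quantises any
refinement done on the smoothed profile; `observe_edge()` therefore
re-localises with a baseline-subtracted centroid of the *raw* column scores
around the smoothed peak, reaching well under half a pixel. And the
confidence ratio is scale-free, so featureless glass would pass it;
profiles whose range falls below an absolute floor (0.01 intensity
gradient per pixel, several times the read-noise floor) are flagged flat
instead. Observation fields are searched laterally (half-field steps, up
to two each way) because a reloaded slide can push the edge out of the
nominal field.

A vertical edge carries no y information. The spec of this workflow leaves
y-measurement open; the package resolves it by measuring the slide's long
top edge — the glass/stage-background boundary, equally
location-invariant — with the same algorithm on the transposed image.
Without it, a 10% ROI pad (tens of um) cannot absorb seating offsets of
hundreds of um and phase 2 would miss most objects; with it, residual
errors are a few um (dominated by the uncorrected seating rotation, whose
lever arm across the coverslip is about 7 um at the default rotation
noise), which the default padding absorbs comfortably. Rotation estimation
from the edge-tilt slope is implemented but off by default; it reports the
apparent tilt and is intended for diagnostics rather than correction.

## Autofocus

Focus is scored by the Brenner gradient (mean squared lag-2 horizontal
difference) or the variance of the 3x3 Laplacian, both invariant to
intensity offsets, over a configurable central crop. The search is
coarse-to-fine: a 10 um grid over ±50 um, then a 2 um grid spanning ±one
coarse step around the coarse optimum — at most 22 renders. Fields whose
scores are all equal (featureless glass under identical noise seeds) return
the range midpoint flagged featureless. In the acquisition workflow the
focus field is the whole camera frame at the ROI center: the object's sharp
boundary must fall inside the scored crop, because the interior texture
(15 um granularity) carries less gradient
energy against read noise. Using one seed for all z renders makes the
comparison paired — noise contributes identically at every z — so the
argmax reflects scene blur alone. Focus is searched once per slide by
default (the simulated focal plane is planar); a per-ROI policy is
available.

## Detection

The detector is intentionally simple and generalisable: polarity
normalisation (objects darker than background are inverted), Otsu
thresholding, morphological closing (radius 20 um), 8-connected components
and an area filter (20,000–600,000 um^2), with every parameter denominated
in micrometres so one configuration serves survey and full-resolution
imagery. Two guards keep automatic thresholding honest on object-free
images, where Otsu will happily split pure noise: foreground must be the
minority phase (under 40% of pixels), and the two Otsu classes must be
separated by at least 0.05 intensity units. Component boxes are padded by
10% per side, merged transitively when they overlap, and labelled
`R0001...` in reading order. A user-supplied detector can replace the
built-in pipeline; its output is validated against the same ROI invariants
and normalised identically.

In live-view survey mode, frames are block-mean downsampled 4x (8 um/px)
and pasted at nominal stage positions into a survey mosaic; detection runs
once on the mosaic. Placement is nearest-pixel, so box coordinates carry
up to half a survey pixel of error — absorbed by the ROI padding.

## Stitching

Tile placement starts from nominal stage positions; adjacent pairs are
refined by phase correlation on overlap strips (nominal overlap plus a
16 px search margin, capped at 256 px and cropped to the central 640 px of
the cross dimension — wider strips add cost, not information), and a
translation-only weighted least squares anchors each connected component
at its nominal position. Three robustness choices: the top five
correlation peaks are each tested against the direct overlap correlation
(the global maximum is not always the true shift — periodic texture and
quantisation contours produce spurious peaks); the period ambiguity of
each peak is resolved toward the nominal overlap; and pairs whose
peak-neighbourhood confidence falls below 0.1 are dropped, so featureless
glass tiles fall back to nominal placement rather than contaminating the
solve. Sub-pixel refinement runs in the image domain: an iterative
gradient least-squares step on the integer-aligned overlap, executed in
both directions and averaged so interpolation bias cancels — the whitened
cross-power surface is reliable for the integer peak but its sub-pixel
phases are dominated by quantisation residuals. Mosaics are rendered with
either overwrite or linear border-ramp feathering.

## Problem sizes and numerical choices

The package's study-scale benchmark (shared by the test suite and by
`scripts/acceptance.R`) runs eight default slides — about 2,400 objects —
through the complete two-phase pipeline, processing slides as independent
sequential runs and deleting each slide's imagery after scoring to bound
disk use at roughly one slide (~900 MB). Eight slides keeps the full
benchmark within a practical desk-scale compute budget while leaving the
per-object sample in the thousands; the calibration (50 reloads), stitcher
(50 pairs), crash-recovery (20 interruption points) and autofocus (20
fields) checks run at their full sizes. The mosaic-fidelity oracle
disables read noise, because two independent renders of the same scene
differ by about 2.9 gray levels of noise alone, which would mask the
geometric comparison being made.

Degenerate inputs are contracts, not errors: an empty slide yields zero
ROIs; a region smaller than one field yields a single centered tile; a
featureless autofocus field returns the midpoint flagged; a single tile
stitches to itself; ties in `find_edge()` break to the lower column index
with reduced confidence.

## Known limitations

The seating-rotation residual is corrected only through padding; detection
is calibrated only against the synthetic generator and says nothing about
stained real specimens; the dataset metadata dialect is
micro-manager-inspired, not byte-compatible; and the simulated hardware has
no backlash, illumination shading or lens distortion, so the calibration
accuracies reported here are upper bounds on what physical hardware would
deliver.

## A minimal run

```{r example}
library(scopeflow)
cfg <- default_config()
cfg$slide$n_objects <- 25L
cfg$slide$coverslip <- list(x_um = 30000, y_um = 8000, w_um = 8000, h_um = 8000)

st <- wf_store("demo_run")
simulate_slide_pool(st, 2, cfg)
run_phase1(st, cfg)        # load, live-view survey, detect
run_phase2(st, cfg)        # reload, calibrate, re-image at 20x, stitch
phase2_capture(st, "slide001")
generate_report(st)        # self-contained HTML under demo_run/
```
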