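---
title: "Simulating annotated wheat seedling canopies and evaluating leaf-tip detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating annotated wheat seedling canopies and evaluating leaf-tip detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(wheattips)
```

## The problem

Counting leaves on wheat seedlings in the field is the standard way to place
a plant on the Haun developmental scale, and the leaf *tip* is the image
feature that makes the count automatable: one visible tip per emerged leaf.
Training a detector for such tiny objects normally requires a large,
painstakingly hand-labelled image set. The alternative implemented here is
to *simulate* the training data: build explicit 3D seedling canopies from
architectural parameters, render them to RGB images, and place the tip
labels automatically from the scene geometry, where they are exact and free.

`wheattips` provides that pipeline end to end at desk scale: a procedural
functional-structural plant model, a z-buffer renderer with controllable
realism factors, automatic 12 x 12 px tip boxes, sliding-window tiling and
COCO/CSV interchange, a fully classical baseline detector, IoU-matched
detection and counting metrics with per-stage reporting, a feature-space
domain-gap measure, and drivers for two in-silico experiments (realism
factors and spatial resolution).

## The plant model

Development is driven by cumulative thermal time $T$ (degree-days) through
the Haun stage

$$H = T / \phi,$$

where $\phi$ is the phyllochron (degree-days per leaf; default 100). A
plant carries $\lceil H \rceil$ leaves: $\lfloor H \rfloor$ fully expanded
plus one expanding leaf at fraction $H - \lfloor H \rfloor$. This is the
simplest census consistent with the Haun-scale definition; the full
physiology of sheath and internode dynamics is out of scope.

Each blade is a quadratic Bezier midrib in the vertical plane of its
azimuth. The curve leaves the insertion point at `inclination_angle` from
the vertical and its end direction is rotated a further `curvature`
$\times 90^\circ$ toward (and past) the horizontal, giving a single droop
dial. The densely sampled curve is rescaled so the midrib polyline length
equals the expanded fraction of the rank's nominal length *exactly*; tests
hold this to a relative error below $10^{-3}$. The blade surface sweeps a
width profile that rises from half the maximum width at the insertion to
the maximum at 30% of the midrib length and tapers linearly to zero at the
tip, so the detected feature — a sharp tip — exists by construction.
Successive leaf azimuths alternate by $180^\circ$ plus Gaussian jitter
(default s.d. $12^\circ$). Tillers are smaller secondary shoots sharing the
plant base; they are off by default because the seedling stages of interest
(Haun 1-4) precede tillering.

Canopies place `round(density x plot area)` plants on rows with Gaussian
positional jitter. All stochastic choices flow from one seed, and scene
construction is bit-reproducible.

Parameter spaces are explored with Latin hypercube sampling
(`sample_parameter_sets()`, backed by the `lhs` package): for every
parameter the $n$ draws occupy $n$ distinct equal-width strata. The shipped
default ranges (`inst/extdata/default_ranges.yaml`) — blade lengths growing
from 40-90 mm at rank 1 and capped at 200 mm, inclination 20-70 degrees,
densities 100-400 plants/m^2, phyllochron 80-120 degree-days, thermal time
80-420 degree-days — are editable defaults spanning ordinary wheat seedling
variation, not a reconstruction of any particular cultivar panel.

## Rendering

The renderer is a deliberate simplification of physically based ray
tracing: a z-buffer rasterizer (Rcpp) over the textured soil plane with
flat Lambertian shading, an isotropic diffuse sky term, and hard cast
shadows by any-hit ray tests against the triangle set. The shading model is

$$c = a \left( f_d + (1 - f_d)\,\max(0, n \cdot s)\, \ell \right),$$

with albedo $a$, diffuse fraction $f_d$, sun direction $s$ and $\ell = 0$
for shadowed points. At $f_d = 1$ (overcast) shadows vanish identically —
a property the tests check bit-for-bit. This retains exactly the three
realism factors the experiments manipulate (leaf texture, soil background,
illumination) at a cost of seconds per frame on one CPU; specular leaf
optics, soft shadows and sky models are intentionally absent.

Geometric conventions: pixel centres at integer coordinates, origin
top-left, $u$ rightward, $v$ downward; depth is the Euclidean distance from
the camera centre; triangles are rasterized in a canonical order (owner,
then centroid) so results never depend on assembly order; depth ties break
toward the smaller owner id. The nominal ground sampling distance is
defined at the image centre along the horizontal sensor axis,
$\mathrm{GSD} = 2 (h / \cos\theta_v) \tan(\mathrm{fov}/2) / W$, and
`camera_for_gsd()` inverts it for the camera height — the mechanism of the
resolution sweep. Colour stays linear in memory; gamma 2.2 is applied only
when writing PNGs.

Textures are procedural by default so the package builds with zero
downloads: band-noise green blades (longitudinal vein stripes over
low-frequency noise) and a Perlin-like brown soil (multi-octave value noise
plus speckle). `"standard"` selects the fixed flat-colour variants used as
defaults when a realism factor is *not* varied; user PNG images override
either.

## Automatic annotation

Tips are projected with the pinhole model and tested against the z-buffer.
A tip is visible iff some pixel in a 3 x 3 window around its projection is
owned by that leaf, *or* the depth at the projection pixel exceeds the tip
depth minus 2 mm (the tip is front-most where it lands). The window exists
because tips are sub-pixel thin — the final blade triangles often miss
every pixel centre — while the depth clause is evaluated at the single
projection pixel: a window-wide depth clause would see past thin occluders
and mark genuinely hidden tips visible. With this rule, visibility agrees
with an independent per-tip ray cast on 99-100% of tips across 50 random
desk-scale scenes (the acceptance suite requires at least 99%). Occluded
tips are not labelled.

Frames are tiled into training-size subimages by sliding windows whose last
row/column clamps to the border, so every pixel is covered; an annotation
belongs to a tile iff its centre lies inside (half-open window), and
annotations in overlaps are duplicated per tile, as is standard in
detection tiling. The default 1024 px tiles with 896 px stride reproduce a
6 x 4 = 24-tile layout on a 5472 x 3648 frame; the overlap amount is
configurable since only "some overlap" is prescribed by practice.

Datasets are written as PNG images plus a JSON manifest, COCO-format boxes
(`[x, y, w, h]`, clipped to image bounds at write time) and a flat CSV.
`read_dataset(write_dataset(x))` is field-for-field identity, and
`attach_annotations_to_translated()` re-points a manifest at an
appearance-translated copy of the images — valid because boundary-
preserving translation leaves tip positions fixed — refusing any file with
changed dimensions rather than rescaling labels.

## The baseline detector

The deep detectors that would consume such a dataset are GPU-scale and out
of scope; what the package ships instead is (a) the *detector contract* —
image in, scored 12 x 12 boxes out, serialized in the same dialect as the
annotations — and (b) a fully classical baseline that satisfies it, so the
whole pipeline is exercisable end to end:

1. **Vegetation mask.** Excess green $\mathrm{ExG} = 2G - R - B$,
   thresholded by Otsu's method. Two refinements target the sub-pixel-thin
   distal blade, whose mixed pixels fall below the Otsu split: *hysteresis*
   (pixels above 40% of the Otsu level join if connected to an
   above-threshold region) and *opening by reconstruction* (the radius-1
   opening decides which connected components survive, killing specks, but
   survivors are kept whole rather than eroded — a plain opening clips the
   blade tail). Holes up to 64 px are filled; unfilled speckle holes leave
   loops in the skeleton and swallow tip endpoints.
2. **Skeleton endpoints.** Zhang-Suen thinning (Rcpp; no installed package
   exposes thinning), spur pruning below 2 px, then endpoints by the
   crossing-number rule: at most two neighbours forming a single contiguous
   arc. The naive "exactly one neighbour" rule misses the doubled pixels
   thinning leaves at diagonal staircase ends.
3. **Tip classification.** An endpoint is a tip if its blade tapers: the
   distance-transform value at the endpoint must be under `taper_ratio`
   (default 0.6) times the median along its incident branch. The distance
   transform is taken on the *core* (plain-Otsu) mask — the hysteresis halo
   is nearly constant-width and would flatten the taper — and the branch
   window spans roughly 12 mm of blade via the GSD, because the taper is a
   physical length, not a pixel count. Branches lying wholly outside the
   core are already sub-threshold thin and count as maximally tapered.
4. **Sub-pixel localization.** Thinning and thresholding both retreat from
   the true zero-width tip, so the endpoint is pushed forward by a
   breadth-first search along the mask tail and then by following the
   fading ExG ridge (down to 10% of the leaf-soil contrast) with half-pixel
   steps and lateral ridge tracking. Non-maximum suppression within 6 px
   and a border margin of half a box finish the list.

All thresholds are exported arguments. On clean fixtures — isolated
seedlings at Haun 1-2, 0.3 mm/px, fully diffuse light, standard textures —
the suite requires precision and recall of at least 0.85; across seed
draws the detector measures roughly 0.85-0.96 for both there. This is an engineering floor for a desk
detector on easy scenes, not a claim about field performance: on dense
canopies, oblique views or coarse resolutions it degrades quickly, which is
precisely what makes it a useful probe in the experiments below.

## Metrics

Matching uses IoU with the conventional strict threshold (a pair counts
only above 0.5) and greedy one-to-one assignment in decreasing-IoU order;
greedy was chosen over optimal assignment for determinism and speed, and a
test checks its counts against an exhaustive matching oracle in the regimes
where they must coincide. Unmatched detections are false positives and
unmatched truths false negatives. For equal 12 x 12 boxes the IoU rule is
equivalent to $(12 - |\Delta u|)(12 - |\Delta v|) > 96$, verified by
exhaustive enumeration of integer offsets.

Counting quality uses per-image counts: $\mathrm{MAE} = \frac1n \sum |y_i -
\hat y_i|$, $\mathrm{RMSE} = \sqrt{\frac1n \sum (y_i - \hat y_i)^2}$, and
the standard coefficient of determination $R^2 = 1 - \mathrm{SS}_{res} /
\mathrm{SS}_{tot}$. Degenerate denominators yield `NA` markers, never
errors; a constant mean predictor scores exactly 0. Per-stage reports bin
images by the floor of the Haun stage clamped into {1, 2, 3, 4}, dropping
empty bins; `tidy()` returns the per-stage rows and `glance()` the overall
row.

## The domain gap

Whether two image sets "look alike" is quantified in a fixed feature space:
the default handcrafted extractor concatenates per-channel 16-bin colour
histograms, an 8-bin gradient-orientation histogram and five
texture-energy statistics ($d = 61$); any `function(image) -> vector` can
replace it, which is how an external network's features would plug in. The
dataset distance standardizes each dimension over the union of both sets
and takes the Euclidean distance between set centroids — the single-scalar
variant consistent with using one number per dataset pair — with an
alternative computed in a jointly embedded 2-D t-SNE plane
(`space = "embedding"`, via Rtsne, perplexity clamped below
$(n-1)/3$, seeded). Centroid-vs-pairwise aggregation and feature-vs-
embedding space are genuinely open choices; both variants are exposed and
the feature-space centroid is the default.

## The two experiments

`run_realism_ablation()` renders matched scene sets in which only flagged
realism factors vary — LT (leaf texture), SB (soil background), LC (light:
diffuse fraction 0.2-1, random sun, shadows on) — with unflagged factors
pinned to standard texture, standard soil, fully diffuse light. The default
grid is the 7-row ladder LT, SB, LC, LT+SB, LC+SB, LC+LT, LC+LT+SB; each
row reports counting metrics of the baseline detector plus the distance to
a reference set (by default the full-realism condition, the most realistic
imagery the simulator produces). Because the scenes are shared across
conditions, lighting changes leave tip geometry untouched — a property the
tests assert.

`run_resolution_sweep()` re-renders the *same* scenes over a GSD grid
(default 0.1-2.0 mm/px in 0.1 mm steps) by adjusting camera height, then
annotates, detects and reports MAE/RMSE/$R^2$ per GSD. The acceptance suite
checks the qualitative signature — counting error at 2.0 mm/px strictly
exceeds that at 0.3 mm/px on 20 fixed scenes — rather than any absolute
value, since absolute accuracy belongs to the detector, not the sweep.

## Problem sizes and numerical choices

The defaults in the test and acceptance suites are deliberately desk-scale:
256-768 px sensors, scenes of 1-10 plants, 14-50 scenes per property, 20
images per dataset in the gap checks. These were chosen as the smallest
sizes at which the checked properties are stable, and all scale up by
argument. Other numerics worth knowing: visibility tolerance 2 mm;
supersampling factor 2 by default (the colour image only; depth/owner
buffers are always single-sample at pixel centres); leaf material is
two-sided with normals flipped toward the camera; degenerate triangles are
skipped with a warning count; annotation boxes are clipped to image bounds
only at write time, while centres must be in-bounds or the tip is dropped.

## What the simulation does and does not show

The generator produces plausible seedling geometry, textures, illumination
and exact labels — enough to exercise every stage of a tip-counting
pipeline and to study *relative* effects (realism factors, resolution,
domain distances) under controlled conditions. It does not emulate real
field imagery: no weeds, residue, dew, motion blur, sensor noise, specular
leaf optics or cultivar-specific architecture. Passing tests therefore
demonstrate internal correctness and qualitative behaviour, not field
accuracy of any detector; absolute numbers from the full-scale workflow
(GPU detectors trained on translated imagery against hand-labelled field
photos) are outside what this package can or does reproduce.

## A worked example

```{r example, eval = FALSE}
library(wheattips)

# one seedling plot at ~Haun 2.5, rendered and annotated
field <- field_config(thermal_time = 250, seed = 42)
scene <- build_canopy(field, plant_params())
camera <- camera_for_gsd(0.5, view_zenith = 45, fov = 40,
                         sensor_width_px = 768,
                         look_at = c(200, 150, 0))
frame <- render_scene(scene, camera,
                      light_config(diffuse_fraction = 0.6),
                      texture_set("procedural", "procedural"))
truth <- annotate_tips(scene, frame)
found <- detect_tips(frame)

report <- per_stage_report(
  eval_image_table(list(truth), list(found), stages = scene$mean_haun))
glance(report)
autoplot(frame, annotations = truth)
```
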