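---
title: "Methods: multi-animal detection and tracking for overhead arena video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-animal detection and tracking for overhead arena video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodtrack)
```

# Problem and model

The package tracks a known, fixed number of laboratory rodents filmed from
directly above an open arena. The camera is static, the floor is roughly
uniform, and the animals are darker than the floor. Three difficulties
dominate this setting: the detector intermittently misses animals
(occlusion, grooming postures, compression artifacts), identities must be
preserved when two animals pass close to each other, and specular highlights
from the light source corrupt the floor appearance.

The pipeline is a classical detect-then-track design:

1. A per-frame detector returns scored bounding boxes; overlapping
   duplicates are removed by non-maximum suppression (NMS) on the
   intersection-over-union (IOU).
2. Each animal carries a constant-velocity Kalman filter over the state
   $(x, y, v_x, v_y)$ with position-only measurements.
3. Detections are assigned to tracks by the Hungarian algorithm on a
   Euclidean cost matrix. The cost is computed against the Kalman
   *predicted* positions rather than the last seen positions; this is what
   keeps identities through crossings, where the nearest previous position
   is the wrong animal but the extrapolated path is not.
4. Every claimed position (matched detection or coasted prediction) is
   verified against the gray image by the nine-point correction: if the
   point does not lie on a dark body, the eight surrounding points of a
   3 × 3 grid are probed and the position snaps to the darkest qualifying
   point.
5. When a track receives no detection, the record is filled from the
   corrected prediction, so every animal has a position in every frame.

Two auxiliary modules support the pipeline. An automatic labeler runs a
classical segmentation (smoothing, contrast equalization, thresholding,
morphology, connected components) and writes PASCAL VOC XML annotations, so
a detection dataset can be bootstrapped without manual boxes. A highlight
remover attenuates gradients inside a user-supplied mask in the log domain
and reconstructs the image by solving a Poisson equation.

# Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Gaussian kernel size | 5 | px | small blur; sigma follows $0.3((k-1)/2-1)+0.8 = 1.1$ |
| Bilateral diameter | 40 | px | smooths floor texture while keeping body edges |
| Bilateral sigma (color, space) | 75, 75 | gray, px | standard edge-preserving setting |
| CLAHE clip limit / tiles | 1.0 / 50 × 50 | — | mild local equalization of uneven lighting |
| Binarization threshold | 100 | gray | body pixels are darker than the floor |
| Morphology | erode × 3, dilate × 4, 5 × 5 box | — | removes speckle, restores body area |
| Max box gate | 200 × 200 | px | rejects merged or background blobs |
| NMS threshold | 0.45 | IOU | removes duplicate detections |
| Process noise diag | (1, 1, 10, 10) | px² | velocity less certain than position |
| Measurement noise diag | (10, 10) | px² | detector center jitter |
| Assignment gate | 150 | px | matches farther than this are rejected |
| Nine-point spacing | 30 | px | about half a body length |
| Nine-point gray threshold | 105 | gray | strictly-below test for a dark body |
| Max coast | 30 | frames | track flagged stale after this |
| Highlight alpha, beta | 0.4, 0.4 | — | gradient attenuation strength |
| Exploration grid | 40 × 30 | cells | arena occupancy summary |
| Frame size | 1024 × 760 | px | reference arena resolution |

All parameters are exposed through `seg_params()`, `kalman_params()`,
`ninepoint_params()`, `highlight_params()` and `tracker_config()`.

# Image conventions

A grayscale frame is a numeric matrix indexed `[y, x]` with values in
0..255; a color frame is an `h × w × 3` array with channels ordered blue,
green, red. Bounding boxes are 0-based, half-open (`area =
(xmax - xmin)(ymax - ymin)`); the VOC writer converts to the format's
1-based inclusive pixel coordinates on output and back on input.

# Numerical choices

* **CLAHE tiling.** The tile-based equalizer requires image dimensions that
  are multiples of the grid. Frames are padded by edge replication to the
  next multiple and cropped back; the grid is clamped so no tile falls
  below 8 px. This keeps the operator total (no pixels invented or lost).
* **Bilateral filter.** Implemented in C++ with a circular window of radius
  20, precomputed spatial weights and a 512-entry range look-up table. The
  window is circular because the filter's "diameter" is interpreted as a
  disk, matching the isotropic intent of the spatial kernel.
* **Strict threshold.** The nine-point body test uses *strictly below* 105.
  A pixel exactly at the threshold is floor, which makes the kept/corrected
  decision reproducible at quantized gray levels.
* **Kalman update.** The covariance update uses the Joseph form and is
  re-symmetrized, so the covariance stays symmetric positive semidefinite
  under long prediction/update interleavings (property-tested).
* **Hungarian algorithm.** Shortest-augmenting-path formulation, exact for
  rectangular matrices via transposition; validated against exhaustive
  permutation search up to 6 × 6.
* **Poisson reconstruction.** Forward-difference gradients with the
  matching backward-difference divergence yield the standard 5-point
  Laplacian. Unknowns are the masked pixels only; Dirichlet values come
  from the untouched surround, so pixels outside the mask are returned
  bit-identical. The sparse symmetric system is solved directly
  (`Matrix::solve`), and the residual of the discrete equation is attached
  to the result (`attr(out, "poisson_residual")`, typically below 1e-12).

# Limitations worth knowing

* **Highlight attenuation only bites on strong edges.** The attenuation
  multiplies each log-domain gradient of magnitude $m$ by
  $\alpha^\beta m^{-\beta}$, which *shrinks* the gradient only when
  $m \ge \alpha$. With $\alpha = 0.4$, a saturated highlight on a bright
  floor (say gray 200) produces log-edge gradients of about 0.24, and the
  transform then amplifies rather than attenuates. On darker floors
  (gray ≤ ~150) the edge exceeds $\alpha$ and the highlight is visibly
  desaturated. The test suite documents both regimes.
* **Constant-velocity coasting drifts on turns.** During long detector
  outages a turning animal leaves the extrapolated path; the nine-point
  correction bounds the error only once the prediction re-enters the
  probe grid's reach of the body.
* **The synthetic generator is a study harness, not a physics model.**
  It renders rotated-ellipse bodies on a noisy floor with reflective walls,
  elastic separation between animals, optional salt-and-pepper noise,
  detection dropout and jitter — enough to exercise every module with exact
  ground truth. It does not emulate limbs, tails, shadows, occlusion by
  enrichment objects, or camera distortion.

# What the synthetic scenes emulate

`arena_scene()` draws every random quantity at construction (positions,
headings, speeds, per-frame noise seeds, dropout and jitter streams), so a
scene is a pure value: any frame can be rendered independently and
identically (`render_frame(scene, i)`), and the detection stream
(`truth_detector()`) is deterministic given the seed. Dropout affects only
the detection stream, never the rendered pixels. `crossing_scene()`
constructs the canonical identity-swap benchmark: two animals on a
collision course whose nearest-previous-position assignment swaps identities
while the prediction-augmented assignment does not.

# Problem sizes

The unit tests run on reduced scenes (320 × 240 to 512 × 380, tens of
frames) to keep the suite fast. The end-to-end checks run the package's
reference configuration: a 1024 × 760 arena, 3 animals, 500 frames with 20%
per-animal detection dropout for the tracking benchmark, and 50-frame clean
and salt-and-pepper scenes for the segmentation recall benchmark. These
sizes are the package's own choices for a convincing demonstration on one
CPU core.
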