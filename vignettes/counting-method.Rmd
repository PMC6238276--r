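---
title: "Counting wheat seedlings from framed field photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting wheat seedlings from framed field photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatcount)
```

## The problem and the model

Plant density at emergence — seedlings per square metre during the first to
third leaf stages — drives decisions about supplementary sowing and later
management, and is traditionally obtained by manual counts. `wheatcount`
implements an image-analysis alternative: a 1 m × 1 m white frame is laid in
the field, photographed from roughly head height, and the photograph alone
yields a seedling-number estimate.

Counting individual plants directly is unreliable at these stages because
leaves overlap and curl. The method therefore avoids instance segmentation
entirely and regresses the count on two whole-plot descriptors plus two
manually known covariates:

* **coverage degree** `Co` — the fraction of the rectified 1-m² area
  classified as seedling foreground;
* **angular points** `Ha` — the number of Harris corner-response maxima on
  the segmented mask. Corners arise at leaf tips, leaf–leaf intersections
  and curl folds, so `Ha` grows with exactly the overlap and curl that
  corrupt `Co`;
* **leaf age** `La` — the mean developmental stage (1–3, non-integer), known
  from scouting;
* **variety coefficient** `Va` — a per-cultivar multiplicative correction
  for seedling habit (lax cultivars spread more canopy per plant than erect
  ones).

Two model families are shipped with the package. Nine per-variety,
per-stage linear equations

$$SN_{v,s} = \alpha_{v,s}\,Ha + \beta_{v,s}\,Co + \gamma_{v,s}$$

and one unified multi-factor model

$$SN = \frac{Va \,( a\,Ha + b\,Co + c)}{d\,La},
\qquad a = 0.44,\; b = 110.43,\; c = 3.35,\; d = 1.11,$$

with `Va` = 1.05 (YM23, half-erect), 0.86 (HM7, lax), 1.12 (YF4, erect).
`builtin_models()` returns all of these. Note the unified parametrisation is
scale-degenerate — multiplying \(a,b,c,d\) by a common factor changes
nothing — which matters for calibration (below).

## The image pipeline

**Target-area rectification.** Frame pixels satisfy two colour conditions on
channels normalised to [0, 1]: brightness `r + g + b > 2.1` and neutrality
`r − b < 0.05`. The second rejects pale straw, which is red-shifted. Both
constants were derived by the method's authors from the colour statistics of
their scenes; they are exposed in `run_config()` because their generality is
untested. Of the pixels passing both tests only the largest connected
component is kept (specular highlights also pass). The counting area is the
*inside* of the frame, so the interior region enclosed by the band is
isolated and its outer boundary traced as an 8-direction Freeman chain,
clockwise from the topmost-leftmost pixel. Boundary curvature with
neighbourhood parameter `k = 8` is

$$\theta_i = |C_{i+1} - C_i|,\qquad
\varphi_i = \min(\theta_i,\, 8 - \theta_i),\qquad
e_i = \varphi_i(\varphi_{i-1} + \varphi_i + \varphi_{i+1}),$$

so `φ ∈ [0, 4]`, straight runs give `e = 0`, and an isolated right-angle
step gives `φ = 2`, `e = 4`. `curvature_profile()` implements exactly this.

For *locating* the four frame corners, however, single-step code differences
are noisy on digitised oblique edges: a near-45° edge alternates codes (0, 7,
0, 7, …) and scores `φ = 1` at every point, while a corner whose 90° turn
falls across two code steps scores no higher than that edge noise.
`detect_frame_corners()` therefore measures the turn angle between the
boundary chords `s` points behind and ahead (`s` ≈ 1% of the perimeter),
keeps the four strongest turns of at least 45° subject to a pairwise
arc-length separation of 10% of the perimeter, and refines each pick to the
boundary point farthest from the chord spanning its neighbourhood (exact
for polygon vertices). A circle never turns 45° at this chord scale, so
shapes without concentrated curvature are rejected rather than mis-cornered.

The four corners, ordered top-left/top-right/bottom-right/bottom-left by
angle about their centroid, define an 8-unknown linear system for the
3 × 3 perspective matrix (`a33 = 1`), solved directly. The inverse transform
then resamples the photograph into a square of `target_size` pixels
(default 800) by bilinear interpolation with zero fill, since no resampling
rule is part of the published method.

**Segmentation.** The excess-green index is computed on chromatic
coordinates, `ExG = 1.8 g − r − b` with `r = R/(R+G+B)` etc., making it
invariant to global brightness; the published coefficient 1.8 (rather than
the more common 2.0) is used as printed. The index map is thresholded by
Otsu's method on a 256-bin histogram spanning the observed value range, with
the foreground strictly above the threshold. Two guards surround the
textbook procedure:

* the effective threshold is floored at `exg_min = 0.15`. Vegetation sits
  at `ExG ≳ 0.4` and soil near or below zero, but on a plot with little or
  no vegetation Otsu has no vegetation mode to find and will happily bisect
  soil-colour noise (chromatic soil fluctuations reach `ExG ≈ 0.11`). The
  floor sits between those two regimes and is inert whenever vegetation is
  present;
* a constant map (for example, a uniformly green test image) is reported as
  a degenerate histogram with an empty mask and a warning rather than an
  arbitrary split.

Morphological cleanup is opening with a true Euclidean disc (radius 1 is
the 4-neighbour cross — deliberately *not* a 3 × 3 box, which destroys a
large fraction of 3-px-wide ribbons) followed by filling of background
holes not 4-connected to the border. Filling is capped at `hole_max_px = 64`
pixels: pinholes inside a blade are tiny, whereas unbounded filling also
swallows large soil pockets ringed by overlapping leaves, inflating
coverage by a quarter at high density. The cleanup is idempotent.

**Features.** `Co` is the foreground fraction of the mask. The Harris
response is computed on the smoothed *mask*, not the colour image — corners
of soil texture are irrelevant and the published detection operates after
segmentation — with Sobel gradients, Gaussian windowing (`σ = 1.5` px),
`R = det M − k\,\mathrm{tr}^2 M` and `k = 0.04` (the empirical 0.04–0.06
range is enforced). The mask is replicate-padded before filtering so image
borders do not masquerade as gradients. Candidate pixels above 1% of the
maximum response pass greedy non-maximum suppression with a 5-px separation
radius; the number kept is `Ha`. The published method specifies only `k`;
threshold and suppression radius are engineering choices absorbed by
calibration, and both live in `run_config()`.

## Calibration

`stepwise_mlr()` implements forward-entry/backward-removal stepwise linear
regression on candidate predictors `{Ha, Co}` with partial-F thresholds
`alpha_in = 0.05`, `alpha_out = 0.10` (classical defaults; the published
analysis does not state its values), final coefficients by ordinary least
squares. `fit_metrics()` reports `R² = 1 − SSE/SST`, adjusted R²,
`RMSE = √(SSE/n)` (population denominator, matching the "mean deviation"
reading) and `REP = 100·RMSE/mean(obs)`; the source analysis never defines
REP algebraically, so this conventional definition is used and documented.

`fit_unified()` resolves the scale degeneracy explicitly: the caller must
fix `d` (default 1.11, the published value) — making the model linear in
`(a, b, c)` on the transformed regressors `Va·Ha/(d·La)`, `Va·Co/(d·La)`,
`Va/(d·La)` — or fix `(a, b, c, d)`, whereupon each variety's `Va` has the
closed-form one-parameter least-squares solution. Requesting a fit with
nothing pinned is an identifiability error, not a silent normalisation.

`train_validate_split()` reproduces the study design of calibrating at one
site and validating at the other when a site column exists, and otherwise
performs a seeded random split.

## The synthetic scene generator

No imagery is distributed with the method, so `generate_scene()` renders
scenes with exact ground truth: low-frequency brown soil, pale elongated
straw distractors with `r − b ≥ 0.1` (so the frame thresholds must actively
reject them), a white frame band warped by a bounded random perspective
(corner displacement ≤ `frame_tilt`·size, default 6%), and plants placed
uniformly inside the frame. Each plant carries ⌊`leaf_stage`⌋ or
⌈`leaf_stage`⌉ tapered quadratic-Bézier leaf ribbons; a curled leaf is
drawn foreshortened to its fold point with a short flap folded back at
110–140°, which reproduces the observed signature of curl — lower coverage,
more angular points — without 3-D modelling. Scenes are deterministic given
`seed`.

Default conditions: 520-px scenes (≈ 415 px per metre inside the frame),
plant densities spanning 75–300 per m² (the agronomic range of the
underlying field design), leaf ribbons 34 ± 6 px long and 5 ± 0.6 px wide,
15% curl probability, 25 straw distractors. Two candour notes. First, the
ribbon width corresponds to ~1.2 cm, wider than a literal wheat blade at
this resolution; it was fixed once so that rendered blades stay above the
noise scale of a radius-1 opening, and it emulates the visual footprint of
a blade cluster rather than a botanical blade. Second, the generator omits
shadows, specular soil highlights, wind blur and perspective foreshortening
of plants — passing tests demonstrate the pipeline's internal consistency
and the recoverability of counts under controlled conditions, not field
performance.

Variety is emulated by leaf-length factors (`variety_profiles()`: lax HM7
1.15, half-erect YM23 1.00, erect YF4 0.88), aligned in direction with the
published variety coefficients (more canopy per plant ⇒ smaller `Va`).

## Numerical and scale choices

* Problem sizes: the test-suite's end-to-end experiment calibrates on 120
  scenes and validates on 60 (four densities × three stages × replicates)
  at `target_size = 400`; the module-level agreement checks
  (mask-versus-truth IoU) run at the published 800-px target where blades
  span enough pixels for overlap metrics to be boundary-tolerant.
* Otsu ties resolve to the lowest threshold; bin count (256) is
  configurable.
* Homographies use the row-vector convention `[x', y', w'] = [x, y, 1]·H`
  with `x = column`, `y = row`, and `a33 = 1`.
* Corner canonical order is by angle about the centroid, rotated so the
  first corner minimises `row + col`.
* Negative seedling estimates are clamped to zero with a warning flag; the
  published equations can go negative near the origin and the source does
  not address it.
* Leaf age is supplied by the user (it is a scouting observation, fractional
  by design); the package never infers it from imagery.

## Known limitations

Chain-code curvature at unit offset cannot distinguish a ~45° staircase
edge from genuine turning; frame corner detection works at chord scale for
this reason, and very obliquely photographed frames (beyond the generator's
6% tilt bound) are untested. The colour thresholds assume a white frame
markedly brighter than everything else; overexposed straw or specular water
could defeat them. The calibration transfers only within the 1–3 leaf-stage
window and the densities it was fitted on; both models extrapolate linearly
and will degrade gracefully but silently outside it.
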