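---
title: "A locust-inspired collision detector for low-resolution frame sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A locust-inspired collision detector for low-resolution frame sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomrisk)
```

## The problem and the model

Locusts avoid collisions using a small set of looming-sensitive neurons
(LGMD and its postsynaptic partner DCMD) that fire in bursts when the
retinal image of an object expands as it does on a collision course.
`loomrisk` implements a numeric abstraction of that pathway for grey-scale
dashboard-camera-like footage at insect-eye resolution (roughly 200 x 110
elements). No membrane potentials, spikes or synaptic conductances are
simulated: each stage is a small arithmetic rule applied per element of the
frame grid.

Grey values are carried on a 0-9.9 scale; 8-bit input is mapped linearly by
$v \cdot 9.9 / 255$. All thresholds below are in these grey-value units.

The per-frame pipeline is:

1. **Excitation.** The luminance change of each element between consecutive
   frames, $|F_t - F_{t-1}|$, is differenced again against the previous
   pair's change, and the absolute result is the element's *e-potential*.
   This second-order differencing cancels any luminance change that is
   constant over time — global illumination drift, and also the steady creep
   of an edge moving a constant fraction of an element per frame — while
   responding strongly to image acceleration, which is the signature of
   looming.
2. **Threshold.** E-potentials must strictly exceed a per-run threshold to
   contribute. The default is derived from the film's Michelson contrast
   $(a-b)/(a+b)$ of a representative frame (the first, by default) via the
   empirical line $0.71 \cdot \mathrm{contrast} + 0.378$; an explicitly
   configured threshold always wins, because in practice the value is tuned
   per film (0.2 for low-contrast, up to 0.7 for high-contrast material).
3. **Cluster rule.** An excited element survives only if more than 10
   excited elements (itself included) lie within a Euclidean radius of 3.
   This rejects isolated flicker and one-element-wide streaks — a
   primitive object test.
4. **Danger zone.** All risk sums are restricted to a circular region where
   frontal collisions are expected, minus the top and bottom quarters of
   the frame (overhead signs and road/lane markings respectively). Its
   center and radius are set per run; in a vehicle both follow from speed
   and steering angle.
5. **Risk.** Two terms: $R_{coll} = (w/s)\sum E_k$ over supra-threshold
   zone members ($w$ excited members, $s$ zone size), and a
   center-proximity bonus $R_{dist} = 10 \sum 1/d_k$ over members with
   $e > \max(0.5, \mathrm{threshold})$ at distances $0 < d_k < r/2$ from
   the zone center. $R_{dist}$ joins the total only when more than 15
   members qualify. The gain 10 controls the contribution of the proximity
   term.
6. **Direction-selective layers.** Four copies of the e-layer receive
   delayed lateral inhibition from 11 elements in a radius-3 hemicircle on
   their null side (right of the focal element for the rightward-preferring
   layer, and 90-degree rotations for the rest). Inhibition is
   distance-weighted, $I_{dist} = 0.35\sum E_k/d_k$, computed from the
   previous step's e-layer, and decays by 2 per step from its stored value;
   a fresh value exceeding the decayed store by more than 1.5 replaces it
   and resets the decay clock. The layer's *i-potential* is
   $\max(0, E - I_{decay})$. For null-direction motion the inhibition
   arrives together with the excitation and cancels it; for
   preferred-direction motion the inhibitors have not yet fired.
7. **Local motion vectors.** Per element, each layer's excited elements
   (i > 0.1) within radius 3 are counted. With more than 9 excited overall,
   one layer beating every other by more than 4 sets the direction; two
   adjacent layers each beating the remaining two set the bisecting
   diagonal, giving 45-degree precision. Opposed dominant layers are
   contradictory and yield no vector.
8. **Artifact suppression.** If the largest fraction of vectors within
   ±45 degrees of any direction exceeds 1/2, the whole field is moving
   coherently — self-motion or camera shake — and the risk estimate is
   suspended (reported as 0). If more than 40% of zone members carry
   e-potentials above 0.5 the detector is overstimulated and likewise
   suspends. If more than 20% of the lower half of the zone carries
   vectors pointing toward the lower frame border (±45 degrees), those
   elements are classified as ground shadow and their e- and i-potentials
   are zeroed before risk and steering are computed.
9. **Steering.** The difference between the zone-restricted excitations of
   the right- and left-preferring layers
   ($E_{layer} = (m/s)\sum i \,|\, i > 0.1$, with $m$ the members above
   1.0) must strictly exceed 6 to indicate an evasive maneuver — away from
   the side whose layer is more strongly excited. The force is exported as
   the raw absolute difference; downstream controllers apply their own
   gain.

Every comparison above is strict, matching the rule statements; boundary
cases (exactly 40%, exactly 50%, a difference of exactly 6) do not trigger.

## Warm-up and timing

Valid e-potentials need two preceding frame pairs, so the first two frames
of every run are flagged `warm_up` and report zero risk. Direction
selectivity additionally needs one step of inhibition history: layer
excitations are equal by construction on the first excitable frame, and
become informative from about the fifth frame. Inhibition follows a strict
one-step delay: $I_{dist}$ computed from the e-layer of step $t-1$ is
stored (resetting the decay clock) and applied within step $t$; the decayed
tail acts on later steps. The alternative bookkeeping — applying the fresh
value only one step later — was rejected because it fails the whole-field
cancellation property (a global luminance step must drive i-potentials to
zero one step after it excites them) and because the extra latency lets any
motion faster than ~1.5 elements/frame outrun the radius-3 hemicircle,
destroying direction selectivity at realistic speeds.

One processing step equals one frame. Time "constants" (the decay step of
2, the one-step delay) are therefore frame-rate dependent; footage at 29
frames/s is the design point, and no rescaling rule for other frame rates
is provided (a known limitation — at 14 frames/s the detector responds
late).

## Parameters

| constant | default | units | meaning |
|---|---|---|---|
| `e_threshold` | contrast-derived | grey value | minimal luminance change that counts |
| `cluster_radius` / `cluster_min_count` | 3 / 10 | elements / count | compactness test |
| `zone_radius` | 50 | elements | danger-zone size (per-run) |
| `top_exclusion`, `bottom_exclusion` | 0.25 | frame-height fraction | excluded bands |
| `dist_gain` | 10 | — | weight of the proximity term |
| `n_gate` | 15 | count | qualification gate for `r_dist` |
| `inhibition_weight` | 0.35 | — | lateral inhibition strength |
| `reset_threshold` | 1.5 | grey value | margin to refresh stored inhibition |
| `decay_step` | 2 | grey value/step | inhibition decay rate |
| `hemicircle_radius` | 3 | elements | inhibitory neighborhood (11 elements) |
| `vector_min_excited` / `dominance_margin` | 9 / 4 | count | vector rules |
| `overstim_limit` / `coherence_limit` / `shadow_fraction` | 0.40 / 0.5 / 0.2 | fraction | suspension rules |
| `steering_threshold` | 6 | excitation | minimal layer-excitation difference |

## What the synthetic stimuli emulate — and what they do not

Real validation footage (dashboard recordings of crashes and ordinary
traffic) is not redistributable, so the package ships deterministic
generators that emulate the structural features each pathway needs:

* `looming_square()` — a dark square growing exponentially about the zone
  center, the accelerating-expansion signature of an approach at constant
  speed. Exponential (not linear) growth is the default deliberately:
  second-order differencing cancels constant-rate edge motion, so a
  slowly, linearly growing object is — correctly — nearly invisible to the
  detector until its expansion accelerates.
* `translating_bar()` — a dark bar crossing at constant integer speed:
  an object passing by safely. Integer element speeds are used in all
  translating scenes because constant sub-element creep produces
  constant-rate luminance ramps that the differencing cancels by design.
* `camera_shake()` — rigid whole-field shifts (random-walk jitter or
  constant drift) of a static cluttered background; exercises the
  coherent-motion suspension.
* `ground_shadow()` — two dark stripes (a bridge shadow and its railing)
  sweeping down through the lower half of the zone while widening, with an
  exact mirror image sweeping upward above the zone (the overhead structure
  itself). The upward counterflow is not decoration: the coherence rule
  windows span ±45 degrees, so three adjacent direction bins are pooled,
  and any scene whose only motion is the downward shadow would be
  suspended as whole-field motion before the shadow rule could act. Under
  forward self-motion real scenes always carry such counterflow (ground
  features stream down, overhead structures stream up); the generator
  reproduces it with an exact raster mirror so the up/down vector counts
  balance and the strict >50% rule stays silent. Half-integer band
  coordinates align stripe edges with element boundaries, so each step
  covers whole rows — again avoiding the constant-rate cancellation.

The generators do **not** emulate sensor noise, compression artifacts,
perspective distortion, textured objects, or multiple independent objects.
A pass on these scenes demonstrates that each rule behaves as specified on
inputs with the right structure, not that the detector meets any
performance bar on real traffic footage.

Scene sizes (60 frames of 200 x 110 elements for the looming/translating
comparison, 10-30 frames for the rule-specific scenes) keep the whole test
suite and the acceptance script comfortably within a minute or two on one
CPU while leaving every spatial constant at its design value.

## Numerical and design choices

* **Neighborhoods** are Euclidean on the integer lattice; the focal element
  counts toward its own cluster (the multi-agent "in-radius" convention).
  All neighborhoods clip at the frame border — a traffic image is not a
  torus.
* **The cluster filter counts on the pre-filter layer**, so its result is
  independent of sweep order and it is idempotent.
* **Hemicircle membership** is the strict half-plane (dx ≥ 1 for the
  rightward layer) intersected with the radius-3 disk, which yields exactly
  the 11 stated elements; the other three layers are literal 90-degree
  rotations of that offset list, in the same stored order. Because the
  inhibition sum accumulates offsets in list order, the four layers are
  bit-exactly equivariant under 90-degree rotations of the input — a strong
  regression guard that the tests assert with `identical()`.
* **The distance-term qualification** uses `e > max(0.5, threshold)`, the
  conservative intersection of the two printed conditions for which
  elements count as "excited" there.
* **Negative intermediate values clamp at zero** (decayed inhibition and
  i-potentials both).
* **Suspension zeroes the reported risk** for that frame rather than
  holding the last value, and steering advice is withheld on suspended
  frames — no actuation recommendation is issued while the input is judged
  unreliable.
* **Ties between opposed dominant layers** yield no vector: opposed
  "dominant" directions are contradictory evidence.
* **Shadow candidates** are zone members strictly below the zone center's
  row with vectors in {225°, 270°, 315°} (screen coordinates, 270° =
  straight down).
* The `Eq.-style` contrast-to-threshold line does not reproduce the
  per-film thresholds actually documented for the validation films; the
  configured per-run threshold therefore takes precedence and the formula
  is a convenience default.

## Known limitations

* Single static danger zone per run; speed-coupled dynamic sizing is a
  config hook without logic behind it.
* The coherence rule suspends any scene whose only moving content is one
  coherent object — including a lone crossing bar on a clean background.
  On real footage, background flow dilutes the vector histogram; on
  minimal synthetic scenes it does not, which is why the harmless-crossing
  scene reports zero (suspended) risk rather than a small positive one.
* Sensitivity to small objects (pedestrians, animals) is limited by the
  working resolution; the spatial constants (radius-3 neighborhoods, the
  11-element hemicircle) are calibrated to ~200-element-wide frames and
  must be re-tuned together if the resolution changes.
* No vehicle dynamics: steering output is a direction and a dimensionless
  force.

## A worked run

```{r}
stim <- looming_square(n_frames = 40)
res <- process_sequence(stim$frames, cd_config(e_threshold = 0.7))
res
tail(res$results[, c("frame_index", "r_coll", "r_dist", "total_risk",
                     "suspended", "steering_direction")])
```

The risk trace rises as the square's expansion accelerates; a matched
translating bar under the same configuration stays at zero (its coherent
motion is flagged as self-motion-like and suspended).
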