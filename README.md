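# loomrisk

Locust-inspired collision-risk estimation from low-resolution grey-scale
frame sequences.

Locusts detect impending collisions with a dedicated looming-sensitive
neural pathway (LGMD/DCMD) that responds to the accelerating expansion of
an object's retinal image. `loomrisk` implements a numeric abstraction of
that pathway as a frame-sequence processing library plus CLI, aimed at
dashboard/windscreen-camera footage downsampled to insect-eye resolution
(about 200 × 110 elements). It is intended for researchers in bio-inspired
machine vision and for prototyping camera-only crash-warning logic.

## The algorithm

Per frame, on grey values mapped to [0, 9.9]:

* **e-potentials** — second-order absolute frame differencing
  `| |F_t − F_{t−1}| − |F_{t−1} − F_{t−2}| |`, thresholded (strictly) at a
  per-run level and cleaned by a cluster rule (an excited element needs
  > 10 excited elements within a radius of 3).
* **collision risk** inside a circular *danger zone* (minus the top and
  bottom quarter of the frame):
  `R_coll = (w/s) · Σ E_k` over supra-threshold zone members, plus a
  center-proximity term `R_dist = 10 · Σ 1/d_k` over strongly excited
  members with `0 < d_k < r/2`, added when more than 15 members qualify.
* **four direction-selective layers** with delayed, distance-weighted,
  decaying lateral inhibition (`I_dist = 0.35 · Σ E_k/d_k` over an
  11-element hemicircle on the null side; decay 2 per step; reset margin
  1.5), giving per-element **local motion vectors** at 45° precision.
* **artifact suppression** — risk is suspended when > 50% of vectors share
  a direction ±45° (self-motion/camera shake) or > 40% of the zone is
  excited above 0.5 (overstimulation); elements in the lower zone half
  whose vectors point toward the lower border are masked as **ground
  shadows** when > 20% of that region does.
* **evasive steering** — the right/left layer-excitation difference must
  strictly exceed 6; the maneuver points away from the stronger side.

A deterministic synthetic-stimulus module (looming square, translating
bar, camera shake, ground shadow with overhead counterflow) provides
labelled scenes that exercise every pathway.

## Worked example

```r
library(loomrisk)

stim <- looming_square(n_frames = 40)            # object on collision course
res  <- process_sequence(stim$frames, cd_config(e_threshold = 0.7))
res
#> <cd_result> 40 frames | peak total_risk 680.44 (frame 34) | 0 suspended | e-threshold 0.700

subset(res$results, frame_index %in% c(10, 20, 30, 39),
       select = c(frame_index, r_coll, r_dist, total_risk))
#>    frame_index    r_coll   r_dist total_risk
#> 10          10   0.00000   0.0000     0.0000
#> 20          20   4.87916 137.6177   142.4968
#> 30          30 133.89964 196.2266   330.1263
#> 39          39 345.34306   0.0000   345.3431
```

The total risk climbs as the square's expansion accelerates: first through
the center-proximity term `r_dist` while the object is small and central,
then through `r_coll` as its expanding edges excite a growing fraction of
the zone. A matched translating bar under the same configuration reports
zero risk throughout — its single coherent motion direction is flagged as
self-motion-like and the estimate is suspended.

From a shell, the same pipeline runs over PNG/TIFF sequences or the
built-in scenes:

```sh
cd-run --input frames/ --target-width 200 --out results.csv --overlay overlays/
cd-run --stimulus looming --seed 1 --out looming.csv
```

The per-frame CSV carries risk components, suspension flags and reasons,
steering direction and force, coherence fraction, and shadow counts; the
overlay PNGs tint excited elements red, shadow elements yellow, draw local
motion vectors and the zone outline, and add the steering arrow.

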