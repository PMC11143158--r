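---
title: "Grid-cell firing fields from place-cell reference frames: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cell firing fields from place-cell reference frames: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridscape)
```

## The model

`gridscape` treats a grid cell as a coordinate system rather than a
dynamical unit. Positions are first obtained by path integration of speed
and heading inside a *place-cell frame* — a 2D local frame anchored to the
external cues of the current environment. A grid cell
`G = (s, theta, phase)` then defines an oblique lattice space spanned by

$$\epsilon_1 = s(\cos\theta, \sin\theta), \qquad
  \epsilon_2 = s(\cos(\theta + \pi/3), \sin(\theta + \pi/3)),$$

and a place-frame position $p$ maps linearly into lattice coordinates

$$g = [\epsilon_1\ \epsilon_2]^{-1} p - \vartheta .$$

Integer lattice coordinates are *preferred positions*; because the basis
vectors subtend exactly 60 degrees, their pre-images form a hexagonal
(triangular) lattice with spacing $s$, orientation $\theta$ (periodic with
period $\pi/3$) and a translation set by the phase $\vartheta$.

The firing rate is a function of the residual distance
$d = \lVert g - [g] \rVert$, with $[\cdot]$ componentwise rounding:

$$\varsigma = \operatorname{clip}\!\left(\tfrac12 -
  \tfrac1\pi \arctan\!\big(\kappa\,(d/s - \zeta)\big),\ 0,\ 1\right).$$

This normalization is a deliberate design choice. A bare
$\arctan(\kappa(d/s - \zeta))$ is negative near field centers and grows
with distance, which contradicts every property demanded of the rate —
values in $[0,1]$, maxima at preferred positions, $\zeta$ acting as a
firing threshold and $\kappa$ as a bump-sharpness control. The affine
rescaling above is the minimal monotone-decreasing form that satisfies
all of them: the rate crosses $0.5$ exactly where $d/s = \zeta$, tends to
$\tfrac12 + \tfrac1\pi\arctan(\kappa\zeta)$ at centers and to
$\tfrac12 - \tfrac1\pi \cdot \tfrac\pi2 = 0$ far away.

Two further reading decisions are built in:

* **Distance.** The squared form $ (g-[g])^\top (g-[g]) $ is sometimes
  written for $d$, but the threshold semantics and the word "distance"
  require the Euclidean norm; `lattice_distance(..., method = "squared")`
  preserves the literal squared variant.
* **Division by `s`.** `d` is measured in lattice units and is divided by
  `s` again inside the sigmoid. A consequence worth knowing: the bump
  radius *relative to the spacing* grows linearly with `s` (at the default
  `zeta = 0.4`, fields of cells with `s` above about 1.4 m merge into a
  continuous elevation with local maxima). The multi-cell spacing sweep
  shows bump size growing with spacing accordingly.

Phases are stored wrapped to $[0,1)$ lattice units, matching their role as
a subtractive offset of lattice coordinates and the worked values (0.5,
0.4, 0.8) used in the experiments. Componentwise rounding uses
half-away-from-zero ties for cross-platform determinism. Rounding in the
oblique frame can occasionally pick a lattice point that is not the
Euclidean-nearest in world space; we keep the componentwise rule, whose
effect is confined to low-rate regions between fields.

## Reference frames and their adjustment

A `frame_transform` maps world coordinates into a compartment's place
frame via $p = R(\phi)\,w + \varpi$. The reference compartment's frame is
the identity, i.e. the global frame. In a freshly entered multi-compartment
environment, perceptually identical compartments receive identically
oriented frames with different origins, so the firing pattern *replicates*
across compartments; frames that also differ in orientation (the
four-compartment arena) produce patterns related by rotation and
translation.

With experience the non-reference frames converge to the global frame.
One trajectory sample inside a non-reference compartment triggers one
adjustment step of that compartment's frame: with the current
componentwise difference $(\phi_d, \varpi_d)$ from the target and gain

$$\gamma(N_t) = \frac{\alpha}{\beta + e^{-\xi (N_t - M)}},$$

the difference contracts to $(1-\gamma)\,(\phi_d, \varpi_d)$. The
difference is recomputed from the current frames at every step (it carries
the time index), angles are wrapped to $(-\pi, \pi]$ so the angular decay
is well defined, and $0 < \gamma < \alpha/\beta \le 1$ makes both
difference magnitudes non-increasing, strictly decreasing when nonzero —
geometric convergence once $N_t$ passes $M$.

**Experience counter.** $N_t$ counts trajectory samples taken in
non-reference compartments and expresses familiarity with the
environment's connectedness. By default the counter is *shared* across
compartments: a single familiarity variable gates all frame adjustments,
while each frame still only moves when its compartment is visited, so
compartments converge at different times. The alternative — fully
independent per-compartment counters — is available via
`adjustment_state(counter = "per_compartment")` and the `counter` config
key. We made the shared form the default for two reasons: it is the more
natural reading of a familiarity signal ("the animal realizes the
compartments are connected"), and it is robust at reduced simulation
scale, where per-room occupancy fluctuates severalfold between seeds and
an unlucky room can otherwise starve below $M$. In a two-compartment
arena the two modes coincide.

Convergence tolerances default to $10^{-3}$ rad and $10^{-3}$ m, well
below the rate-map bin resolution (0.1 m).

## The trajectory generator

The random walk is a surrogate for rodent open-field foraging: speed is
nominally 0.3 m/s with
mean-corrected lognormal jitter (log-sd 0.1), heading performs a wrapped
Gaussian random walk with increment sd 0.15 rad per 0.1 s step
(persistence length roughly 1.3 m, matching the fairly straight runs of a
foraging rodent), and a step that would cross a wall re-draws the heading
uniformly until an admissible direction is found. The generator is a pure
function of `(environment, parameters, seed)`.

What it emulates: ergodic coverage of the arena (a 200,000-step walk
visits over 95% of 0.1 m bins of the 5 x 5 m arena) and adequate mixing
between compartments, which the frame-adjustment experiments need. What
it does not emulate: thigmotaxis, goal-directed runs, realistic speed
profiles, head-direction/speed-cell noise, or any sensory model. Passing
tests therefore show properties of the model under idealized uniform-ish
sampling, not robustness to the occupancy biases of real behavior.

Arena layouts: a 5 m x 5 m square; a circle of radius 2 m; two 5 x 4 m
compartments separated by a 0.5 m wall and joined by a 1 m-wide corridor
along the top (place-frame origins at each room's left-bottom corner,
equal orientations; the initial translation difference is 5.5 m); and a
2 x 2 grid of 3 x 3 m rooms joined by four 1 m doorway corridors, with
frame orientations 0, 90, 180, 270 degrees. Corridor dimensions are
configurable; only the connectedness topology matters to the model. Corridor samples are
assigned to the reference frame and excluded from map comparisons.

## Rate maps and metrics

`bin_rate_map()` bins samples into half-open 0.1 m bins (at least ten bins
per spacing at the smallest spacing used, 0.5 m) and stores per-bin mean
rate and occupancy. The *correlation of global fit* is the Pearson
correlation, over jointly visited non-corridor bins, between the map
under the current (possibly mid-adjustment) frames and the map with every
compartment expressed in the reference frame. It is computed over the full
trajectory at each checkpoint, so the curve isolates the state of the
frames; it is low under replicated local fields and reaches 1 when the
frames coincide with the global frame.

The adjustment-off *replication check* compares per-compartment maps in
local frame coordinates. Its error budget is dominated not by counting
noise but by within-bin sampling bias (field gradient times the offset of
the mean sample position from the bin center), so the comparison uses
half-size bins and only bins visited at least twice in both maps; under
these choices replicated compartments correlate above 0.99 at the scaled
run length. Where rotated frames make the local windows disjoint
(four-compartment), each local map is compared against the analytic field
on its own window instead of against another empirical map.

**Lattice-parameter estimation.** From exact field centers,
`estimate_lattice_params()` uses the modal nearest-neighbor distance
(spacing), the circular mean of neighbor directions folded to period
$\pi/3$ (orientation), and the lattice coordinate of the center nearest
the origin (phase). This recovers generating parameters to 1e-6 and
fails informatively for fewer than 7 centers or collinear sets. From
empirical binned maps, peak detection (raw rate above 0.5, local maximum
of a 3 x 3-smoothed map over a configurable window, centroid refinement)
feeds the same estimator, and `fit_lattice_to_map()` refines the result
by maximizing the correlation between the map and the analytic field over
$(s, \theta, \vartheta)$, with a multi-start over phase to escape the
parameter's periodicity. Template fitting is what makes the large-spacing
regime tractable, where merged fields leave only a shallow modulation for
peak detection.

## Problem sizes and the scaled preset

Default experiment configurations are, for two compartments: cell
`(1.5, pi/4, (0,0))`, schedule `alpha 0.5, beta 1.0, xi 0.1, M 1e5`,
770,000 steps with snapshots at 10,000 / 145,000 / 395,000 / 770,000;
for four compartments: cell `(1.0, pi/4, (0,0))`, schedule
`alpha 0.8, beta 1.0, xi 0.2, M 1e5`, 833,000 steps with snapshots at
50,000 / 320,000 / 575,000 / 833,000.
`scaled_config()` divides steps, `M` and snapshots by 50 and multiplies
`xi` by 50, so the gain traverses the same sigmoid within the shorter
run; convergence depends only on the sigmoid's shape, not on absolute
counts. The test-suite and the acceptance script run at this 1/50 scale
(15,400 and 16,660 steps), and single-cell analyses use 200,000-step
walks; these sizes were chosen as the smallest at which coverage, mixing
and map-noise levels leave comfortable margins on every property checked.

## Known limitations

* One spacing per cell; no dorsoventral module hierarchy, and the cell
  parameters are set, not learned.
* No mechanism for *detecting* connectedness: the experience counter
  simply accumulates, modelling only the consequent frame adjustment.
* The lattice readout is purely positional; no attractor dynamics,
  spiking, or metric (distance-readout) use of the code.
* The arctan normalization and the double division by `s` are modelling
  decisions documented above; alternative readings of the rate law would
  change bump geometry at large spacings.
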