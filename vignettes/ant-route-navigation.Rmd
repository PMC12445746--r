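---
title: "Modelling ant visual route navigation with antnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ant visual route navigation with antnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnav)
```

## The model

Solitary foraging ants retrace habitual routes using remembered panoramic
views. `antnav` simulates an embodied agent doing exactly this, in three
stages.

**World and vision.** A procedurally generated flat world is populated with
tree-like landmarks at a density of 0.007 per m² (heights uniform on
0.1–30 m), each a vertical frustum: a trunk cylinder over the lowest 20% of
the height topped by a wider canopy cylinder. The agent's eye sits 1 cm
above the ground and sees a binary panoramic image of 36 × 180 pixels at 2°
per pixel, with a 50 m clipping distance. Rows span elevations 0–72° above
the horizon: on a flat, featureless plain nothing below the horizon carries
information, so the camera's vertical field is placed entirely above it.
This also makes the obstacle-avoidance threshold of 20° (28% of the view
height) a meaningful apex elevation. Landmarks paint dark silhouettes
(object = 0) on a light sky (1); the skyline is the per-column elevation of
the highest dark pixel.

**Route memory.** Views sampled every 0.2 m along a training route are
flattened (row-major) into vectors of length $N$ and train a one-layer
Infomax network with $M$ output units ($M = N/2$ at full scale) exactly
once each:

$$h_i = \sum_j w_{ij} s_j, \qquad y_i = \tanh(h_i),$$
$$\Delta w_{ij} = \frac{\eta}{MN}\Big(w_{ij} - (y_i + h_i)\sum_k h_k w_{kj}\Big).$$

The raw novelty of a view is $d_\mathrm{raw} = \sum_i |h_i|$; familiar
views elicit weak responses. Raw novelty is normalised to $[0,1]$ between
the mean response to the training views ($d_\min$) and to column-scrambled
training views ($d_\max$), which share the environment's pixel statistics
but no spatial structure. The normalised value is clamped to $[0,1]$
because every downstream controller treats it as a proportion.

**Behaviour.** Training routes are shaped by heuristics: a global vector
(bearing to the goal + 5° Gaussian noise), obstacle avoidance (deflect to
the nearest azimuth whose 2 m-deep skyline drops below 20°; always applied
last), optional beacon aiming, an optional restricted 256° field of view,
an optional gated oscillation
$\vartheta = \vartheta_\mathrm{target} + 55°\sin(115°/\mathrm{m} \cdot l_\mathrm{path})$
with view storage only in the second and fourth phase quarters, and
optional goal-directed learning legs (two straight 8.2 m inbound walks at
±45° to the route direction). Motor noise (sd 15°) perturbs every executed
heading. Test-phase controllers are:

* **VBO** — rotate the view in 2° steps, move toward the minimum of the
  rotational familiarity function (RFF), step 0.2 m;
* **FBM** — no scanning; turn $\alpha(-1)^n d$ and step
  $\beta(1-d) + s_\min$ from the forward view's novelty alone
  ($\alpha = 80°$, $\beta = 0.15$ m, $s_\min = 0.45$ m);
* **CS** — cast $\theta_\mathrm{VBO} + m\,\alpha(-1)^n$ (cast gain
  $\alpha = 60°$, $m$ = best novelty of the scan), but surge straight
  whenever the best novelty improved over the previous step; step 0.30 m
  (0.20 m on gated-oscillation routes).

Scans can be modulated: a 36° head scan estimates local familiarity and
sets the body-scan range
$\varphi = \varphi_\min + m(\varphi_\max - \varphi_\min)$; body scans no
larger than the head scan are skipped.

Test routes terminate within 0.25 m of the goal or at 1.5× the nominal
training length. Convergence is measured by route displacement — the mean,
over *training*-route positions, of the distance to the nearest test-route
position — and by the same quantity restricted to the final 5% of the
training route (goal reaching). A test route is rapidly divergent when it
never enters the closed disk of radius half the start–goal distance centred
on the goal.

## Worked example

```{r example, eval = FALSE}
library(antnav)
L <- 20
env <- generate_environment(child_seed(1, "env", 1), extent = L + 110,
                            center = c(L / 2, 0))
strat <- strategy_config("baseline+CS", m_frac = 8)
training <- build_training_route(env, c(0, 0), c(L, 0), strat$heuristic,
                                 master_seed = child_seed(1, "train", 1))
recap <- recapitulate(env, training, pose(0, 2, 0), strat$recap, seed = 42)
trial_summary(training, recap)
plot_routes(training, recap, env = env)
```

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `density` | 0.007 | m⁻² | landmark density |
| `clip` | 50 | m | camera clipping distance |
| `storage_density` | 5 | m⁻¹ | stored views per metre of path |
| `gv_noise_sd` | 5 | deg | global-vector noise |
| `motor_noise_sd` | 15 | deg | motor noise on executed headings |
| `oa_threshold`, `oa_depth` | 20, 2 | deg, m | obstacle avoidance |
| `A`, `B` | 55, 115 | deg, deg/m | oscillation amplitude and period |
| `goal_loops$length` | 8.2 | m | goal-directed leg length |
| `fbm` | 80, 0.15, 0.45 | deg, m, m | FBM turn/step gains |
| `cs$alpha`, `cs$s_cs` | 60, 0.3 | deg, m | cast gain and CS step |
| `phi_min`, `phi_max` | 36, 360 | deg | head- and body-scan ranges |
| `goal_radius`, `max_path_factor` | 0.25, 1.5 | m, — | termination |
| `eta` | 0.4 | — | Infomax learning rate (below) |
| `m_frac` | 2 | — | network size divisor, $M = N/\texttt{m\_frac}$ |

## Numerical and design choices

**Infomax normalisation and learning rate.** The weight update divides by
$MN$ by default. The per-update gain is roughly
$\eta\, s^\top\!s \cdot M / \mathrm{denom}$; with binary panoramas
($s^\top\!s \approx 0.7N$) the $MN$ denominator keeps the gain below 1 for
any output size, whereas dividing by $N$ alone diverges once $M$ exceeds a
few units (a documented switch, `weight_norm = "N"`, retains that form for
use with correspondingly smaller $\eta$). The learning rate is not a
quantity with an external reference value, so it was calibrated once
against the behaviour the memory must exhibit: trained views must score
clearly below views rendered 10 m off the route, the RFF at a stored pose
must dip at relative heading 0, and the RFF minimum must rise above 0 away
from the route so that casting has a signal to work with — all while
keeping the update gain below 0.5. With binary views, a single pass at
small $\eta$ depresses trained views by less than the scene-to-scene
variation in raw novelty, which saturates the normalised field; $\eta = 0.4$
satisfies all of the checks with a stability margin.

**Conventions.** Headings are degrees counter-clockwise from +x in
$[0, 360)$; column $c$ (0-based) covers relative azimuth
$[-180 + 2c, -180 + 2(c+1))$, so the centre column pair straddles the
heading. Flattening is row-major. VBO argmin ties break toward the smallest
absolute relative heading (prefer straight); discretised novelty can tie on
degenerate scenes even though exact ties are measure-zero under noise. The
first CS step has no novelty history and is treated as "not improving"
(cast), so the agent starts by sampling. The oscillation's phase clock
advances by the commanded step (0.2 m) regardless of the realised heading —
an intrinsic oscillator unaffected by motor noise — and is computed as
`step_index * step` rather than accumulated, because the default settings
place one step (23° × 90 steps = 2070°) exactly on a quarter boundary
where accumulation error could flip the learning gate. Training routes
terminate on the odometric clock reaching the nominal length, which makes
the stored-view count an exact function of route length (100 views on
20 m, 500 on 100 m). Full-panorama scans use in-silico column rotation,
bit-identical to re-rendering by rotation equivariance; restricted-FOV
scans re-render each sample. If a step would land inside a trunk (rare,
because obstacle avoidance runs first), the agent falls back to the
unnoised avoidance heading, then scans outward for a free heading.

**Released agents** face the nominal route direction. The reference
experiments do not state the orientation at release; VBO and CS rescan
anyway, but FBM has no scan, so some convention is required and the route
direction is the neutral one for an agent that has just been displaced
mid-foraging.

**Interrogation bookkeeping.** CS pays the 18-sample head scan every step
in both the modulated and the fixed condition, plus the body scan (80
samples at $\varphi_\max = 160°$; skipped entirely when the modulated range
does not exceed the head scan). Matched modulated/fixed trials share the
same motor-noise stream.

## What the generator emulates — and what it does not

The synthetic world reproduces the statistics the navigation algorithms
actually consume: landmark density, the height distribution, a flat
featureless ground, no distal panorama, and skylines of randomly placed
vertical objects. It does not reproduce photorealistic tree geometry,
greyscale texture, or lighting. Binary silhouettes make nearby views more
similar to each other than textured renders would be: near the route, fresh
views are almost indistinguishable from trained ones, so normalised novelty
sits close to 0 more often than in a textured world. Qualitative contrasts
between strategies (parallel VBO drift, CS convergence and surging, scan
savings from modulation) survive this abstraction; absolute magnitudes that
depend on how quickly familiarity decays around the route — the size of
FBM's wander, the fraction of scanning saved by modulation — are
systematically smaller here than with richer imagery would be expected.
Passing behavioural tests therefore demonstrates the mechanisms, not
field-calibrated magnitudes.

## Problem sizes

Full-scale conditions are 75 environment seeds × 45 release points with
$M = N/2$ networks. The test suite and the acceptance script run desk-scale
versions chosen as the package's own defaults: reduced networks
($M = N/8$ or $N/16$), 2–20 seeds, and 3–5 release points; protocol
objects expose the full-scale settings through their arguments
(`trial_protocol(n_seeds = 75, displacement_spacing = 0.25,
displacement_max = 5.5, m_frac = 2)`).

## Known limitations

* One network, one route: no multiple memory banks or appetitive/aversive
  pairs.
* The renderer's binary intensity compresses the novelty scale (above).
* Obstacle avoidance shares the panorama geometry (36 × 180) at 2 m depth;
  agents enclosed by obstacles abort the trial rather than backtrack.
* The spiking mushroom-body route memory and dual opposing-network
  steering are out of scope by design.
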