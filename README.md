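# antnav

An agent-based simulator of **ant visual route navigation** for
computational neuroethologists and builders of insect-inspired robots. Ants
learn foraging routes as egocentric panoramic views and retrace them by
steering toward familiar scenery. A plain "visual compass" — turn to the
heading whose view best matches memory — follows routes but does not
*converge* to them: displaced agents travel parallel paths and drift away.
`antnav` reproduces, in a procedurally generated world, the behavioural
ingredients that turn the compass into a robust navigator: oscillatory
route learning with phase-gated view storage, goal-directed learning
walks, and a cast-and-surge controller borrowed from olfactory search.

## The model in brief

* **World & vision** — seeded random "woods" (0.007 trees/m², heights
  0.1–30 m) on a flat plain, seen as binary 36 × 180 panoramas (2°/pixel,
  50 m clip) from 1 cm above the ground.
* **Route memory** — a one-layer Infomax network trained once per stored
  view (5 views/m): `h = W s`, `Δw_ij = η/(MN) · (w_ij − (y_i + h_i) Σ_k
  h_k w_kj)` with `y = tanh(h)`. Novelty `d_raw = Σ|h_i|` is normalised to
  [0, 1] between the mean response to training views and to
  column-scrambled training views.
* **Learning heuristics** — global vector (+5° noise) with obstacle
  avoidance; optionally beacon aiming, a 256° restricted field of view, a
  gated oscillation `ϑ = ϑ_target + 55° · sin(115°/m · l_path)` storing
  views only while returning to the axis, and paired 8.2 m goal-directed
  learning legs at ±45°.
* **Recapitulation** — VBO (move to the rotational familiarity function's
  minimum), FBM (klinokinesis: turn `α(−1)ⁿ d`, step `β(1−d)+s_min`), and
  CS (casts `θ_VBO + m·α(−1)ⁿ` suppressed into straight surges while
  familiarity improves), with optionally familiarity-modulated scan ranges
  `φ = φ_min + m(φ_max − φ_min)`. Motor noise sd 15° throughout.
* **Metrics** — route displacement (mean distance from each training-route
  position to the nearest test-route position), its goal-region variant
  (final 5%), rapid-divergence classification, and view-interrogation
  counts.

## Worked example

```r
library(antnav)
L <- 20
env <- generate_environment(child_seed(1, "env", 1), extent = L + 110,
                            center = c(L / 2, 0))
strat <- strategy_config("baseline+CS", m_frac = 8)
training <- build_training_route(env, c(0, 0), c(L, 0), strat$heuristic,
                                 master_seed = child_seed(1, "train", 1))
recap <- recapitulate(env, training, pose(0, 2, 0), strat$recap, seed = 42)
trial_summary(training, recap)
```

```
<ant_environment> seed 1063297527: 118 landmarks over a 130 m square (density 0.007 /m^2)
<infomax_network> 6480 -> 810 units, eta = 0.4, trained on 100 views (calibrated)
<ant_recap> CS: 100 steps, 19800 view interrogations, terminated: max_path
  route_displacement goal_displacement rapidly_divergent interrogations_total
1               2.14              2.16             FALSE                19800
  interrogations_per_step n_steps path_length termination
1                     198     100          30    max_path
```

The cast-and-surge agent, released 2 m off a 20 m learned route, runs its
capped 30 m test path while staying on average 2.1 m from the route — and
equally close to the goal region — scanning 198 view samples per step
(18-sample head scan + 180-sample body scan). `plot_routes(training,
recap, env = env)` draws the training route, test path and landmarks;
`autoplot(compute_rff(training$network, env, pose(0, 2, 0)))` shows the
rotational familiarity function the controller steers by.

Experiment protocols wrap this loop: `run_displacement_trial()` sweeps
strategies × seeds × release points into a tidy results table
(`summarize_trials()` aggregates seed-first, as the displacement protocol
prescribes), and `run_scan_sweep()` compares familiarity-modulated against
fixed scanning across maximum scan ranges. A thin command-line front end
lives at `inst/scripts/antnav-cli.R`.

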