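# refnav

Reference-frame based spatial navigation simulator.

`refnav` is for computational neuroscientists and roboticists who want a
compact, fully inspectable model of how an agent combines **allocentric**
(world-anchored), **egocentric** (self-anchored) and **route-centric**
(learned-sequence) representations of space to reach goals. The model couples:

* a **population code**: every directional signal (head direction, allocentric
  and egocentric goal direction, egocentric cue direction) is carried by 360
  Gaussian-tuned units, `e_i = exp(-Δ(θ_i, θ_in)² / σ²)` with σ = 10°,
  plus zero-mean activity noise and max-normalization;
* a **hippocampal cognitive map**: a landmark graph with winner-take-all place
  cells, shortest-path route search, and a 360-unit allocentric goal direction
  population;
* a **retrosplenial arbitration stage**: the allocentric→egocentric frame
  transformation (EGD = AGD − heading), a per-strategy confidence system
  (exponential decay λ, additive bonuses u for approach, route progress and
  goal-cue alignment, stuck handling) and softmax strategy selection
  `p_i = exp(c_i/T) / Σ_j exp(c_j/T)`;
* a **parietal stage**: distance-attenuated egocentric cue direction cells
  (`(D/d_c)·G`), goal-modulated EGCD cells, conjunctive HD×ECD cells,
  sequential-egocentric and cue-following route execution, and three movement
  cells (left/forward/right band sums);
* a **motor stage**: movement cells → two wheel velocities normalized to
  max 0.5 → differential-drive pose update with wall-sliding collisions.

Three built-in experiments exercise the model: a blinking-light arena
(conjunctive-cell tuning), a five-armed star maze (allocentric vs sequential
egocentric strategy competition), and an eight-region vista-space world
(hierarchical route navigation with stuck-escape).

## Worked example

Run a small star-maze probe experiment — the agent is trained on the
alley-1→7 route, then released in alley 5, where the trained turn sequence
and the allocentric goal pull in different directions:

```r
library(refnav)
res <- run_starmaze(nav_config(), n_trials = 20, seed = 42)
print(res)
#> <experiment_result: starmaze> 20 trials, seed 42
#>   counts: allocentric 3, egocentric 12, mixed 5 (timeouts 0)
#>   percentages: allocentric 15.0%, egocentric 60.0%, mixed 25.0%
```

Each trial is classified from the trajectory alone: ending at the alley-1
dead end means the agent replayed the trained sequence (egocentric); reaching
the alley-7 goal directly means it trusted the map (allocentric); entering
alley 1 and then still finding the goal is a mixed trial — the confidence
system lost faith in the replay mid-run and handed control to the
allocentric frame.

The vista world shows the same machinery doing hierarchical navigation:

```r
v <- run_vista(nav_config(), n_trials = 10, seed = 1)
print(v)
#> <experiment_result: vista> 10 trials, seed 1
#>   completion: 100.0%
#>   mean contribution: allocentric 21.2%, egocentric 12.6%, route_cue 66.2%
```

`mean_contribution` is the share of goal-progress steps each strategy
produced: route-centric travel over region centroids does most of the work,
with the direct strategies filling in inside regions — and getting the agent
stuck in the trap region until stuck-handling hands control to the route.

A thin CLI wraps the runners:

```sh
Rscript inst/cli/refnav starmaze --seed 1 --trials 130 --out out/
Rscript inst/cli/refnav vista --seed 1 --trials 80 --block-corridor 9,1 --out out/
```

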