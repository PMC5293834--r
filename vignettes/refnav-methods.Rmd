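---
title: "refnav: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{refnav: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`refnav` simulates goal-directed spatial navigation as the interplay of three
representations of space — allocentric (world-anchored), egocentric
(agent-anchored) and route-centric (a learned sequence of choice points or
cues) — carried by Gaussian-tuned neural populations and arbitrated by a
per-strategy confidence system. A differential-drive agent closes the loop:
population activity becomes movement-cell drive, wheel velocities, and a new
pose.

This vignette documents the model equations as implemented, every tunable
parameter with its default and unit, the deliberate design choices made where
the architecture leaves room, and what the built-in experiments do and do not
demonstrate.

# Population code

All directional signals use the same code. Unit $i$ of an $N$-unit population
(default $N = 360$, one unit per degree) has preferred angle
$\theta_i = (i-1)\,360/N$ and activity

$$e_i = \exp\!\left(-\frac{\Delta(\theta_i, \theta_{\mathrm{in}})^2}{\sigma^2}\right),$$

where $\Delta$ is the *wrapped* circular difference in degrees and
$\sigma = 10$ globally. Wrapping is essential: with a raw difference, units
near the 0/360 seam would be blind to inputs on the other side of the seam.
All angles in the package follow one convention: degrees, $0^\circ$ along
$+x$, counter-clockwise positive, wrapped into $(-180, 180]$.

After a population is computed, unit-wise zero-mean Gaussian noise
(`noise_sd`, default 0.05) is added, negative activities are clamped to zero
(firing rates), and the population is divided by its maximum so the most
active unit reads exactly 1. The literal activity-centred, variance-5 noise
reading is available behind `nav_config(noise_literal = TRUE)` but swamps the
signal (activities live in $[0,1]$); the 0.05 default is a calibrated
stand-in that keeps decoding errors within about $\pm 3^\circ$, which is what
the behaviour downstream tolerates without becoming deterministic.

Decoding (`population_peak`) is the argmax preferred angle, ties toward the
lowest angle.

# Hippocampus: cognitive map

The map is a landmark graph: Cartesian landmark positions plus symmetric
edges whose distance and allocentric direction are always derived from the
coordinates (never stored separately, so they cannot drift out of sync).
Place coding is winner-take-all: the landmark nearest the agent is the active
place cell. Routes are minimum-distance landmark sequences (Dijkstra via
igraph, deterministic tie-breaks). The goal vector of a route telescopes to
the straight displacement from first to last landmark; the allocentric goal
direction (AGD) is therefore recomputed every step as the direct bearing from
the agent's live position to the goal and encoded in the 360-unit AGD
population. Maps are supplied to the agent; there is no map learning.

# Retrosplenial stage: frame transformation and arbitration

Head direction (HD) is encoded from the agent's internal compass. The
egocentric goal direction (EGD) population encodes
$\Delta(\text{AGD peak} - \text{HD peak})$: 0 means the goal is dead ahead,
the sign follows the counter-clockwise-positive convention.

Each enabled strategy $i$ carries a confidence $c_i \in [0,1]$, initialised
at 0.8. Per step:

* all values decay, $c_i \leftarrow c_i(1 - \lambda_{\mathrm{default}})$,
  $\lambda_{\mathrm{default}} = 0.02$;
* if the felt distance to the goal decreased, the active strategy gains
  $u_{\mathrm{default}} = 0.025$; if it increased, the active strategy decays
  by $\lambda_{\mathrm{dist}} = 0.002$;
* on route progress the active strategy gains $u_{\mathrm{progress}} = 0.25$;
* when the goal-cue direction (EGCD peak) is within $\pm 10^\circ$ of
  straight ahead, the active strategy gains the alignment bonus
  ($u_{\mathrm{ego}} = 0.05$ in the star maze, $u_{\mathrm{direction}} =
  0.005$ in the vista world — kept as separate keys);
* when stuck, the active strategy decays by $\lambda_{\mathrm{stuck}} = 0.02$
  and all others gain $u_{\mathrm{stuck}} = 0.01$;
* values are clamped to $[0,1]$.

The *felt distance* feeding the approaching/receding events is
experiment-specific, as the architecture prescribes experiment-specific
confidence computations: the straight-line distance in the open arena and the
star maze (with a $10^{-6}$ dead band), but the cognitive-map route length
(straight leg to the active place cell, graph distance to the goal's
landmark, straight leg to the goal) in the multi-region vista world, where
straight-line progress across walls is meaningless and would reward pressing
into them.

Strategy selection is a softmax over confidences,
$p_i = e^{c_i/T} / \sum_j e^{c_j/T}$, sampled with a single uniform draw over
the cumulative partition in strategy-id order. Two knobs are deliberately
exposed because the architecture does not state them:

* **Decision period `P`** (default 10 steps): re-evaluating every step makes
  the agent thrash; holding the chosen strategy for `P` steps yields the
  coherent trajectory segments the behaviour requires.
* **Temperature `T`** (default 0.0275): confidences live in $[0,1]$, so the
  plain $T = 1$ softmax is nearly uniform over them and cannot commit to a
  strategy. `P` and `T` were calibrated once against the star-maze strategy
  distribution on a dedicated seed set (900001–900004) and then frozen; no
  other parameter was fitted.

Stuck detection keeps a reference position: if the agent stays within
`stuck_radius` (1 length unit) of it for more than `stuck_threshold` (50)
steps, stuck events fire until it breaks away. A place-cell-dwell criterion
was rejected because with region-sized place fields it cannot distinguish
normal traversal of a region from genuine immobility.

# Parietal stage: cues, EGCD and movement cells

Cue sensing returns, per visible cue, the Euclidean distance $d_c$ and
egocentric direction. ECD units sum $(D/d_c)\,G(\theta_i, \theta_c, 10)$ over
cues, $D = 3$ relating distance to drive. EGCD units modulate ECD by EGD
through a broad weight matrix $w_i(m) = G(\theta_i, \theta_m, 80)$: EGD units
above 0.5 contribute $e^{\mathrm{gd}}_m w_i(m)$, weaker units contribute
$e^{\mathrm{gd}}_m (w_i(m) - 1)$ (inhibition); negatives clamp to zero. The
net effect is that the cue angularly closest to the goal direction wins. For
the cue-following route strategy the EGCD is a pure bump at the current
target's egocentric direction (route goal cues are treated as visible from
everywhere, so distance is ignored).

Movement cells sum fixed index bands of a 360-unit egocentric population
(unit $k \leftrightarrow$ angle $k - 180$): left $[1,180]$, forward
$[126,234]$, right $[181,360]$, overlapping as printed. Note the bands are
not perfectly symmetric — the $0^\circ$ unit belongs to the left band only —
so a bump dead ahead produces a sub-degree-per-step steering bias that the
closed loop corrects; the tests assert this explicitly rather than a fake
exact symmetry.

Conjunctive cells multiply the HD-population activity at their preferred
head direction with the ECD-population activity at their preferred cue
direction; with noise off the response factorizes exactly.

## Sequential egocentric replay

A trained route is stored as (choice point, turn command) pairs, commands
$\pm 180$. Executing a command saturates the one-sided movement-cell drive.
Two implementation decisions matter:

* **Turn termination.** A saturated one-sided drive makes the agent pivot on
  a circle of radius half the wheelbase — smaller than any sensible capture
  radius — so "turn until the choice point is passed" would never terminate.
  Instead the recorder also stores the signed bend of the trained route at
  the choice point, and replay turns until the heading has rotated by that
  bend (within `turn_align_tol`, 15°).
* **Positional replay.** Commands are consumed at successive junction
  *encounters*, not at specific landmark identities. This is what makes a
  route trained from alley 1 reproduce the same turn sequence when replayed
  from alley 5 — and, by the maze's rotational symmetry, deliver the agent to
  alley 1.

# Motor stage

Movement-cell activity maps to wheel velocities: the forward drive feeds both
wheels, each turn band feeds its own-side wheel, and the raw pair is divided
by twice its maximum so the larger component is exactly 0.5 (the agent cannot
reverse). The printed form of this mapping pairs the turn bands with the
*opposite* wheels; under this package's counter-clockwise-positive egocentric
angles that pairing steers the agent away from cues, so the own-side pairing
— which is the same steering law expressed in this convention — is used, and
the closed-loop convergence onto cues is asserted by tests.

Kinematics: heading changes by
$(v_R - v_L)\,\texttt{speed\_scale}/\texttt{wheelbase}$ (radians,
counter-clockwise positive; left wheel faster = clockwise turn), translation
is the mean wheel velocity times `speed_scale` along the new heading. The
pose-update law and its constants are package choices (absent from the
architecture): `speed_scale` 0.2, `wheelbase` 0.3, `body_radius` 0.15 length
units, giving 0.1 length units per step at full drive and ~19°/step at full
turn — timescales that put the first star-maze junction near step 50.
Collisions resolve by pushing the agent centre out of any penetrated wall
along the wall normal, which yields sliding rather than stopping; corridor
worlds depend on this wall-following.

Sliding has a pathological fixed point: when the goal direction is almost
exactly anti-normal to a wall, the tangential component vanishes and greedy
steering pins the agent there indefinitely (sensor jitter even keeps the
"approaching" bonus firing). An obstacle-avoidance reflex breaks it: when
nearly all commanded motion is absorbed by a wall (`wall_turn`, default
15°/blocked step), the heading rotates toward the nearer wall tangent until
motion resumes. The reflex serves the goal-directed strategies only —
ballistic route replay is supposed to stay pressed at a dead end, that is
its terminal behaviour — and it is disabled in the vista world, where
escaping pockets is the confidence system's job (stuck events leading to
route replanning), not a kinematic one.

# Environments and experiments

**Blinking-light arena.** A circular wall (radius 10) with 32 boundary
lights, exactly one active; on capture (radius 0.5) a different light is
drawn uniformly. Map and arbitration are off; the agent runs the egocentric
strategy on the single active cue. Selected conjunctive cells are recorded
every step *at the sensed pose* (recording the post-move pose would shift the
apparent head-direction tuning by one step's turn). Tuning surfaces are
binned at 10° with bin centres on the whole decades, so the estimator can
express the true preferred pair exactly; coverage of the (heading, cue
angle) plane comes from the cue switches, so surface tests use runs long
enough for several hundred switches.

**Star maze.** A regular-pentagon ring corridor (circumradius 5, width 1)
with five radial arms (length 5) at the vertices; alleys numbered clockwise,
arms odd. Landmarks at the five junctions and five arm ends; four distal
cues. In a regular pentagon the intermediate junction of the trained
1 → 7 route is a genuine ~72° bend at which the radial arm (54° off) is the
*straighter* continuation, so the supervised recorder stores three turn
commands, not two; wall-sliding alone cannot carry the agent around that
bend. Probe trials start at the end of alley 5 with the first strategy drawn
25/75 (allocentric / sequential egocentric); thereafter the confidence
softmax arbitrates between the two. The alley-7 goal terminates a trial
immediately; the alley-1 end holds no goal, so the trial is scored there
only after the agent has dwelt 50 steps *while still committed to the route
strategy* — an agent that abandons the replay at the empty dead end is
re-orienting, not finishing, and gets the chance to leave. This dwell window
is exactly where late strategy switches turn an egocentric run into a
"mixed" one, mirroring how a navigator pauses at an empty dead end before
turning back. Successful
execution of a stored turn counts as route progress (+0.25), which produces
the junction-locked confidence rebounds the behaviour needs. Classification
is purely trajectory-based: terminal at alley 1 = egocentric; terminal at
the goal without an alley-1 visit = allocentric; alley-1 visit then goal =
mixed; otherwise timeout (reported separately).

**Vista world.** Eight 10×10 regions on a 3×3 grid with the centre absent,
joined by 1.5-wide doors centred on the shared walls; region numbering
{1,2,3,4,5,6,7,9} preserves the narrated facts (start region 4 bottom-left;
region 5 has only east/west doors and traps direct northward travel; region
3 connects northward; the label 8 is skipped, mirroring an inconsistency in
the source's region naming). Region centroids are the route landmarks; goal
cues are placed at seeded random positions, one drawn per trial. All three
strategies arbitrate; stuck handling is on. The cue-following route targets
the *next* region's centroid directly (its own centroid is where it already
is, place-cell-wise) and lets the walls channel it through the door; on
(re)activation the route is replanned from the current place cell, which is
what carries the agent out of trap regions and around blocked corridors.

# Problem sizes and determinism

The shipped experiments use the study sizes: 130 star-maze probe trials
(budget 2000 steps each; typical trials run 170–600), 80 vista trials
(budget 5000; typical 250–1300), and blinking-light runs of 5000 steps
(tuning-surface analyses use 60000 steps, ≈ 400+ cue switches). Each trial
derives a child seed from the master seed and trial index, so any trial is
reproducible in isolation and a fixed (config, seed) pair reproduces an
experiment bit-identically.

# What the simulations do and do not show

The generator-built worlds are idealised: exact geometry, noiseless
proprioception (heading is read from the pose), cues sensed with a simple
$D/d$ attenuation and 360° field of view, and maps given rather than
learned. Passing tests therefore demonstrate the internal consistency of the
model — frame transformations, arbitration dynamics, route replay, the
reported strategy distributions — not robustness to sensory noise, mapping
error, or real-robot kinematics. Known limitations: no learning or SLAM, no
spiking neurons, no reverse gear, no turning overshoot, and the confidence
system's biological substrate is left open.
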