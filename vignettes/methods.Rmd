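---
title: "Model and methods: reinforcement-learning Schelling dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: reinforcement-learning Schelling dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Two populations of agents, A and B, live on a square lattice with periodic
boundaries (type A is encoded `-1`, B `+1`, empty cells `0`). Each agent
observes an $n \times n$ window centred on itself, with $n = 2r + 1$ and a
default radius $r = 5$, normalised by its own type so that same-kind
neighbours read $+1$ and different-kind neighbours $-1$; alongside the
window it perceives its remaining lifetime divided by the maximum initial
lifespan. At every iteration all agents act once, in a fresh uniformly
random order, choosing among five actions: stay, left, right, up, down.

Moving onto an empty cell relocates the agent; moving onto a same-kind
agent is blocked; moving onto a different-kind agent resolves a hostile
interaction in which the mover wins the cell and one extra iteration of
lifespan while the occupant dies and is reborn elsewhere. Agents also die
when their lifetime (at least 100 iterations at birth) runs out, and every
death triggers an immediate rebirth of a same-type newborn at a random
empty cell, so per-type populations are exactly conserved.

The per-step reward is the plain sum of six components:

$$R = SR + IR + VR + DR + OR + TR$$

with the segregation reward $SR = s - \alpha d$ computed from the same-kind
($s$) and different-kind ($d$) counts in the post-action window, the
interdependence reward $IR \in [0, 100]$ paid to interaction winners, a
vigilance reward $VR = 0.1$ per surviving step, a death penalty $DR = -1$,
an occlusion penalty $OR = -1$ for bumping into a same-kind agent, and a
stillness penalty $TR = -1$ for staying put. The intolerance weight
$\alpha \in [0, 1]$ plays the role of the classical Schelling tolerance
threshold; $IR$ works against it by making cross-type contact profitable.

Each type learns its own Deep Q-Network: with the centre cell pinned to
$+1$, a window of radius 5 still has $3^{120} \approx 1.8 \times 10^{57}$
spatial states, far beyond tabular methods. Both networks start from the
same parameter draw, act $\varepsilon$-greedily with an exponentially
decaying exploration rate counted per type, store transitions in per-type
replay buffers, and are trained with double Q-learning targets, the Adam
optimiser and soft target-network updates ($\tau = 0.05$).

## Network architecture and numerical choices

The Q-network body applies $r$ valid $3\times3$ convolution steps (five at
the default radius) with rectifier nonlinearities and no pooling; each step
shrinks the window by two cells, so the $11 \times 11$ input collapses to a
single spatial cell. Default channel widths are 16, 32, 32, 64, 64. The
normalised remaining lifetime joins *after* the convolutional body: the
final channel vector is concatenated with the age scalar and mapped by one
fully connected layer to the five action values. Design notes:

* **Loss.** The temporal-difference error is passed through a Huber loss.
  With interaction rewards up to 100 a squared loss would let single
  transitions dominate a batch; the Huber gradient is bounded at 1.
* **Optimiser.** Adam with learning rate $10^{-3}$, first-moment decay 0.9
  and second-moment decay 0.999. No gradient clipping and no reward
  normalisation are applied.
* **Exploration.** $\varepsilon(k) = 0.999\, e^{-k/k_0}$ over the per-type
  action counter $k$, with $k_0 = 100{,}000$ at full scale, clamped to the
  final rate 0 once below $10^{-3}$. The counter is global per type, not
  per agent.
* **Training cadence.** 60,000 gradient steps per network spread evenly
  over the 5,000-iteration episode (12 per iteration), batches of 256 from
  a capacity-$10^6$ ring buffer, sampled uniformly with replacement;
  training starts once a buffer holds a full batch. The soft target update
  follows every gradient step. There is no environment reset within an
  experiment (one episode).
* **Reward delivery.** A transition is finalised when its agent next acts
  (non-terminal, with the survival reward added at the iteration boundary)
  or when it dies (terminal, with the death penalty added). This hands the
  death signal to the learner even when an agent is eliminated before
  acting in the current iteration; the rare transition that spans a
  boundary then carries both that boundary's vigilance reward and the
  death penalty. Survival and death rewards are otherwise mutually
  exclusive, as are the interaction reward and the death penalty within
  one step.
* **Initial lifetimes.** Initial agents draw their remaining lifetime
  uniformly from $\{1, \dots, 100\}$, which desynchronises death waves;
  newborns always receive the full lifespan. The normalised age passed to
  the network divides by the base lifespan and is *not* clipped at 1, so
  interaction winners can report values above 1.
* **Implementation.** The training step (forward, double-Q target, Huber
  backward, Adam, soft update) exists twice: a pure-R reference whose
  gradients are verified against central finite differences in the test
  suite, and a numerically identical compiled path (RcppArmadillo) used by
  the training loop. The suite asserts agreement between the two to
  near machine precision over chained steps.

## Segregation metric

Segregation is measured by multiscale entropy: windows of sides 6, 12 and
25 slide over the lattice at stride 1 with toroidal wrapping (50 is
divisible by neither 6 nor 12, so wrapping avoids edge-tiling artifacts
and lets every position contribute). For each window containing at least
one agent the two type counts are normalised to probabilities and scored
by base-2 binary entropy, so a balanced window scores 1 and a pure window
0; empty windows are excluded as the entropy of an empty distribution is
undefined. The segregation value is $1 - \langle e \rangle$ where
$\langle e \rangle$ pools *all* windows of *all* scales into one
unweighted mean. (The alternative — averaging per scale first — weights
scales equally when window counts differ; with stride 1 and wrapping every
scale contributes the same number of windows, so the two conventions
coincide here.) Per-iteration series are optionally smoothed by a centred
50-iteration moving mean with partial edge windows.

The analysis statistics over the last part of a run are: per-cell
occupancy heatmaps (mean type indicator over stored snapshots; every
iteration inside the analysis window, every 10th before it), and two
conditional probability matrices built from per-agent records. For the
age-by-segregation matrix each record's window segregation is
$s/(s+d)$ (records without neighbours are excluded and counted), ages are
split into 10 equal-count groups — the model fixes the number of groups,
not their edges, so empirical deciles with ties broken by rank are used —
and segregation into 5 equal bins on $[0,1]$. Counts are normalised per
age group first and then per segregation bin, so rows sum to 1 and group
size imbalance does not masquerade as signal. The action-by-age matrix
applies the same double normalisation to action rows.

## Scaled-down study profile

The full-scale experiment (50×50 lattice, $r=5$, 5,000 iterations, 10
replicates, the full $\alpha \times IR$ grid) reproduces the figure-level
patterns but takes hours per sweep on one core. The package therefore
ships `scaled_experiment_spec()`, a reduced profile used by the test suite
and the acceptance script, chosen once as a coherent miniature of the full
study:

* 25×25 lattice at the same per-type density (0.05, i.e. 31 agents per
  type), 1,000 iterations, 3 replicate seeds per condition, analysis
  window of 250 iterations;
* the model's geometry is deliberately *not* scaled: the field of view
  stays at radius 5 (11×11 window, five convolution steps) and the
  segregation windows stay at 6/12/25. The intolerance–interdependence
  contrast lives in medium-range foe avoidance and mid-scale mixing, and
  shrinking the window or the metric scales with the lattice removes the
  very mechanism under study (with a 7×7 view and 3×3 metric windows,
  pure same-kind attraction saturates the metric identically at
  `alpha = 0` and `alpha = 1`);
* the training cadence preserves the *replay ratio* rather than the raw
  step count: the full-scale setup replays roughly 12 samples per stored
  transition per iteration (12 steps × batch 256 over ~250 transitions),
  so the profile keeps 12 gradient steps per iteration at batch 64 over
  ~62 transitions. Cheaper cadences (4–6 steps) leave the policies
  undertrained and visibly mute the interdependence mechanism. Narrow
  networks (channel widths 4, 4, 4, 8, 8) pay for the cadence; replay
  capacity is 20,000 and the exploration decay constant 10,000 actions —
  the same fraction of the total action budget (~62,000 actions) that
  100,000 is of the full-scale budget, so the exploration-to-greedy arc
  is preserved.

What the scaled runs do show: the oldest age decile consistently sits in
more segregated windows than the youngest (every run of every
configuration tried); intolerance ($\alpha = 1$ vs $\alpha = 0$) raises
final segregation in the paired mean over common seeds; and a maximal
interdependence reward ($IR = 100$) can collapse segregation far below
the $IR = 0$ level. What they do not show: absolute segregation levels
of the full-scale system; a per-seed uniform $\alpha$ ordering (the
contrast, ~0.02, sits below the seed-to-seed spread, ~0.05, at this
lattice size); or a monotone $IR$ gradient — at $IR = 50$ agents learn
to hunt nearby foes, and each kill locally *purges* the window of the
other type (the victim respawns far away), which raises measured
segregation, while the $IR = 100$ mixing outcome is bistable across
seeds. Recovering the full-scale figure-level patterns — graded
segregation in $\alpha$ and a smooth decrease in $IR$ — needs the 50×50
lattice, the 5,000-iteration horizon and the full network and batch
sizes.

## Fixtures and what passing tests mean

The metric stack is validated without any training: deterministic
fixtures (a half-and-half split lattice as the segregated extreme, a
checkerboard as the mixed extreme) and scripted policies (always-stay,
seeded uniform-random, approach-nearest-foe and flee-foes under wrapped
Chebyshev distance) drive the environment, and every statistic is checked
against brute-force enumeration oracles. The learner is anchored by a
closed-form fixed point: in a one-state world with constant reward 0.1
and $\gamma = 0.98$ the Q-value must converge to $0.1/0.02 = 5$. These
tests establish correctness of the machinery; the scaled experiments
establish the emergent orderings under stochastic training, which is why
they are asserted as paired orderings over fixed seeds rather than as
point values.

## Known limitations

* Rebirth preserves the type of the deceased; the model never changes
  population ratios, so demographic drift is out of scope by design.
* The hostile interaction is the only cross-type interaction; there is no
  cooperative channel, and the winner is always the mover.
* Exploration decays per type, not per agent; individual agents born late
  in a run never experience a high-exploration phase of their own.
* The compiled and R training paths are kept in lockstep by tests, but
  only the compiled path is exercised at experiment scale.
* Scaled-run conclusions are ordinal, not metric (see above).
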