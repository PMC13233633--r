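---
title: "Inhibition-stabilized attractor networks as finite-state machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibition-stabilized attractor networks as finite-state machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isnet)
```

## The model

An inhibition-stabilized network (ISN) is built from $N$ canonical
excitatory-inhibitory pairs of threshold-linear rate units (inhibition-
stabilized pairs, ISPs). With $\mathbf r$ the length-$2N$ vector of unit
rates, $\mathbf W$ the signed $2N \times 2N$ weight matrix, $\boldsymbol
\theta$ the activation thresholds and $I_\alpha(t)$ the current of stimulus
$\alpha$ delivered through its weight vector $\boldsymbol\omega_\alpha$,

$$\tau\,\dot{\mathbf r} = -\mathbf r + \mathbf W \mathbf r -
\boldsymbol\theta + \sum_\alpha \boldsymbol\omega_\alpha\, I_\alpha(t),
\qquad \mathbf r \ge 0,$$

where a unit sitting at zero rate whose right-hand side is negative does
not decrease (projected, "clamped" dynamics). The rate time constant is
$\tau = 10$ ms throughout.

Units are stored interleaved (E1, I1, E2, I2, ...), which keeps every
within-pair $2\times 2$ block on the diagonal of $\mathbf W$. Within-pair
weights are strong and identical across pairs; between-pair connections are
weak and random, and all weights obey Dale's law: all outgoing weights of
an excitatory unit are non-negative, of an inhibitory unit non-positive.

For a single pair with weights $W_{EE}, W_{IE}, W_{EI}, W_{II}$ and
thresholds $\theta_E < \theta_I$, the non-zero (UP) fixed point and the
Jacobian trace and determinant at that point are available in closed form;
`upFixedPoint()` evaluates them and classifies the point as a stable node,
stable spiral, saddle or unstable point from $\mathrm{Tr}$ and $\Delta$
(`stable` requires $\mathrm{Tr}<0$, $\Delta>0$; `spiral` requires
$\mathrm{Tr}^2 < 4\Delta$). The origin (DOWN state) is stable whenever both
thresholds are strictly positive, so a pair is bistable when additionally
the inhibitory nullcline gain $W_{EI}/(1-W_{II})$ exceeds the excitatory
nullcline gain $(W_{EE}-1)/(-W_{IE})$ and the UP point is stable with
positive rates (`bistabilityCheck()`).

## Integration scheme

`simulateISN()` integrates the clamped system with classic fourth-order
Runge-Kutta at a default step of $10\,\mu$s. The threshold nonlinearity is
enforced after every full step *and* on the intermediate stage states;
whether intermediate stages should be clamped is genuinely open, so both
modes are provided (`clamp_stages`), with stage clamping the default
because it prevents evaluation of the vector field at unphysical negative
rates. In clamp-inactive regions the integrator shows clean fourth-order
convergence against the closed-form linear solution (verified in the test
suite), and the stimulus pulse is on for $t \in [t_0, t_0 + \tau_{dur})$ —
onset-inclusive, offset-exclusive, i.e. $H(0)=1$ — so a pulse lasts exactly
its nominal duration on the integration grid.

Settling runs (`settleNetwork()`) use a coarser step, $10^{-4}$ s, because
equilibration periods are 12 s long and the settled states are
subsequently *refined to machine precision*: on the interior of a clamping
region the dynamics are linear, so once the active set is known the exact
fixed point solves $(\mathbb I - \mathbf W_{AA})\,\mathbf r_A =
-\boldsymbol\theta_A$ (`exactFixedPoint()`). Every catalogued attractor is
verified stationary through the clamped derivative, which makes the coarse
settling step safe: the step only has to deliver the trajectory into the
right neighbourhood, not resolve the fixed point itself. The headline
settling result (the 5 Hz excitatory UP rate of the solved fiducial pair)
is additionally checked at $10^{-5}$ and $2\times10^{-5}$ s in the
acceptance tests to guard against step-size sensitivity.

## Convergence criteria

A 12 s equilibration counts as converged if either

1. **proximity** — every unit stays within 0.5 Hz of the final state for
   the last 0.5 s (checked on a sliding window so most runs exit early), or
2. **decay envelope** — near-undamped spirals (small $|\mathrm{Tr}|$, large
   $\Delta$) oscillate beyond any practical equilibration time; linearity
   near the fixed point means a consistently shrinking oscillation is
   sufficient evidence of convergence. The exact wording of "consistently
   decay" is an open choice; we measure the maximum distance to the
   candidate fixed point (the exact linear fixed point of the current
   active set) in each quarter of the final 2 s window and require the four
   quarter-maxima to decrease strictly. A peak-by-peak test proved brittle:
   with the max-norm distance, a rotating trajectory generates several
   sub-peaks per revolution whose sampled heights are not monotone even
   when the envelope is. The settled state is then *extrapolated* to the
   candidate point.

Runs meeting neither criterion are reported as non-converged, never
silently classified.

## The inverse solver

`solveISPFromSpec()` designs a pair from a target $(\mathrm{Tr}, \Delta)$,
the two thresholds, and the UP rates $(r_E^*, r_I^*)$. Substituting the two
fixed-point constraints into the determinant equation cancels all quadratic
terms, leaving a single linear equation in $W_{EE}-1$; the solver is
therefore a closed-form solve rather than an iterative root search, and the
round-trip residual (rates, trace, determinant) is checked against
$10^{-9}$. Solutions violating Dale signs are refused, never silently
returned. Trace and determinant are accepted in physical units
($s^{-1}$, $s^{-2}$) or dimensionless ($\tau\,\mathrm{Tr}$,
$\tau^2\Delta$) with an explicit flag.

The fiducial pair used throughout the package fixes $\theta_E = 5.34$,
$\theta_I = 82.43$, $r_E^* = 5$ Hz, $r_I^* = 10$ Hz, $\mathrm{Tr} = -50$
s$^{-1}$, $\Delta = 1.5\times10^4$ s$^{-2}$ — a bistable, inhibition-
stabilized stable spiral.

## State-dependence and tolerance

A stimulus is *state-dependent* for a bistable pair when the same pulse
drives DOWN$\to$UP from the origin and UP$\to$DOWN from the UP state
(`stateDependenceTest()`). `stimulusSweep()` maps this over an
(amplitude, duration) grid; the default grids are $40\times40$,
log-spaced over a 100-fold amplitude range and a 1000-fold duration range.
The fraction $f_{sd}$ of state-dependent cells converts to the
scale-invariant **tolerance**

$$\mathrm{tolerance} = 10^{\sqrt{\tfrac{4 f_{sd}}{\pi}\,
\log_{10}\tfrac{\max I}{\min I}\,
\log_{10}\tfrac{\max \tau_{dur}}{\min \tau_{dur}}}} - 1,$$

the fold-range (minus one) of a circle, on log axes, with the same area as
the state-dependent region; a circular region of log-diameter 1 on ten-fold
axes gives exactly 9. Sweeps of solved pairs across the
$(\mathrm{Tr},\Delta)$ plane show positive tolerance only in the spiral
regime $\mathrm{Tr}^2 < 4\Delta$: the transient rotation around the UP
point is what lets an excitatory pulse terminate inside the DOWN basin.
On linear duration grids the state-dependent mask is near-periodic with
period $\approx 2\pi/\omega$, $\omega = \sqrt{4\Delta - \mathrm{Tr}^2}/2$,
the spiral's rotation frequency — both properties are asserted in the
tests.

## Random network construction

`assembleISN()` samples the four between-pair connection classes (E→E,
E→I, I→E, I→I) row by row. Class target means and sds are scaled by $1/N$
so total input per unit is independent of network size, and each row is
resampled until its sample mean is within 5% and its sample sd within 10%
of target, so every unit receives near-identical class-wise input
(homeostatic normalization). Magnitude families: log-normal (parameterized
by desired arithmetic mean and sd, converted internally to the underlying
normal), gamma (mean and CV, convenient for enforcing Dale's law at high
variability), and homogeneous. With only $N-1$ entries per class-row the
moment acceptance becomes infeasible for very skewed draws; gamma CVs up
to about 2 are practical at $N=5$ with the default resampling cap, which
bounds the heterogeneity range studied below.

There is no canonical value for the cross-connection magnitudes, so the
default class means are set to $\beta/10$ times the matching within-pair
weight magnitude ($\beta = 1$ by default): summed cross input per class is then roughly a tenth of the
within-pair input, comfortably inside the within-pair-dominated regime
(`couplingDominance()` reports ~11 for the fiducial configuration). The
default log-normal CV of 0.5 is a moderate heterogeneity — strong enough
to break permutation symmetry, weak enough to preserve most of the $2^N$
capacity. Consequently the exponential-growth checks of state counts
assert the qualitative trend (growth factor $b > 1$), not particular
coefficients, which depend on the chosen magnitudes.

Cue identities for the task are length-$2N$ weight vectors drawn from a
standard log-normal and rescaled to unit mean (`makeCueVector()`).

## Attractor enumeration

`enumerateAttractors()` seeds $3\cdot 2^N$ relaxations: every UP/DOWN
pattern, each at three initial-rate guesses for the UP pairs — the
isolated-pair UP rates scaled by 0.5, 1 and 2 — bracketing the attractor
from below and above. States are unique up to signature (a pair is
UP when its excitatory rate exceeds 0.5 Hz, matching the convergence
tolerance) plus a 0.5 Hz max-norm rate check, so distinct rate patterns
with identical signatures — possible in heterogeneous networks — are
counted separately. For homogeneous networks the symmetry-reduced method
relaxes one representative per UP-count $k$ ($3(N{+}1)$ relaxations) and
adds $\binom{N}{k}$ states per stable $k$; it agrees with the exhaustive
count wherever both run.

## Itinerancy and the state machine

`transitionGraph()` applies one uniform pulse from every attractor and
maps each to its post-stimulus attractor. The longest itinerant path `L`
walks this functional map from every start until a state repeats, counting
transitions taken; a terminal self-loop edge is not counted, but an edge
closing onto a previously visited *different* state is. Under this
convention the homogeneous worked example ($n$-UP $\to (N{-}n)$-UP $\to$
all-UP $\to$ all-DOWN $\to$ all-UP) scores exactly 4, and homogeneous
networks can never exceed 4 — in a symmetric network every UP pair receives
identical input, so a stimulus that silences one silences all, and the
only reachable states from a generic pattern are itself, its complement,
all-UP and all-DOWN. `homogeneousItinerancySweep()` exploits exactly this
argument to sweep $O(N)$ class-level transitions per grid cell instead of
$O(2^N)$, and the class-level walk is tested against the explicit graph.
Heterogeneous networks break the symmetry and exceed the bound (the
packaged 5-pair example reaches $L = 6$).

`extractFSM()` treats the network as a deterministic finite-state machine:
states are the reachable attractors, the initial state is the quiescent
all-DOWN state (always stable here since thresholds are positive), the
alphabet is a pair of cue vectors, and the transition function is
discovered by breadth-first search in which traversing an edge means
simulating the pulse plus a full equilibration. Each (state, cue) edge is
simulated once and cached; the BFS core is factored so a lookup-table
"dynamical system" can drive it in tests. The inter-cue interval in task
sequences is configurable and defaults to the equilibration period — the
conservative choice that lets every transition complete before the next
cue arrives.

## Task scoring

The six-cue left/right task enumerates all $2^6 = 64$ sequences; 22 are
left-majority, 22 right-majority, 20 are 3-3 ties. **Reliability** groups
the non-tie sequences by final state and scores
$\sum_i \max(|S_i \cap L|, |S_i \cap R|) / (|L| + |R|)$ — equivalently,
the per-state majority output labeling, which an exhaustive search over
all labelings confirms optimal. Ties are traced through the machine but
excluded from reliability and from primacy/recency, whose numerators and
denominators also exclude sequences whose final state is labeled `none`;
ties do appear in psychometric curves at $k = 3$, and `none` decisions
contribute half a left-decision there (and are reported separately).
A one-state machine scores 0.50, any single-cue-position rule scores
exactly $8/11 \approx 0.73$ (the history-free baseline, verified for all
six positions and both polarities), and a signed-difference counter scores
1.00. Exhaustive search over all deterministic two-symbol machines finds
no perfect machine with three states and a perfect one with four.

Psychometric curves report $P(\text{left} \mid k \text{ left cues})$. The
logistic-versus-linear comparison fits a logistic regression and a linear
probability model to the binary decisions and compares their *binomial*
log-likelihoods (the linear fit's fitted probabilities are clipped into
$(0,1)$); with equal parameter counts the log-likelihood difference is the
natural comparison statistic.

## Study conditions chosen for the qualitative experiments

Two experiments need conditions that are genuinely open choices.

**Heterogeneity.** The gamma-family CV sweep uses levels 0, 1 and 2 with
networks of 5 pairs at fixed class means: CV 0 is the homogeneous limit,
CV 2 approaches the feasibility limit of the row-moment resampling at
$N=5$ (see above). Under these conditions the state count falls with CV
while the mean longest path peaks at the intermediate level — the
inverted-U asserted (as a seed-averaged ordering only) in the acceptance
tests. The test uses 6 matrices per level and a $5\times2$ stimulus grid
to keep the suite fast; `heterogeneityExperiment()` defaults to 10
matrices per level.

**Primacy/recency.** Congruence of the decision with the first/last cue is
averaged over networks at weak versus strong amplitudes. The mechanism —
weak stimuli strand the network in early basins (primacy), strong stimuli
let the final cue dictate the final state (recency) — requires a stimulus
range spanning "can activate but rarely silence" through "silences and
re-activates freely". For the fiducial fast spiral, UP$\to$DOWN is
achievable at virtually every amplitude, so recency dominates everywhere;
the experiment therefore uses a more strongly damped spiral
($\mathrm{Tr} = -100$ s$^{-1}$, $\Delta = 10^4$ s$^{-2}$, same thresholds
and UP rates), whose single-pair response map has an activate-only band at
low amplitudes and a silence-dominated band at high ones. Amplitudes
$\{8, 11\}$ (weak) versus $\{42, 60, 85\}$ (strong) at 5 and 10 ms
durations, over ten network/cue seeds, give the asserted ordering: higher
primacy at weak, higher recency at strong amplitudes. This is a
directional, seed-averaged claim; per-network outcomes vary. Note that
very strong stimuli are excluded by the physics rather than by choice: far
above the effective range a uniform-ish pulse drives the inhibitory units
so hard that every state collapses to all-DOWN and no decisions exist.

## Packaged examples

`makeReferenceFixtures()` regenerates the packaged example objects: (a) a
state-dependent fiducial pair (it responds bidirectionally to the
reference pulse $I_{app} = 52.15$, 1 ms), (b) a heterogeneous 5-pair
network with $L \ge 5$ itinerancy, and optionally (c) a task network, cue
pair and stimulus implementing a reliability-1.0 machine on the six-cue
task. All are found by scanning fixed candidate lists under fixed
seeds, so regeneration is bit-identical. These are synthetic objects
constructed by the package itself.

## What the synthetic data do and do not emulate

Everything in this package is simulation: the generators produce
connectivity statistics, cue vectors and stimulus protocols for a
modeling study — not recordings. Passing tests therefore demonstrate
internal consistency of the dynamics, enumeration and scoring machinery
under the stated conditions (deterministic dynamics, no noise, exact
rectangular pulses, all-to-all coupling, identical within-pair weights).
They do not show robustness to biological noise, spiking discreteness,
synaptic dynamics, sparse or topographic connectivity, or learning — all
outside scope. Non-deterministic (noisy) machines, plasticity, and
spiking equivalents are likewise out of scope.

## Problem sizes

The test suite settles networks of up to 9 pairs (symmetry-reduced) and 5
pairs (exhaustive), sweeps $20\times20$ homogeneous itinerancy grids, and
runs the heterogeneity and primacy/recency experiments at the sizes listed
above; the full suite and the acceptance script each complete in a few
minutes on one core. Larger grids and more matrices per level only refine
the same statistics; the functions scale to them directly.

## Known limitations

* The decay-envelope criterion extrapolates to the *linear* fixed point of
  the current active set; a trajectory whose active set at the window tail
  differs from that of its eventual attractor would be misclassified
  (not observed under the packaged configurations, where the criterion is
  exercised only near weakly damped UP states).
* Symmetry-reduced enumeration assumes exact homogeneity; it refuses
  heterogeneous networks rather than approximate them.
* The moment-matched row resampling cannot reach very high CVs at small
  $N$; the resampling cap raises an explicit error rather than silently
  relaxing the tolerances.
* Reported reliabilities for simulated networks depend on the chosen
  cross-connection magnitudes. With this package's defaults,
  perfect (reliability 1.0) machines exist but are rare in the space of
  random cue pairs and stimuli — the packaged example was found by seeded
  search, and it uses 12 reachable states rather than the minimal 4 (the
  minimal perfect 4-state machine exists abstractly and is found by the
  exhaustive machine search).
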