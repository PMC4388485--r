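---
title: "Embodied decision models: coupling a drift-diffusion accumulator to action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied decision models: coupling a drift-diffusion accumulator to action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftact)
```

## The modelling problem

In most laboratory accounts of two-alternative forced choice (2AFC), a
decision variable $z(t)$ accumulates noisy sensory evidence until it hits one
of two symmetric bounds $\pm b$, and the motor response is treated as a mere
readout. Mouse- and reach-tracking experiments complicate that picture: the
hand starts moving long before the evidence is conclusive, trajectories curve
toward the unchosen option, and movements are sometimes revised mid-flight.
`driftact` simulates a family of architectures that couple the same
discrete-time accumulator to a simple two-dimensional action system, so that
the joint dynamics of deciding and moving can be studied quantitatively.

The accumulator is the standard discrete drift-diffusion update
$$ z(t + \Delta t) = z(t) + \Delta z, \qquad \Delta z \sim
\mathcal{N}(\mu, \sigma^2), $$
with unbiased start $z(0) = 0$. Defaults are $\mu = 1/3$, $\sigma = 1$ and
$\Delta t = 50$ ms, with positive drift toward target 1; crossing is
inclusive ($z \ge b$), so zero-noise configurations terminate at exact
multiples of $\Delta t$. Note that the increments are per *step*, not scaled
by $\sqrt{\Delta t}$: the model is a discrete random walk, and because the
increment standard deviation is comparable to the bound for small $b$,
first-passage overshoot matters — closed-form error rates of the continuous
diffusion limit do **not** apply (the package's tests validate first-passage
behaviour against a brute-force simulation instead).

The action unfolds in a planar arena: start at $(0, 0)$, targets at
$(\mp 1, 1.5)$, constant speed $v = 2$ units/s. The straight-line travel
time to either target is $\sqrt{3.25}/2 \approx 0.9014$ s, the hard floor on
any response that requires movement. The decision state steers the movement
through an *action focus* — a point on the segment joining the targets that
the agent approaches at constant speed:
$$ (\Delta x, \Delta y) = v\,\Delta t\,
\frac{(x,y)_{\text{focus}} - (x,y)}{|(x,y)_{\text{focus}} - (x,y)|}. $$

## The five architectures

* **`baseline`** — no action system: the trial ends the moment $z$ crosses a
  bound. The best attainable speed-accuracy frontier for a given stimulus.
* **`m1` (serial)** — the agent is immobile until the first crossing, then
  moves in a straight line to the chosen target. Its response-time
  distribution is exactly the baseline's shifted by $\sqrt{3.25}/2$ s, a
  property the test suite asserts at paired seeds.
* **`m2` (changes of mind)** — movement starts at the first crossing, but
  the accumulator keeps running; whenever the *opposing* bound is crossed
  the focus switches to the other target, producing kinked trajectories.
  Between the bounds the focus (once defined) holds its last value, so the
  agent keeps moving toward the last-instructed target. The final choice is
  the target actually reached, not the last bound crossed.
* **`m3` (action preparation)** — the focus is always defined:
  $$ (x,y)_{\text{focus}} = \frac{(b + z)\,T_1 + (b - z)\,T_2}{2b},
  \qquad -b \le z \le b, $$
  clamped to $T_1$ for $z \ge b$ and $T_2$ for $z \le -b$. Movement starts
  at $t = 0$ from the midline and the choice follows from action completion:
  the trial ends when the agent reaches a target, which requires the
  (effective) evidence to be at or beyond a bound.
* **`m4` (preparation + commitment)** — as `m3`, but the agent's position
  feeds back into an effective evidence
  $$ z_{\text{com}} = z + g\,\frac{d_2 - d_1}{d_1 + d_2}, $$
  where $d_{1,2}$ are the distances to the targets and $g = 4b$ by default.
  Proximity to a target adds effective evidence for it, making an ongoing
  approach progressively harder to revise. The raw accumulator is never
  modified — the combination is recomputed each step, so the decision state
  remains recoverable from the evidence stream alone.

Two orientation choices deserve a note, since the interpolation weights and
the sign of the commitment term can each be written two ways. We fix the
convention *upper bound ⇔ target 1* throughout and require (i) the
interpolated focus to be continuous with its clamp at both bounds, and
(ii) commitment to favour the *nearer* target (it would otherwise be an
anti-commitment term that destabilises an ongoing approach). Both
requirements pin the formulas to the forms above.

### Event order within a step

A simulation interval $(t, t + \Delta t]$ uses the evidence available at its
start: the focus is computed from $z(t)$ (and the position at $t$ for
`m4`), the agent moves for $\Delta t$ toward it, and the interval's
increment lands at $t + \Delta t$. Decision-dependent movement therefore
begins on the step after the bound crossing — with zero noise and $b = 1$,
the serial model decides at exactly $t_{\text{dec}} = 0.15$ s and responds
at $0.15 + \sqrt{3.25}/2 \approx 1.051$ s. Arrival is detected when the
focus coincides with a target and lies within one step; the terminal step
is shortened and contributes `distance/v` to the response time, so travel
time is exact rather than quantised to whole steps. Two floating-point
details are handled deliberately: the interpolated focus is parameterised
as $T_2 + w\,(T_1 - T_2)$ so it sits exactly on the target line, and each
movement coordinate is clamped between its old value and the focus
coordinate, so $y$ is non-decreasing to the last bit — a property the
trajectory metrics rely on.

## Reproducibility model

`run_batch()` gives trial $i$ its own seed substream, a pure function of
`(master_seed, i)`; batches are therefore identical regardless of splitting
or execution order, and emitted CSV artifacts are byte-reproducible from
their JSON manifest. The inner loop is compiled (Rcpp) but consumes R's own
RNG, so a single-trial run with `set.seed()` is reproducible from the R
side, and the scalar R implementation of the baseline trial
(`run_baseline_trial()`) agrees with the compiled engine draw-for-draw.

## Trajectory analytics

All metrics integrate over $y$, the axis from the start to the target line,
exploiting that $y$ never decreases along simulated trajectories:

* `trajectory_area()` — $\int |x(y) - x_{\text{chosen}}|\,dy$, the area
  between the path and the vertical line through the chosen target. A
  straight serial-model path gives exactly $0.75$.
* `auc_curvature()` — the area between the path and its endpoint chord, the
  mouse-tracking "area under the curve".
* `mean_trajectory()` — the per-height average $\bar{x}(y)$ over a common
  grid (101 points by default), i.e. averaging *parallel to the x-axis*;
  trajectories are not time-normalised. Duplicate heights within a
  trajectory (the stationary pre-decision phase at $y = 0$, the terminal
  slide along the target line at $y = 1.5$) are collapsed to the last
  sample at that height so $x(y)$ is single-valued.
* `angle_from_vertical()` — the least-squares slope $dx/dy$ over the first
  or last fraction (default 10%) of the height range of a mean trajectory,
  reported as degrees from vertical.

Two estimator caveats matter when comparing architectures. First,
per-trajectory areas are averaged (not the area of the mean trajectory).
Second, the *final* angle of architectures that approach the target along
the $y = 1.5$ line (`m3` especially) is concentrated in a terminal boundary
layer much thinner than 10% of the height range: the y-parameterised mean
trajectory jumps to the target x-coordinate over the last grid interval, so
the 10% window mixes the horizontal approach with the smooth interior and
reads tens of degrees below a tangent-based estimate (a 2% window reads
$\sim 84^\circ$ where the 10% window reads $\sim 70^\circ$ for `m3`). We
keep a single fixed window for all models and both segments rather than
adapting it per architecture; the window is a parameter (`fraction`) for
users who want the terminal tangent.

## Calibration and sweeps

`sweep_boundaries()` traces a model's speed-accuracy frontier over a grid of
bounds (31 geometrically spaced values on $[0.01, 10]$ by default —
geometric because the range spans three decades), $10^4$ trials per point
by default with $10^5$ available where higher fidelity is wanted.
`calibrate_boundary()` finds the bound giving a target mean response time:
it evaluates a coarse geometric grid under common random numbers, brackets
the target, and bisects. Mean RT is not monotone in $b$ for the commitment
model (the gain $g = 4b$ accelerates arrivals faster than the widening
bound delays them, up to $b \approx 4$), so the target can be attained at
two bounds; the calibration deterministically returns the *smallest* such
bound, which coincides with ordinary bisection for the monotone models.

With the defaults this yields $b \approx 3.8$ for `m1`/`m2` and
$b \approx 8$ for `m3` at a 1.5 s target, and $b \approx 0.75$–$1.2$ for
`m4` at a 1.0 s target.

## What the simulations show — and known gaps

The deterministic layers are exact (travel time, serial-model area $0.75$
and angle $\arctan(1/1.5) \approx 33.7^\circ$). At calibrated bounds the
preparation model reproduces the published mean area ($\approx 1.28$ vs
$1.25$) and near-vertical initial angle, and the commitment model its area
($\approx 1.0$ vs $1.06$), small initial angle, and $\approx 55^\circ$
diagonal final approach; the strict area ordering
`m1 < m2 < m4 < m3` holds throughout. The frontier structure also
reproduces: the serial frontier is the baseline rigidly shifted, commitment
extends the attainable response times below preparation's, and at matched
mean RT the error ordering is baseline ≤ preparation ≤ changes-of-mind ≤
serial.

Several published magnitudes do *not* reproduce under the stated protocol,
and the package reports its own computed values rather than adjusting
toward them:

* The change-of-mind model at a 1.5 s calibration yields mean area
  $\approx 0.78$ and initial angle $\approx 32^\circ$ (published: $0.91$,
  $21^\circ$). Those published values correspond, in this implementation,
  to $b \approx 0.7$–$1.0$, where the mean RT is only $\approx 1.13$ s: at
  $b \approx 3.8$ a post-decision reversal requires the walk to retrace
  $2b$ within the $\sim 18$ travel steps, which is vanishingly rare. We
  also tested freezing the agent whenever $|z| < b$ and
  diffusion-scaled increments; neither reconciles the calibration with the
  published area.
* The preparation model's minimum mean RT over the default sweep is
  $\approx 1.06$ s, not the published $\approx 1.2$ s floor, and its final
  angle under the 10% window is $\approx 70^\circ$–$74^\circ$, not
  $90^\circ$ (see the estimator caveat above).
* At a fixed calibrated bound, quadrupling the stimulus noise *shortens*
  first passages ($\mathrm{E}[T] \sim b^2/\sigma^2$ when noise dominates)
  and therefore straightens preparation-model trajectories; mean AUC
  decreases rather than increases. Curvature grows with noise only if the
  bound is recalibrated upward to hold the response time fixed.

## What the synthetic batches do and do not emulate

The generator produces per-sample $(t, x, y, z, z_{\text{com}})$ records of
exactly the form a mouse-tracking session yields after normalisation (and
`read_trajectories()` maps external recordings into the same arena by an
affine per-axis transform). It emulates: graded curvature toward the
unchosen option, discrete changes of mind, noise-dependent deviation, and
speed-accuracy trade-offs under bound manipulation. It deliberately does
not emulate: reaction-time non-decision offsets, velocity profiles
(movement is constant-speed), angular-velocity limits (kinks are sharp),
biomechanical costs, trial-to-trial drift variability, or stimulus-direction
randomisation (drift is always toward target 1, so "error" means arrival at
target 2). Passing tests therefore validate the decision–action coupling
logic, not a full account of human reach kinematics.

## Numerical choices and problem sizes

Tolerances: arrival uses the exact shortened step; trajectory endpoints are
checked to $10^{-9}$ arena units; CSV round-trips to $10^{-12}$. Ties:
bound crossing is inclusive; at exactly $z = 0$ the interpolated focus is
the midpoint. Degenerate inputs: $\sigma = 0$ is legal (deterministic
drift); a zero-drift, zero-noise configuration exhausts the step cap
(default $10^6$) and raises an error rather than hanging. Batch sizes used
by the packaged analyses: $10^4$ trials for calibration and sweep points
(with a $10^5$ preset where higher fidelity is wanted), 600 recorded trials
per metrics batch from which the first 150 target-1 finishers are selected,
and three replicate seeds for all stochastic summaries.
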