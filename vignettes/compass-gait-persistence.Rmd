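---
title: "A compass-gait walker with a phase-resetting CPG: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compass-gait walker with a phase-resetting CPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgait)
```

## The scientific question

Healthy human walking is not metronomic: stride intervals fluctuate from one
stride to the next, and those fluctuations are *statistically persistent* —
a long stride tends to be followed by further long strides.  Detrended
fluctuation analysis (DFA) quantifies this with a scaling exponent
$\alpha$: $\alpha = 0.5$ for uncorrelated (white) fluctuations,
$\alpha < 0.5$ for anti-persistence, $0.5 < \alpha \le 1$ for persistence,
and $\alpha > 1$ for brown (integrated white) noise.  Persistence is lost
with aging, Parkinson's and Huntington's disease, and when walking to a
metronome.

`cpgait` implements a minimal neuromechanical model of this phenomenon: a
planar compass-type biped (point masses at the hip and on each leg) driven
by a single phase oscillator — a minimal central pattern generator (CPG) —
whose phase $\phi$ advances at constant rate $\omega$ and produces
feedforward sinusoidal joint torques

$$u_1 = A_1 \cos\phi + \sigma_1, \qquad
  u_2 = A_2 \cos(\phi + \Delta) + \sigma_2,$$

at the stance ankle and the hip respectively, with additive torque noise
$\sigma_i = \xi U_i$.  The single mechanistic switch is what happens to
$\phi$ at foot contact:

* **phase resetting**: $\phi^+ = \phi_0$, a constant — the neural rhythm is
  re-anchored to the mechanical contact event;
* **no resetting** ("flip"): $\phi^+ = \phi^- - \pi$, which merely mirrors
  the torque pattern the way the touchdown collision mirrors the legs, so
  the oscillator keeps its own clock.

Both modes share the *same* noiseless gait by construction ($\phi_0$ is
defined as the phase the flip-mode gait settles into), so any difference
between them under noise isolates the effect of resetting.

## The mechanical model

The walker has legs of length $l = 1$ m joined at a frictionless hip; hip
mass $M = 50$ kg, leg masses $m = 11$ kg at distance $b = 0.4$ m below the
hip, gravity $g = 9.8$ m/s².  During swing the configuration
$(\theta_1, \theta_2)$ — stance angle from vertical and inter-leg angle —
obeys a standard two-link equation of motion
$\mathbf{M}(\theta_2)\ddot q + \mathbf{C}(q,\dot q) + \mathbf{G}(q) = u$.
The swing tip reaches the ground when $2\theta_1 - \theta_2 = 0$; contact
counts as touchdown only in front of the walker ($\theta_1 < 0$) with the
legs closing ($2\dot\theta_1 - \dot\theta_2 < 0$); crossings with opening
legs are the swing leg scuffing the floor on its way forward and are
ignored.  Touchdown is a fully inelastic impact with instantaneous leg-role
exchange: angles negate, and the angular velocities jump by a linear map
that conserves the angular momentum of the whole walker about the new
contact point and of the trailing leg about the hip.  The package
implements the closed-form impact matrices and cross-checks them in the
test suite against an independent conservation-law derivation; the swing
dynamics are likewise cross-checked against a position-level Lagrangian
oracle, and passive trajectories against energy conservation.

A useful structural fact, exploited by the tests: a steady period-1 gait
must re-enter the torque pattern half an oscillator cycle later each step,
so the step period of *every* stable gait is locked to $T = \pi/\omega$
($\approx 0.654$ s at the default $\omega = 4.8$ rad/s; stride
$\tau = 2\pi/\omega \approx 1.309$ s).  Consequently gait speed is set by
step length alone, $v = 2 l \lvert\sin\theta_1^-\rvert / T$, and the torque
cost of one step cycle is analytic,
$\varepsilon = \int (u_1^2 + u_2^2)\,dt = (A_1^2 + A_2^2)\,\pi/(2\omega)$ —
minimizing energy at a given speed means finding the weakest amplitudes
that still walk at that speed.

## Simulation engine

Trials integrate the coupled system with the Euler–Maruyama scheme at a
fixed step of $10^{-5}$ s (compiled C++ core).  Touchdowns are detected as
sign changes of $2\theta_1 - \theta_2$ under the contact conditions and the
event time is refined by bisection within the detection step (toggleable
via `refine`), which removes time-step quantization from stride intervals;
a trial of 1300 steps yields 650 strides (a stride is two consecutive
steps, measured between every other touchdown), of which the first 150 are
discarded as transient and the next 500 analysed.  A trial aborts as a
*fall* when $\lvert\theta_1\rvert > \pi/2$, when
$\lvert\dot\theta_1\rvert > 50$ rad/s, or when no touchdown occurs for 5 s;
falls are data, not errors.  Noise streams are two independent,
platform-deterministic Gaussian generators (splitmix64 + Box–Muller)
derived from the trial seed, so every trial is exactly reproducible from
`(seed, xi)`.

### The noise discretization, and why the default is per-step-cycle noise

"Unit-variance white Gaussian torque noise of amplitude $\xi$" admits more
than one discrete reading, and the choice matters quantitatively.  The
package implements three (`noise_spec(discretization = ...)`):

* `"wiener"` — SDE white noise: each integrator step adds
  $\xi\sqrt{dt}\,N(0,1)$ per torque channel (through the inverse mass
  matrix).  At $\xi = 1$, $v = 0.4$ m/s this yields stride-interval
  standard deviation $\approx 0.045$ s and occasional falls of the
  non-resetting model within 1300 steps.
* `"per_step"` — a unit draw scaled by $dt$; its effective amplitude is
  $\sqrt{dt}$ smaller than `"wiener"` (SD $\sim 10^{-4}$ s at $\xi = 1$),
  far too weak to matter.  Retained for comparison.
* `"cycle_hold"` (default) — $U_i$ drawn once per step cycle and held
  until the next touchdown: a fresh motor-command error per movement, of
  $\xi$ N·m standard deviation.  At $\xi = 1$ this reproduces the
  reference stride-interval variability (SD $\approx 0.031$ s, close to
  the $\approx 0.03$ s reported for this model class and for healthy
  adults) and both reset modes complete 650-stride trials without falling
  for $\xi \le 1$.

Because the per-movement reading reproduces both the fluctuation magnitude
and the robustness of the reference results while the literal SDE reading
overshoots both by about 40–50%, `"cycle_hold"` is the package default.
The qualitative resetting/no-resetting dichotomy below is the same under
all three readings.

## Limit cycles, Floquet multipliers, and the phase response

`find_limit_cycle()` locates the steady gait as a fixed point of the
touchdown return map (forward convergence, then damped Newton with a
finite-difference Jacobian to residual $10^{-10}$).  The post-touchdown
section eliminates $\theta_2$ ($= 2\theta_1$ on the section); the
oscillator phase is a live section coordinate only in flip mode — with
resetting it is pinned to $\phi_0$ immediately after every touchdown and
cannot carry any mode.  This dimensional bookkeeping (3-D resetting vs 4-D
flip section) is the geometric heart of the mechanism.

`floquet_multipliers()` linearizes either the one-step touchdown map
(`map = "step"`, the default) or its two-step composition
(`map = "stride"`) by central differences ($h = 10^{-6}$; results are
stable to $< 10^{-3}$ under $h$-refinement).  At the $v = 0.4$ m/s
reference parameter set the one-step dominant multiplier is $+0.653$ —
real, positive, comfortably inside the unit circle — and the resetting
mode has almost the same dominant mode ($+0.653$); the stride-map
multipliers are the squares of the step-map ones (dominant $0.426$).  The
*step* map is the default because step-to-step recovery is the
conventional stability measure for walking and the value $0.65$ is the
one this model family is characterized by.

`phase_response()` measures the model's signature asymmetry directly: an
impulse applied mid-stride shifts the timing of all subsequent touchdowns
*permanently* when resetting re-anchors the clock to the (shifted) contact
event, with a magnitude that depends on when in the cycle the impulse
lands; without resetting the oscillator keeps absolute time and the shift
decays to zero with the Floquet rate.  Accumulated over a trial's noise,
this makes the resetting model's accumulated stride-interval sum a drifting
random-walk-like signal and the flip model's a tightly bound, rough one —
the dichotomy DFA picks up as $\alpha_{\text{reset}} \gg \alpha_{\text{flip}}$,
with $\alpha_{\text{flip}} \approx 0.06$ deeply anti-persistent.  In this
implementation the resetting model's exponent sits at
$\alpha \approx 0.50$ (10-trial means 0.49–0.52 across noise readings and
amplitudes) rather than clearly above 0.5: each shock's permanent timing
shift is realized almost entirely within the stride it occurs in, so the
interval sequence is nearly white.  A markedly persistent $\alpha$
(e.g. $\approx 0.6$) would require the shift to build up over two to three
strides; the package's tests therefore assert the robust dichotomy and
treat the absolute level of $\alpha_{\text{reset}}$ as the fragile
quantity it is.

## Energy-optimal calibration

`optimize_for_speed()` runs the staged grid search: a coarse pass over
$A_1, A_2 \in [0, 20]$ (step 1) and $\Delta \in [0, 1.6]$ rad (step 0.1),
then two local refinements around the incumbent down to resolution
0.1/0.1/0.01, with the speed-matching tolerance tightening from 0.03 m/s
(coarse) to 0.005 m/s (final).  Candidates are evaluated in flip mode
(the steady gait is mode-independent) from a fixed generic post-touchdown
state, with convergence declared when consecutive step periods agree to
$10^{-7}$ s five times within 200 steps; selected optima are re-verified
with a Floquet check.  Candidate evaluation uses $dt = 10^{-4}$ s — with
event-time bisection the steady-gait observables change by $< 10^{-5}$
between $dt = 10^{-4}$ and $10^{-5}$, and the coarse-plus-refinement
search then completes in minutes on one core.

Two honest caveats from this search, documented rather than hidden.
First, because $\varepsilon \propto A_1^2 + A_2^2$, the global minimizers
in this model sit in a weakly-actuated valley (small $A_2$, larger
$\Delta$) where the swing leg is driven mostly by gravity — these gaits
are genuinely stable here (Floquet magnitudes 0.7–0.95) but clear the
ground by only millimetres.  The reference optima for this model family
($A_2 \gg A_1$, $\Delta \approx 0.4$–0.6) are *not* the unconstrained grid
minima of this implementation, and the calibration targets should be read
with that discrepancy in mind.  Second, the speeds achieved at the
reference sets are 0.32 and 0.48 m/s rather than exactly 0.3 and 0.5;
speed-matching below the reporting resolution ($\pm 0.005$ m/s) therefore
selects different candidates than a coarser ($\pm 0.05$ m/s) match would.

## The synthetic-series module

`synthetic_series()` generates the reference processes that validate DFA
independently of the walker: white noise ($\alpha = 0.5$), brown noise
(cumulative white, $\alpha \approx 1.5$), and fractional Gaussian noise
with Hurst exponent $H$ via circulant embedding of the exact
autocovariance (exact in distribution; validated in the tests against the
closed-form lag-1 autocorrelation $2^{2H-1} - 1$ and by Hurst recovery
within 0.05).  These series share the stride-series CSV dialect, so the
DFA stage consumes simulated and synthetic series identically.  What
passing DFA tests on these processes shows is that the *analysis* is
correct; they do not make the walker's stride series resemble human data
in any respect beyond the scaling exponent.

## DFA implementation choices

The profile is the mean-centred accumulated sum; box sizes are 20 integers
log-spaced in $[4, N/4]$ (for $N = 500$: 4, 5, 6, …, 87, 104, 125;
duplicates after rounding are resolved upward, so the interior values may
differ by $\pm 1$ from other implementations — $\alpha$ is insensitive to
this at the precision used anywhere in the package).  Segments are
non-overlapping from the start of the series, any remainder discarded;
detrending is linear (DFA-1) per segment; $F(n)$ pools the squared
residuals across segments by root-mean-square, the convention that
reproduces $\alpha = 0.5$ on white noise exactly; the fit is unweighted
least squares of $\log F$ on $\log n$ (natural logs; the slope is
base-invariant).  A series whose profile detrends to zero everywhere
(e.g. a constant series) is reported as a degenerate-series error rather
than $\alpha = -\infty$.

## Reproducing the study-scale experiments

```{r, eval = FALSE}
w <- walker_params()
cyc <- find_limit_cycle(w, preset_cpg(0.4, mode = "flip"), dt = 1e-5)
reset <- cpg_params(A1 = 4.9, A2 = 10, delta = 0.47,
                    phi0 = cyc$cpg$phi0, mode = "resetting")
tr <- run_trial(w, reset, noise_spec(xi = 1, seed = 1),
                n_steps = 1300, dt = 1e-5,
                initial = cyc$state, phi_init = cyc$phi)
dfa(analysis_window(tr))
```

`run_experiment()` batches such trials over (mode, speed, $\xi$) cells
with per-cell derived seeds and writes annotated CSVs;
`scripts/acceptance.R` in the source repository re-runs the full pipeline
(stability analysis, 10-trial batteries per mode, staged calibration,
speed range) from a single seed.  Problem sizes used there — 650-stride
trials at $dt = 10^{-5}$ s, the 21×21×17 coarse grid with two refinement
stages at $dt = 10^{-4}$ s — were chosen so the whole pipeline completes
in well under half an hour on a single core.

## Known limitations

* The model is deliberately minimal: no ground compliance, slipping,
  double support, knees, or 3-D dynamics; noise enters only as additive
  joint-torque noise.
* The first-order integrator conserves passive energy only to
  $O(dt)$ (about $2 \times 10^{-4}$ J over a 0.3 s swing at
  $dt = 10^{-5}$); the tests assert the first-order convergence rate
  rather than a tighter bound a higher-order scheme would reach.
* The resetting model's scaling exponent sits at the white-noise boundary
  here rather than clearly in the persistent band; see the phase-response
  section for the diagnosis.
* Grid calibration inherits the coarse-to-fine heuristic's usual caveat:
  a minimizer whose basin is smaller than the coarse step can be missed.
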