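# cpgait

Why do stride times in healthy human walking wander the way they do?
Successive stride intervals are *statistically persistent* — deviations tend
to be followed by deviations of the same sign — and this persistence is lost
with aging, Parkinson's and Huntington's disease, and metronome-paced
walking. `cpgait` is an R package for studying one candidate mechanism with
a deliberately minimal neuromechanical model: a planar compass-type biped
driven by a single phase-oscillator central pattern generator (CPG), with
**phase resetting at foot contact** as the only mechanistic switch.

The oscillator phase advances as `dphi/dt = omega` and produces feedforward
torques at the ankle and hip,

```
u1 = A1 cos(phi) + sigma1        u2 = A2 cos(phi + Delta) + sigma2
```

with additive Gaussian torque noise `sigma_i = xi U_i`. At each touchdown
the walker's legs exchange roles through an inelastic impact, and the phase
either **resets** (`phi+ = phi0`) or merely **flips** (`phi+ = phi- - pi`,
mirroring the torque pattern the way the impact mirrors the legs). Both
modes share the same noiseless gait, so their difference under noise
isolates the contribution of resetting. Stride-interval series from
simulated trials are analysed with detrended fluctuation analysis (DFA):
scaling exponent `alpha = 0.5` means uncorrelated intervals, `alpha < 0.5`
anti-persistence, `0.5 < alpha <= 1` persistence.

The package provides, as plain R functions over a compiled C++ core:

- `run_trial()` — Euler–Maruyama simulation of the hybrid
  (continuous + impact) dynamics with seeded, reproducible torque noise;
- `dfa()` (+ `shuffle_surrogate()`, `synthetic_series()`) — DFA with
  surrogate testing and reference generators (white / brown / fractional
  Gaussian noise) of known exponent;
- `find_limit_cycle()`, `floquet_multipliers()`, `phase_response()` —
  noiseless gait, its Floquet stability, and phase-response-curve sampling;
- `evaluate_candidate()`, `optimize_for_speed()`, `speed_range()` — the
  energy-cost calibration of `(A1, A2, Delta)` per gait speed by staged
  grid search;
- `run_experiment()` — seeded batch experiments over (mode, speed, noise)
  cells with CSV output.

## A worked example

Walk the reference 0.4 m/s parameter set with and without phase resetting
at noise amplitude `xi = 1`, and compare the persistence of the stride
intervals:

```r
library(cpgait)

w   <- walker_params()                      # M = 50 kg, m = 11 kg, l = 1 m ...
cyc <- find_limit_cycle(w, preset_cpg(0.4, mode = "flip"), dt = 1e-5)
print(cyc)
#> Limit cycle (flip mode): v = 0.3976 m/s, stride period = 1.308997 s
#>   touchdown angle = -0.13048 rad, epsilon = 40.5824 (N m)^2 s
#>   post-touchdown phase = 2.515323 rad, residual = 5.33e-14

floquet_multipliers(cyc)
#> Floquet spectrum (step map, flip mode):
#>   +0.652854 +0.000000i  (|.| = 0.652854)
#>   -0.140018 +0.376752i  (|.| = 0.401929)
#>   -0.140018 -0.376752i  (|.| = 0.401929)
#>   +0.165155 +0.000000i  (|.| = 0.165155)
#> dominant magnitude 0.6529 (real positive)

reset <- cpg_params(A1 = 4.9, A2 = 10, delta = 0.47,
                    phi0 = cyc$cpg$phi0, mode = "resetting")
tr <- run_trial(w, reset, noise_spec(xi = 1, seed = 1),
                n_steps = 1300, dt = 1e-5,
                initial = cyc$state, phi_init = cyc$phi)
dfa(analysis_window(tr))        # 500 strides after a 150-stride transient
#> DFA: N = 500, 20 box sizes in [4, 125]
#> alpha = 0.4980 (anti-persistent)
```

The stride period is locked to half the oscillator period
(`pi / 4.8 = 0.654` s per step), the noiseless gait walks at 0.4 m/s, and
its dominant Floquet multiplier is 0.65 — real and positive, so
perturbations decay monotonically step to step. Under noise the two reset
modes separate sharply: the same trial without resetting gives
`alpha = 0.0524` — deeply anti-persistent, because the oscillator's fixed
clock pulls every timing deviation straight back — while with resetting the
contact events re-anchor the clock, timing shifts persist, and `alpha`
rises by an order of magnitude to the white-noise boundary (10-seed mean
0.49, individual trials 0.47-0.56).
`phase_response()` shows the mechanism directly: a mid-stride impulse
shifts all later touchdowns permanently under resetting, and not at all
without it.

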