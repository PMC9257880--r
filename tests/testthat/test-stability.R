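w <- walker_params()

test_that("limit cycle is a fixed point with the documented gait", {
  cyc <- v04_cycle()
  expect_lt(cyc$residual, 1e-9)
  z2 <- stride_map(cyc$z, w, cyc$cpg, steps = 2L, dt = 1e-4)
  expect_equal(as.numeric(z2), cyc$z, tolerance = 1e-8)
  # the v = 0.4 m/s reference set walks at 0.4 m/s
  expect_equal(cyc$v, 0.4, tolerance = 0.01)
  # step period is locked to half the oscillator period
  expect_equal(cyc$step_period, pi / cyc$cpg$omega, tolerance = 1e-8)
})

test_that("stride map equals the composition of two step maps", {
  cyc <- v04_cycle()
  z <- cyc$z + c(2e-3, -1e-3, 1e-3, 5e-4)
  one <- stride_map(z, w, cyc$cpg, steps = 1L, dt = 1e-4)
  two <- stride_map(as.numeric(one), w, cyc$cpg, steps = 1L, dt = 1e-4)
  direct <- stride_map(z, w, cyc$cpg, steps = 2L, dt = 1e-4)
  expect_equal(as.numeric(two), as.numeric(direct), tolerance = 1e-10)
})

test_that("section map agrees with a full trial's touchdown extraction", {
  cyc <- v04_cycle()
  tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 2L, dt = 1e-4,
                  initial = cyc$state, phi_init = cyc$phi)
  z <- stride_map(cyc$z, w, cyc$cpg, steps = 2L, dt = 1e-4)
  expect_equal(tr$td_post[2L, c(1, 3, 4)], as.numeric(z)[1:3],
               tolerance = 1e-10)
  expect_equal(attr(z, "tau"), tr$step_times[3L], tolerance = 1e-10)
})

test_that("resetting and flip modes share the noiseless limit cycle", {
  cyc <- v04_cycle()
  reset <- v04_reset_cpg()
  cyc_r <- find_limit_cycle(w, reset, dt = 1e-4)
  expect_equal(cyc_r$state, cyc$state, tolerance = 1e-7)
  expect_equal(cyc_r$tau, cyc$tau, tolerance = 1e-8)
  expect_equal(cyc_r$v, cyc$v, tolerance = 1e-7)
})

test_that("Floquet spectrum: dominant mode positive real near 0.65", {
  cyc <- v04_cycle()
  fl <- floquet_multipliers(cyc, map = "step")
  expect_length(fl$multipliers, 4L)
  expect_true(fl$dominant_is_real_positive)
  expect_lt(fl$dominant_magnitude, 1)
  expect_equal(fl$dominant_magnitude, 0.653, tolerance = 0.01)
  # stride-map multipliers are the squares of the step-map ones
  fs <- floquet_multipliers(cyc, map = "stride")
  expect_equal(sort(Mod(fs$multipliers)),
               sort(Mod(fl$multipliers)^2), tolerance = 0.01)
  # resetting mode has almost the same dominant mode
  cyc_r <- find_limit_cycle(w, v04_reset_cpg(), dt = 1e-4)
  fr <- floquet_multipliers(cyc_r, map = "step")
  expect_length(fr$multipliers, 3L)
  expect_equal(fr$dominant_magnitude, fl$dominant_magnitude,
               tolerance = 0.005)
  expect_true(fr$dominant_is_real_positive)
})

test_that("Floquet multipliers are stable under h refinement", {
  cyc <- v04_cycle()
  doms <- vapply(c(1e-6, 1e-5), function(h)
    floquet_multipliers(cyc, h = h)$dominant_magnitude, numeric(1))
  expect_lt(abs(diff(doms)), 1e-3)
})

test_that("phase response: persistent shift with resetting, none without", {
  cyc <- v04_cycle()
  reset <- v04_reset_cpg()
  cyc_r <- find_limit_cycle(w, reset, dt = 1e-4)

  # zero perturbation, zero shift
  p0 <- phase_response(cyc_r, perturbation = c(0, 0), at_phase = 0.4)
  expect_equal(p0$phase_shift, 0, tolerance = 1e-10)

  shifts_r <- vapply(c(0.2, 0.5, 0.8), function(f)
    phase_response(cyc_r, perturbation = c(0.05, 0), at_phase = f,
                   horizon = 12L)$phase_shift, numeric(1))
  shifts_f <- vapply(c(0.2, 0.5, 0.8), function(f)
    phase_response(cyc, perturbation = c(0.05, 0), at_phase = f,
                   horizon = 12L)$phase_shift, numeric(1))
  # resetting: permanent, phase-dependent shift
  expect_true(all(abs(shifts_r) > 1e-4))
  expect_gt(max(shifts_r) - min(shifts_r), 1e-4)
  # no resetting: the oscillator clock wins; shifts decay to zero
  expect_true(all(abs(shifts_f) < 1e-4))
  expect_lt(max(abs(shifts_f)), 0.05 * max(abs(shifts_r)))
})

test_that("phase shift is linear in small impulse magnitudes", {
  cyc_r <- find_limit_cycle(w, v04_reset_cpg(), dt = 1e-4)
  mags <- c(0.01, 0.02, 0.04)
  s <- vapply(mags, function(m)
    phase_response(cyc_r, perturbation = c(m, 0), at_phase = 0.35,
                   horizon = 12L)$phase_shift, numeric(1))
  expect_equal(s[2] / s[1], 2, tolerance = 0.1)
  expect_equal(s[3] / s[1], 4, tolerance = 0.2)
})

test_that("perturbation decay rate matches the dominant multiplier", {
  cyc <- v04_cycle()
  fl <- floquet_multipliers(cyc, map = "step")
  dz <- c(1e-4, 1e-4, -1e-4, 1e-4)
  z <- cyc$z + dz
  norms <- numeric(8)
  for (k in 1:8) {
    z <- as.numeric(stride_map(z, w, cyc$cpg, steps = 1L, dt = 1e-4))
    norms[k] <- sqrt(sum((z - cyc$z)^2))
  }
  # log-linear decay slope over the asymptotic tail
  rate <- exp(mean(diff(log(norms[3:8]))))
  expect_equal(rate, fl$dominant_magnitude, tolerance = 0.05)
})
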