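w <- walker_params()

test_that("noiseless trial from the limit cycle has constant stride intervals", {
  cyc <- v04_cycle()
  tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 24L, dt = 1e-4,
                  initial = cyc$state, phi_init = cyc$phi)
  expect_false(tr$fell)
  expect_length(tr$stride_intervals, 12L)
  expect_equal(tr$stride_intervals, rep(cyc$tau, 12L), tolerance = 1e-6)
})

test_that("identical seeds reproduce a trial exactly", {
  cyc <- v04_cycle()
  t1 <- run_trial(w, cyc$cpg, noise_spec(0.1, seed = 42), n_steps = 30L,
                  dt = 1e-4, initial = cyc$state, phi_init = cyc$phi)
  t2 <- run_trial(w, cyc$cpg, noise_spec(0.1, seed = 42), n_steps = 30L,
                  dt = 1e-4, initial = cyc$state, phi_init = cyc$phi)
  t3 <- run_trial(w, cyc$cpg, noise_spec(0.1, seed = 43), n_steps = 30L,
                  dt = 1e-4, initial = cyc$state, phi_init = cyc$phi)
  expect_identical(t1$step_times, t2$step_times)
  expect_identical(t1$stride_intervals, t2$stride_intervals)
  expect_false(identical(t1$step_times, t3$step_times))
})

test_that("stride intervals are non-overlapping double steps", {
  cyc <- v04_cycle()
  tr <- run_trial(w, cyc$cpg, noise_spec(0.05, seed = 3), n_steps = 21L,
                  dt = 1e-4, initial = cyc$state, phi_init = cyc$phi)
  expect_length(tr$stride_intervals, 10L) # floor(21 / 2)
  tt <- tr$step_times
  manual <- tt[seq(3, 21, 2)] - tt[seq(1, 19, 2)]
  expect_equal(tr$stride_intervals, manual)
})

test_that("step period is insensitive to dt once events are refined", {
  cyc <- v04_cycle()
  tau_at <- function(dt) {
    tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 8L, dt = dt,
                    initial = cyc$state, phi_init = cyc$phi)
    tr$stride_intervals[4L]
  }
  expect_lt(abs(tau_at(1e-5) - tau_at(5e-6)), 1e-6)
})

test_that("analysis window selects and validates strides", {
  x <- seq_len(650)
  expect_length(analysis_window(x), 500L)
  expect_equal(analysis_window(x)[1], 151)
  expect_equal(analysis_window(x, discard = 0, keep = 650), x)
  err <- tryCatch(analysis_window(seq_len(400)), error = function(e)
    conditionMessage(e))
  expect_match(err, "250")  # reports the shortfall after the discard
})

test_that("gait speed matches contact geometry on the limit cycle", {
  cyc <- v04_cycle()
  tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 30L, dt = 1e-4,
                  initial = cyc$state, phi_init = cyc$phi)
  v <- gait_speed(tr, discard = 2L, keep = 10L)
  expect_equal(v, 2 * w$l * abs(sin(cyc$contact_angle)) / cyc$step_period,
               tolerance = 1e-6)
  expect_equal(v, 0.4, tolerance = 0.01)
})

test_that("falls are reported as data, not errors", {
  # absurd parameters: enormous torques destabilize immediately
  bad <- cpg_params(A1 = 500, A2 = 500, delta = 0.3, mode = "flip")
  tr <- run_trial(w, bad, noise_spec(0), n_steps = 10L, dt = 1e-4,
                  initial = default_guess <- walker_state(0.13, 0.26,
                                                          -0.56, -0.26),
                  phi_init = 2.5)
  expect_true(tr$fell)
  expect_match(tr$fall_reason, "threshold|timeout")
  expect_error(gait_speed(tr), "fell")
})

test_that("noise discretizations scale as designed", {
  cyc <- v04_cycle()
  run_sd <- function(disc, xi) {
    tr <- run_trial(w, cyc$cpg, noise_spec(xi, seed = 9,
                                           discretization = disc),
                    n_steps = 60L, dt = 1e-4, initial = cyc$state,
                    phi_init = cyc$phi)
    stats::sd(tr$stride_intervals)
  }
  s_hold <- run_sd("cycle_hold", 1)
  s_wien <- run_sd("wiener", 1)
  s_step <- run_sd("per_step", 1)
  # per_step is weaker than wiener by about sqrt(dt)
  expect_lt(s_step, s_wien / 50)
  expect_gt(s_hold, 1e-3) # cycle_hold produces appreciable variability
})
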