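w <- walker_params()

test_that("unactuated walker cannot sustain level-ground gait", {
  e <- evaluate_candidate(w, 0, 0, 0, dt = 1e-4)
  expect_false(e$stable)
  expect_true(is.na(e$v))
})

test_that("the v = 0.4 reference set evaluates as a stable 0.4 m/s gait", {
  e <- evaluate_candidate(w, 4.9, 10, 0.47, dt = 1e-4)
  expect_true(e$stable)
  expect_equal(e$v, 0.4, tolerance = 0.01)
  expect_lt(e$dominant, 1)
  # step period locked to half the oscillator period makes the torque cost
  # analytic: epsilon = (A1^2 + A2^2) * pi / (2 omega)
  expect_equal(e$epsilon, (4.9^2 + 10^2) * pi / (2 * 4.8), tolerance = 1e-3)
})

test_that("epsilon matches a trapezoid-rule oracle on the torque trace", {
  cyc <- v04_cycle()
  tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 2L, dt = 1e-4,
                  initial = cyc$state, phi_init = cyc$phi,
                  record = TRUE, record_dt = 1e-4)
  traj <- tr$trajectory
  t1 <- tr$step_times[2L]
  in_step <- traj[, "t"] >= t1 & traj[, "t"] <= tr$step_times[3L]
  tt <- traj[in_step, "t"]
  f <- traj[in_step, "u1"]^2 + traj[in_step, "u2"]^2
  trap <- sum(diff(tt) * (head(f, -1) + tail(f, -1)) / 2)
  expect_equal(tr$eps_step[2L], trap, tolerance = 5e-3)
})

test_that("grid scan + pick respect speed window, epsilon order and ties", {
  tab <- data.frame(A1 = c(2, 3, 3, 5), A2 = c(5, 4, 6, 2),
                    delta = c(0.5, 0.4, 0.4, 0.3),
                    stable = c(TRUE, TRUE, TRUE, FALSE),
                    v = c(0.40, 0.401, 0.402, 0.40),
                    epsilon = c(7, 7, 9, 1), tau = 1.3)
  best <- cpgait:::pick_optimum(tab, 0.4, 0.005)
  # unstable rows excluded despite lowest epsilon; tie broken by smaller A1
  expect_equal(best$A1, 2)
  expect_null(cpgait:::pick_optimum(tab, 0.9, 0.005))
})

test_that("a small scan around the reference set finds it optimal", {
  tab <- grid_scan(w, A1s = c(4.7, 4.9, 5.1), A2s = c(9.5, 10, 10.5),
                   deltas = c(0.45, 0.47, 0.49), dt = 1e-4)
  expect_true(any(tab$stable))
  st <- tab[tab$stable, ]
  # all stable candidates share the locked step period
  expect_true(all(abs(st$tau - 2 * pi / 4.8) < 1e-4))
  # epsilon depends on the amplitudes alone through A1^2 + A2^2
  expect_equal(st$epsilon, (st$A1^2 + st$A2^2) * pi / (2 * 4.8),
               tolerance = 1e-3)
})

test_that("speed range over a pinned grid brackets the candidate speed", {
  tab <- grid_scan(w, A1s = 4.9, A2s = 10, deltas = 0.47, dt = 1e-4)
  rng <- speed_range(w, coarse = tab, refine = FALSE)
  expect_equal(unname(rng[1]), unname(rng[2]))
  expect_equal(unname(rng[1]), 0.4, tolerance = 0.01)
  dead <- grid_scan(w, A1s = 0, A2s = 0, deltas = 0, dt = 1e-4)
  expect_error(speed_range(w, coarse = dead, refine = FALSE), "no stable")
})

test_that("staged refinement zooms onto the epsilon minimizer", {
  coarse <- grid_scan(w, A1s = c(4, 5, 6), A2s = c(9, 10, 11),
                      deltas = c(0.4, 0.5), dt = 1e-4)
  opt <- optimize_for_speed(w, 0.4, coarse = coarse, dt = 1e-4)
  expect_s3_class(opt, "gait_optimum")
  expect_lt(abs(opt$v - 0.4), 0.00501)
  expect_true(is.finite(opt$phi0))
  expect_lt(opt$dominant, 1)
  # the winner beats every stable same-speed candidate on the final table
  tab <- attr(opt, "table")
  ok <- tab$stable & abs(tab$v - 0.4) <= 0.005
  expect_true(all(opt$epsilon <= tab$epsilon[ok] + 1e-9))
})
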