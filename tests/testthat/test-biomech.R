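w <- walker_params()
wl <- list(M = w$M, m = w$m, l = w$l, b = w$b, g = w$g)

test_that("upright equilibrium has zero acceleration", {
  a <- swing_accelerations(walker_state(0, 0, 0, 0), c(0, 0), w)
  expect_equal(a, c(0, 0))
})

test_that("accelerations match the position-level Lagrangian oracle", {
  set.seed(11)
  for (i in 1:10) {
    st <- walker_state(runif(1, -0.4, 0.4), runif(1, -0.6, 0.6),
                       runif(1, -2, 2), runif(1, -2, 2))
    u <- runif(2, -10, 10)
    expect_equal(swing_accelerations(st, u, w), oracle_accel(st, u, wl),
                 tolerance = 1e-6)
  }
})

test_that("mass matrix is symmetric positive definite across theta2", {
  for (th2 in seq(-pi, pi, length.out = 41)) {
    M <- mass_matrix(th2, w)
    expect_equal(M[1, 2], M[2, 1])
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(M, oracle_mass_matrix(c(0, th2), wl), tolerance = 1e-6)
  }
})

test_that("passive swing conserves mechanical energy, improving with dt", {
  passive <- cpg_params(A1 = 0, A2 = 0, delta = 0, mode = "flip")
  st <- walker_state(0.12, 0.2, -0.3, 0.4)
  drift <- function(dt) {
    res <- cpgait:::sim_raw(w, passive, n_steps = 1L, dt = dt, init = st,
                            phi = 0, t_stop = 0.3, fall_timeout = 10)
    abs(cpgait:::cg_energy_cpp(res$final_state, cpgait:::as_wp_vec(w)) -
          mechanical_energy(st, w))
  }
  d1 <- drift(1e-5)
  d2 <- drift(1e-4)
  expect_lt(d1, 5e-4)       # frozen sanity bound for the first-order scheme
  # first-order integrator: drift shrinks linearly with dt
  expect_lt(d1, d2 / 5)
  expect_equal(mechanical_energy(st, w), oracle_energy(st, wl),
               tolerance = 1e-8)
})

test_that("touchdown condition implements contact-in-front with closing legs", {
  expect_true(touchdown_condition(walker_state(-0.2, -0.4, -0.5, 0.5)))
  # theta1 > 0: contact would be behind the walker
  expect_false(touchdown_condition(walker_state(0.2, 0.4, -0.5, 0.5)))
  # legs opening (ds/dt > 0): forward scuffing is ignored
  expect_false(touchdown_condition(walker_state(-0.2, -0.4, 0.5, 0.5)))
  # off the section
  expect_false(touchdown_condition(walker_state(-0.2, -0.3, -0.5, 0.5)))
})

test_that("collision map matches conservation oracle and loses energy", {
  set.seed(7)
  for (i in 1:12) {
    a <- runif(1, -0.3, -0.02)
    st <- walker_state(a, 2 * a, runif(1, -1.5, -0.1), runif(1, -1, 1))
    if (!touchdown_condition(st, tol = 1e-9)) next
    post <- collision_map(st, w)
    expect_equal(unname(post), oracle_collision(st, wl), tolerance = 1e-10)
    # angles swap-and-negate; post state on the next touchdown section
    expect_equal(post[["theta1"]], -st[["theta1"]])
    expect_equal(post[["theta2"]], -st[["theta2"]])
    expect_equal(2 * post[["theta1"]] - post[["theta2"]], 0)
    # fully inelastic impact cannot create kinetic energy
    expect_lte(oracle_kinetic(post, wl), oracle_kinetic(st, wl) + 1e-12)
  }
})

test_that("collision with zero angular velocities returns zero velocities", {
  st <- walker_state(-0.15, -0.3, 0, 0)
  post <- collision_map(st, w, check = FALSE)
  expect_equal(unname(post[3:4]), c(0, 0))
})

test_that("kinetic energy is quadratic in velocities", {
  st <- walker_state(0.1, 0.2, 0.5, -0.3)
  st2 <- walker_state(0.1, 0.2, 1.0, -0.6)
  e0 <- mechanical_energy(walker_state(0.1, 0.2, 0, 0), w)
  expect_equal(mechanical_energy(st2, w) - e0,
               4 * (mechanical_energy(st, w) - e0))
})
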