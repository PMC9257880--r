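#' Angular accelerations during the swing phase
#'
#' Solves the two-link equations of motion
#' `M(theta2) qdd + C(q, qd) + G(q) = u` for the angular accelerations,
#' where `M` is the configuration-dependent mass matrix, `C` collects
#' Coriolis/centrifugal terms and `G` the gravity terms.
#'
#' @param state numeric length-4 state `(theta1, theta2, dtheta1, dtheta2)`,
#'   see [walker_state()].
#' @param torques numeric length-2 `(u1, u2)`: ankle and hip torque, N m.
#' @param walker a [walker_params()] object.
#' @return Numeric length-2 vector `(ddtheta1, ddtheta2)` in rad/s^2.
#' @examples
#' swing_accelerations(walker_state(0, 0, 0, 0), c(0, 0), walker_params())
#' @export
swing_accelerations <- function(state, torques, walker = walker_params()) {
  stopifnot(length(state) == 4L, length(torques) == 2L)
  cg_accel_cpp(as.double(state), as.double(torques), as_wp_vec(walker))
}

#' Mass matrix of the swing-phase dynamics
#'
#' @param theta2 inter-leg angle, rad.
#' @param walker a [walker_params()] object.
#' @return The symmetric 2 x 2 mass matrix (kg m^2).
#' @export
mass_matrix <- function(theta2, walker = walker_params()) {
  cg_mass_matrix_cpp(as.double(theta2), as_wp_vec(walker))
}

#' Touchdown condition of the swing leg
#'
#' The swing-leg tip contacts the ground in front of the walker when the
#' section function `s = 2 theta1 - theta2` vanishes while the stance leg
#' has rotated past vertical (`theta1 < 0`) and the legs are closing
#' (`ds/dt = 2 dtheta1 - dtheta2 < 0`).  Crossings with `ds/dt > 0`
#' correspond to the swing leg scuffing the ground on its way forward and
#' are ignored.
#'
#' @param state numeric length-4 state.
#' @param tol absolute tolerance on `s` for the equality condition.
#' @return `TRUE` if all three touchdown conditions hold.
#' @examples
#' touchdown_condition(walker_state(-0.2, -0.4, -0.5, 0.5)) # TRUE
#' touchdown_condition(walker_state(0.2, 0.4, -0.5, 0.5))   # behind: FALSE
#' @export
touchdown_condition <- function(state, tol = 1e-10) {
  s <- 2 * state[[1]] - state[[2]]
  sdot <- 2 * state[[3]] - state[[4]]
  abs(s) <= tol && state[[1]] < 0 && sdot < 0
}

#' Leg-swap collision map at touchdown
#'
#' Applies the instantaneous, fully inelastic touchdown impact: the leg
#' roles are exchanged, so the angles swap sign (`theta1+ = -theta1-`,
#' `theta2+ = -theta2-`) and the angular velocities jump according to
#' `Q+(theta1-) qd+ = Q-(theta1-) qd-`, which conserves the angular momentum
#' of the whole walker about the new contact point and of the trailing leg
#' about the hip.  `Q+` is inverted numerically.
#'
#' @param state pre-impact state `(theta1, theta2, dtheta1, dtheta2)`; must
#'   satisfy [touchdown_condition()] unless `check = FALSE`.
#' @param walker a [walker_params()] object.
#' @param check verify the touchdown condition first (with tolerance
#'   `tol`)?
#' @param tol tolerance forwarded to [touchdown_condition()].
#' @return The post-impact state, which lies on the touchdown section of the
#'   next step (`2 theta1+ - theta2+ = 0`).
#' @export
collision_map <- function(state, walker = walker_params(), check = TRUE,
                          tol = 1e-8) {
  stopifnot(length(state) == 4L)
  if (check && !touchdown_condition(state, tol = tol))
    stop("state does not satisfy the touchdown conditions")
  out <- cg_collision_cpp(as.double(state), as_wp_vec(walker))
  names(out) <- c("theta1", "theta2", "dtheta1", "dtheta2")
  out
}

#' Total mechanical energy of the walker
#'
#' Kinetic plus gravitational potential energy of the hip mass and both leg
#' masses, measured with the potential datum at the stance contact point.
#' Along passive (`u1 = u2 = 0`), noiseless swing trajectories this quantity
#' is conserved up to integrator order, which makes it the standard test
#' instrument for the integrator and the Lagrangian terms.
#'
#' @param state numeric length-4 state.
#' @param walker a [walker_params()] object.
#' @return Energy in joules.
#' @export
mechanical_energy <- function(state, walker = walker_params()) {
  stopifnot(length(state) == 4L)
  cg_energy_cpp(as.double(state), as_wp_vec(walker))
}
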