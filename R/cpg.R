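#' Advance the oscillator phase
#'
#' The CPG phase obeys `dphi/dt = omega` between touchdowns; this advances
#' it by one time step and wraps the result into `[0, 2 pi)`.
#'
#' @param phi current phase, rad.
#' @param omega oscillator frequency, rad/s.
#' @param dt time step, s (`dt >= 0`).
#' @return The wrapped phase `phi + omega * dt`.
#' @export
phase_advance <- function(phi, omega, dt) {
  stopifnot(dt >= 0, omega > 0)
  wrap_phase(phi + omega * dt)
}

#' Feedforward joint torques of the CPG
#'
#' `u1 = A1 cos(phi) + sigma1` (ankle), `u2 = A2 cos(phi + delta) + sigma2`
#' (hip).  Shifting the phase by `-pi` negates both deterministic torques,
#' which is what makes the half-cycle phase flip at touchdown consistent
#' with the sign flip of the mechanical angles.
#'
#' @param phi oscillator phase, rad.
#' @param cpg a [cpg_params()] object.
#' @param noise numeric length-2 `(sigma1, sigma2)` additive torque noise.
#' @return Named numeric vector `c(u1, u2)` in N m.
#' @export
feedforward_torques <- function(phi, cpg, noise = c(0, 0)) {
  stopifnot(length(noise) == 2L)
  c(u1 = cpg$A1 * cos(phi) + noise[[1]],
    u2 = cpg$A2 * cos(phi + cpg$delta) + noise[[2]])
}

#' Phase update at touchdown
#'
#' In `"resetting"` mode the phase is reset to the constant `phi0`
#' regardless of its pre-touchdown value; in `"flip"` mode it advances by
#' `-pi` (half a cycle), mirroring the torque pattern exactly as the
#' collision mirrors the mechanical angles.
#'
#' @param phi_minus phase just before touchdown, rad.
#' @param cpg a [cpg_params()] object; in resetting mode `phi0` must be
#'   calibrated.
#' @return The post-touchdown phase in `[0, 2 pi)`.
#' @export
touchdown_phase_update <- function(phi_minus, cpg) {
  if (cpg$mode == "resetting") {
    if (is.na(cpg$phi0))
      stop("phi0 is not calibrated; run calibrate_phi0() first")
    wrap_phase(cpg$phi0)
  } else {
    wrap_phase(phi_minus - pi)
  }
}

#' Calibrate the reset phase phi0
#'
#' Runs the noiseless flip-mode model forward until the post-touchdown phase
#' `phi+` converges, and returns that limit.  Because the flip-mode and
#' resetting-mode models share this steady gait by construction, resetting
#' the phase to the calibrated `phi0` leaves the noiseless limit cycle
#' unchanged while altering only the response to perturbations.
#'
#' `phi0` depends on `(A1, A2, delta)` and must be recalibrated for every
#' parameter set.
#'
#' @param walker a [walker_params()] object.
#' @param cpg a [cpg_params()] object (its `mode` is ignored; calibration
#'   always runs the flip-mode dynamics).
#' @param initial length-4 initial state; default is a generic
#'   post-touchdown guess that lies in the basin of all stable gaits studied
#'   here.
#' @param phi_init initial oscillator phase.
#' @param dt integrator time step, s.
#' @param tol convergence tolerance: consecutive `phi+` values must agree
#'   to within `tol` rad...
#' @param consec ...for this many consecutive touchdowns.
#' @param max_steps step budget before declaring calibration failure.
#' @return The converged reset phase (rad), with attribute `"steps"` giving
#'   the number of steps used.
#' @examples
#' \donttest{
#' cpg <- preset_cpg(0.4)
#' phi0 <- calibrate_phi0(walker_params(), cpg, dt = 1e-4)
#' }
#' @export
calibrate_phi0 <- function(walker, cpg, initial = NULL, phi_init = 2.5,
                           dt = 1e-5, tol = 1e-9, consec = 5L,
                           max_steps = 2000L) {
  if (is.null(initial)) initial <- default_section_guess()
  flip <- cpg_params(omega = cpg$omega, A1 = cpg$A1, A2 = cpg$A2,
                     delta = cpg$delta, mode = "flip")
  state <- as.double(initial)
  phi <- phi_init
  chunk <- 64L
  done <- 0L
  phis <- numeric(0)
  while (done < max_steps) {
    n <- min(chunk, max_steps - done)
    res <- sim_raw(walker, flip, n_steps = n, dt = dt, init = state,
                   phi = phi)
    if (res$fell || res$n_touchdowns < n)
      stop("calibration failed: the flip-mode model fell (",
           res$fall_reason, ") after ", done + res$n_touchdowns, " steps")
    phis <- c(phis, res$td_post[seq_len(n), 5L])
    done <- done + n
    if (length(phis) > consec) {
      d <- abs(diff(phis))
      tail_d <- d[seq(length(d) - consec + 1L, length(d))]
      if (all(tail_d < tol)) {
        out <- phis[length(phis)]
        attr(out, "steps") <- done
        return(out)
      }
    }
    state <- res$final_state
    phi <- res$final_phi
  }
  stop("phi0 did not converge within ", max_steps,
       " steps (last change ", signif(abs(diff(phis))[length(phis) - 1L], 3),
       " rad)")
}

# A generic post-touchdown state in the basin of attraction of the stable
# gaits considered here (stance leg ahead of vertical, both legs rotating
# forward).  Used as the default warm start for calibration and limit-cycle
# searches.
default_section_guess <- function() {
  walker_state(0.13, 0.26, -0.56, -0.26)
}
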