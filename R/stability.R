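# Section coordinates.  The post-touchdown section satisfies
# 2*theta1 - theta2 = 0, so theta2 is eliminated; the oscillator phase is a
# live coordinate only in flip mode (in resetting mode it is pinned to phi0
# immediately after every touchdown and cannot carry Floquet modes).
section_dim <- function(cpg) if (cpg$mode == "resetting") 3L else 4L

section_pack <- function(state, phi, cpg) {
  z <- c(state[[1]], state[[3]], state[[4]])
  if (cpg$mode == "flip") z <- c(z, phi)
  z
}

section_unpack <- function(z, cpg) {
  state <- c(z[[1]], 2 * z[[1]], z[[2]], z[[3]])
  phi <- if (cpg$mode == "flip") z[[4]] else cpg$phi0
  list(state = state, phi = phi)
}

#' Touchdown-section return map
#'
#' Flows the noiseless dynamics from a post-touchdown section state through
#' `steps` touchdowns and returns the post-touchdown section state reached.
#' Section coordinates are `(theta1, dtheta1, dtheta2)` with the phase
#' pinned to `phi0` in resetting mode, and `(theta1, dtheta1, dtheta2, phi)`
#' in flip mode.  `steps = 1` is the one-step touchdown map; `steps = 2` the
#' stride map (their composition).
#'
#' @param z section state (length 3 or 4 depending on `cpg$mode`).
#' @param walker a [walker_params()] object.
#' @param cpg a [cpg_params()] object.
#' @param steps number of touchdowns to flow through.
#' @param dt integrator time step, s.
#' @return The section state after `steps` touchdowns, with attributes
#'   `"tau"` (elapsed time), `"contact_angles"` (stance angle at each
#'   touchdown) and `"eps_step"` (torque cost of each step cycle).
#' @export
stride_map <- function(z, walker, cpg, steps = 2L, dt = 1e-5) {
  u <- section_unpack(z, cpg)
  if (cpg$mode == "resetting" && is.na(cpg$phi0))
    stop("phi0 is not calibrated; resetting-mode section requires it")
  res <- sim_raw(walker, cpg, n_steps = steps, dt = dt, init = u$state,
                 phi = u$phi)
  if (res$fell || res$n_touchdowns < steps)
    stop("walker fell during section map flow (", res$fall_reason, ")")
  zf <- section_pack(res$td_post[steps, 1:4], res$td_post[steps, 5L], cpg)
  structure(zf,
            tau = res$td_times[steps],
            contact_angles = res$td_pre[seq_len(steps), 1L],
            eps_step = res$eps_step[seq_len(steps)])
}

#' Find the noiseless limit cycle
#'
#' Locates the periodic steady gait as a fixed point of the touchdown
#' return map: first by forward simulation until the step period converges,
#' then polished by damped Newton iteration on `z - P(z)` with a
#' finite-difference Jacobian.
#'
#' @param walker a [walker_params()] object.
#' @param cpg a [cpg_params()] object.  In resetting mode `phi0` must
#'   already be calibrated; the flip mode needs no calibration.
#' @param guess length-4 post-touchdown state guess (plus `phi_guess`), or
#'   `NULL` for the package's generic warm start.
#' @param phi_guess initial phase for the forward stage.
#' @param dt integrator time step, s.
#' @param forward_steps budget of steps for the forward-convergence stage.
#' @param newton_tol residual tolerance on the fixed point.
#' @param newton_max maximum Newton iterations.
#' @return An object of class `"limit_cycle"`: fields `z` (section fixed
#'   point), `state` (full post-touchdown state), `phi` (post-touchdown
#'   phase), `step_period` and `tau` (stride period, = 2 step periods),
#'   `v` (gait speed from contact geometry), `epsilon` (torque cost per
#'   step cycle), `contact_angle`, `residual`, `mode` and `cpg` (with
#'   `phi0` filled in for convenience).
#' @export
find_limit_cycle <- function(walker, cpg, guess = NULL, phi_guess = 2.5,
                             dt = 1e-5, forward_steps = 400L,
                             newton_tol = 1e-10, newton_max = 25L) {
  if (is.null(guess)) guess <- default_section_guess()
  if (cpg$mode == "resetting" && is.na(cpg$phi0))
    stop("phi0 is not calibrated; run calibrate_phi0() first")

  # Stage 1: forward flow to the neighbourhood of the cycle.
  res <- sim_raw(walker, cpg, n_steps = forward_steps, dt = dt,
                 init = as.double(guess),
                 phi = if (cpg$mode == "resetting") cpg$phi0 else phi_guess,
                 tau_tol = 1e-9, tau_consec = 5L)
  if (res$fell)
    stop("no limit cycle found: walker fell during forward stage (",
         res$fall_reason, ")")
  k <- res$n_touchdowns
  z <- section_pack(res$td_post[k, 1:4], res$td_post[k, 5L], cpg)

  # Stage 2: damped Newton on the stride map.
  h <- 1e-7
  d <- length(z)
  resid <- Inf
  for (it in seq_len(newton_max)) {
    Fz <- stride_map(z, walker, cpg, steps = 2L, dt = dt)
    r <- as.numeric(Fz) - z
    resid <- max(abs(r))
    if (resid < newton_tol) break
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      zp <- z; zp[j] <- zp[j] + h
      zm <- z; zm[j] <- zm[j] - h
      J[, j] <- (as.numeric(stride_map(zp, walker, cpg, 2L, dt)) -
                 as.numeric(stride_map(zm, walker, cpg, 2L, dt))) / (2 * h)
    }
    step <- tryCatch(solve(diag(d) - J, r),
                     error = function(e) stop(
                       "Newton failed: singular Jacobian (residual ",
                       signif(resid, 3), ")"))
    lambda <- 1
    repeat {
      z_new <- z + lambda * step
      ok <- tryCatch({
        r_new <- as.numeric(stride_map(z_new, walker, cpg, 2L, dt)) - z_new
        max(abs(r_new)) < resid || lambda < 1e-3
      }, error = function(e) FALSE)
      if (ok) break
      lambda <- lambda / 2
      if (lambda < 1e-4)
        stop("Newton diverged; last residual ", signif(resid, 3))
    }
    z <- z + lambda * step
  }
  if (resid >= newton_tol * 10)
    warning("limit cycle residual ", signif(resid, 3),
            " above tolerance ", newton_tol)

  Fz <- stride_map(z, walker, cpg, steps = 2L, dt = dt)
  tau <- attr(Fz, "tau")
  th_td <- attr(Fz, "contact_angles")
  eps <- attr(Fz, "eps_step")
  u <- section_unpack(z, cpg)
  cpg_out <- cpg
  if (cpg$mode == "flip") cpg_out$phi0 <- wrap_phase(u$phi)
  structure(list(z = z, state = u$state, phi = u$phi,
                 step_period = tau / 2, tau = tau,
                 v = 2 * walker$l * abs(sin(th_td[1L])) / (tau / 2),
                 epsilon = eps[1L],
                 contact_angle = th_td[1L],
                 residual = resid, mode = cpg$mode,
                 walker = walker, cpg = cpg_out, dt = dt),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("Limit cycle (%s mode): v = %.4f m/s, stride period = %.6f s\n",
              x$mode, x$v, x$tau))
  cat(sprintf("  touchdown angle = %.5f rad, epsilon = %.4f (N m)^2 s\n",
              x$contact_angle, x$epsilon))
  cat(sprintf("  post-touchdown phase = %.6f rad, residual = %.2e\n",
              wrap_phase(x$phi), x$residual))
  invisible(x)
}

#' Floquet multipliers of the periodic gait
#'
#' Eigenvalues of the finite-difference (central) Jacobian of the touchdown
#' return map at the limit-cycle fixed point.  `map = "step"` linearizes the
#' one-step touchdown map (whose dominant multiplier is the conventional
#' measure of step-to-step stability); `map = "stride"` the two-step
#' composition, whose multipliers are the squares of the one-step ones.
#'
#' @param cycle a `"limit_cycle"` object from [find_limit_cycle()].
#' @param walker,cpg model parameters; default to those stored in `cycle`.
#' @param map `"step"` (default) or `"stride"`.
#' @param h finite-difference step per section coordinate.
#' @param dt integrator time step; defaults to the cycle's.
#' @return An object of class `"floquet"`: `multipliers` (complex, sorted
#'   by decreasing magnitude), `dominant_magnitude`,
#'   `dominant_is_real_positive`, `map`, `mode`.
#' @export
floquet_multipliers <- function(cycle, walker = cycle$walker,
                                cpg = cycle$cpg,
                                map = c("step", "stride"), h = 1e-6,
                                dt = cycle$dt) {
  map <- match.arg(map)
  steps <- if (map == "step") 1L else 2L
  z <- cycle$z
  d <- length(z)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    J[, j] <- (as.numeric(stride_map(zp, walker, cpg, steps, dt)) -
               as.numeric(stride_map(zm, walker, cpg, steps, dt))) / (2 * h)
  }
  if (!all(is.finite(J))) stop("non-finite entries in the Floquet Jacobian")
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  dom <- ev[1L]
  structure(list(multipliers = ev,
                 dominant_magnitude = Mod(dom),
                 dominant_is_real_positive =
                   abs(Im(dom)) < 1e-8 && Re(dom) > 0,
                 map = map, mode = cpg$mode, h = h, jacobian = J),
            class = "floquet")
}

#' @export
print.floquet <- function(x, ...) {
  cat(sprintf("Floquet spectrum (%s map, %s mode):\n", x$map, x$mode))
  for (m in x$multipliers)
    cat(sprintf("  %+.6f %+.6fi  (|.| = %.6f)\n", Re(m), Im(m), Mod(m)))
  cat(sprintf("dominant magnitude %.4f (%sreal positive)\n",
              x$dominant_magnitude,
              if (x$dominant_is_real_positive) "" else "not "))
  invisible(x)
}

#' @export
#' @rdname floquet_multipliers
#' @param x a `"floquet"` object.
#' @param ... unused.
#' @param row.names,optional passed through for S3 compatibility.
as.data.frame.floquet <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  data.frame(mode = x$mode, map = x$map,
             re = Re(x$multipliers), im = Im(x$multipliers),
             magnitude = Mod(x$multipliers))
}

#' Phase response of the walking cycle to an impulse
#'
#' Applies a velocity impulse at a chosen fraction of the step cycle and
#' measures the asymptotic shift of touchdown timing relative to the
#' unperturbed gait.  With phase resetting the oscillator clock is re-anchored
#' to the (shifted) contact events, so the timing shift persists; without
#' resetting the oscillator keeps absolute time and the shift decays to
#' zero.
#'
#' @param cycle a `"limit_cycle"` object.
#' @param walker,cpg model parameters; default to the cycle's.
#' @param perturbation length-2 velocity impulse
#'   `(d dtheta1, d dtheta2)` in rad/s.
#' @param at_phase fraction of the step cycle (0 to 1) at which the impulse
#'   is applied.
#' @param horizon number of strides over which to follow the recovery.
#' @param dt integrator time step.
#' @return An object of class `"prc_sample"`: `phase_shift` (s; the
#'   asymptotic touchdown-time shift), `shifts` (per-touchdown shifts),
#'   `at_phase`, `perturbation`.
#' @export
phase_response <- function(cycle, walker = cycle$walker, cpg = cycle$cpg,
                           perturbation = c(0.05, 0), at_phase = 0.5,
                           horizon = 15L, dt = cycle$dt) {
  stopifnot(length(perturbation) == 2L, at_phase >= 0, at_phase < 1)
  n_steps <- 2L * horizon
  t_kick <- at_phase * cycle$step_period

  run_from <- function(state, phi, n) {
    sim_raw(walker, cpg, n_steps = n, dt = dt, init = state, phi = phi)
  }
  # flow to the kick time (no touchdown expected before it on-cycle)
  pre <- sim_raw(walker, cpg, n_steps = 1L, dt = dt, init = cycle$state,
                 phi = cycle$phi, t_stop = t_kick)
  if (pre$n_touchdowns > 0)
    stop("at_phase places the impulse after the first touchdown")
  st <- pre$final_state
  st[3] <- st[3] + perturbation[1L]
  st[4] <- st[4] + perturbation[2L]
  pert <- run_from(st, pre$final_phi, n_steps)
  base <- run_from(pre$final_state, pre$final_phi, n_steps)
  if (pert$fell) stop("walker fell after the perturbation (",
                      pert$fall_reason, ")")
  n <- min(pert$n_touchdowns, base$n_touchdowns)
  shifts <- pert$td_times[seq_len(n)] - base$td_times[seq_len(n)]
  structure(list(phase_shift = shifts[n], shifts = shifts,
                 at_phase = at_phase, perturbation = perturbation,
                 mode = cpg$mode),
            class = "prc_sample")
}

#' @export
as.data.frame.prc_sample <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(mode = x$mode, at_phase = x$at_phase,
             d_dtheta1 = x$perturbation[1L],
             d_dtheta2 = x$perturbation[2L],
             touchdown = seq_along(x$shifts), shift = x$shifts)
}

#' @export
print.prc_sample <- function(x, ...) {
  cat(sprintf(
    "PRC sample (%s mode): impulse (%g, %g) rad/s at phase %.2f\n",
    x$mode, x$perturbation[1], x$perturbation[2], x$at_phase))
  cat(sprintf("  asymptotic touchdown-time shift: %+.6f s\n", x$phase_shift))
  invisible(x)
}
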