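# Thin internal wrapper around the C++ trial engine with sane defaults.
sim_raw <- function(walker, cpg, xi = 0, noise_mode = 0L, seeds = c(0, 0),
                    n_steps, dt, init, phi, record_every = 0L,
                    refine = TRUE, t_stop = -1, tau_tol = 0,
                    tau_consec = 0L, fall_theta = pi / 2, fall_omega = 50,
                    fall_timeout = 5) {
  cg_simulate_cpp(as_wp_vec(walker), as_cpg_vec(cpg), mode_code(cpg),
                  xi, as.integer(noise_mode), seeds[1], seeds[2],
                  as.integer(n_steps), dt, as.double(init), phi,
                  as.integer(record_every), refine, fall_theta, fall_omega,
                  fall_timeout, t_stop, tau_tol, as.integer(tau_consec))
}

#' Run a stochastic walking trial
#'
#' Integrates the coupled walker + CPG system with Euler-Maruyama at fixed
#' step `dt`, applying the leg-swap collision and the CPG phase update at
#' every detected touchdown, until `n_steps` touchdowns have occurred or the
#' walker falls.  Touchdown times are refined by bisection within the
#' detection step (`refine = TRUE`), removing time-step quantization from
#' the stride intervals.
#'
#' A trial starts on the touchdown section: `initial` is a post-touchdown
#' state and time 0 counts as touchdown number 0.  Stride intervals are the
#' differences between every other touchdown time, so `n_steps` touchdowns
#' give `floor(n_steps / 2)` non-overlapping strides.
#'
#' A fall (stance leg past horizontal, runaway angular velocity, or no
#' touchdown within the timeout) terminates the trial and is reported in the
#' result rather than raising an error.
#'
#' @param walker a [walker_params()] object.
#' @param cpg a [cpg_params()] object; in resetting mode `phi0` must be
#'   calibrated.
#' @param noise a [noise_spec()] object.
#' @param n_steps number of touchdowns (steps) to simulate; 1300 steps give
#'   the standard 650-stride trial.
#' @param dt integrator time step, s.
#' @param initial length-4 post-touchdown initial state, or `NULL` to start
#'   from the noiseless limit cycle (computed via [find_limit_cycle()]).
#' @param phi_init initial oscillator phase; defaults to `cpg$phi0`.
#' @param record if `TRUE`, store a subsampled trajectory.
#' @param record_dt trajectory sampling interval, s.
#' @param refine refine touchdown times by bisection?
#' @return An object of class `"walk_trial"` with elements
#'   `stride_intervals` (s), `step_times` (touchdown times, s, starting at
#'   the implicit touchdown 0), `contact_angles` (stance angle at each
#'   touchdown), `fell`, `fall_reason`, `hip_displacement` (m),
#'   `eps_step` (torque cost of each step cycle), `trajectory` (optional
#'   matrix), and the inputs.
#' @seealso [analysis_window()], [gait_speed()], [dfa()]
#' @examples
#' \donttest{
#' w <- walker_params()
#' cpg <- preset_cpg(0.4, mode = "flip")
#' cyc <- find_limit_cycle(w, cpg, dt = 1e-4)
#' tr <- run_trial(w, cyc$cpg, noise_spec(0), n_steps = 20, dt = 1e-4,
#'                 initial = cyc$state, phi_init = cyc$phi)
#' print(tr)
#' }
#' @export
run_trial <- function(walker, cpg, noise = noise_spec(0), n_steps = 1300L,
                      dt = 1e-5, initial = NULL, phi_init = NULL,
                      record = FALSE, record_dt = 1e-3, refine = TRUE) {
  stopifnot(n_steps >= 2L, dt > 0)
  if (cpg$mode == "resetting" && is.na(cpg$phi0))
    stop("phi0 is not calibrated; run calibrate_phi0() first")
  if (is.null(initial)) {
    cyc <- find_limit_cycle(walker, cpg, dt = dt)
    initial <- cyc$state
    if (is.null(phi_init)) phi_init <- cyc$phi
  }
  if (is.null(phi_init)) {
    if (is.na(cpg$phi0))
      stop("phi_init is required when phi0 is not calibrated")
    phi_init <- cpg$phi0
  }
  record_every <- if (record) max(1L, as.integer(round(record_dt / dt))) else 0L
  nm <- switch(noise$discretization,
               wiener = 0L, per_step = 1L, cycle_hold = 2L)
  res <- sim_raw(walker, cpg, xi = noise$xi, noise_mode = nm,
                 seeds = noise_stream_seeds(noise), n_steps = n_steps,
                 dt = dt, init = initial, phi = phi_init,
                 record_every = record_every, refine = refine)
  k <- res$n_touchdowns
  td <- if (k > 0) res$td_times[seq_len(k)] else numeric(0)
  step_times <- c(0, td)
  strides <- stride_from_touchdowns(step_times)
  out <- structure(list(
    stride_intervals = strides,
    step_times = step_times,
    contact_angles = if (k > 0) res$td_pre[seq_len(k), 1L] else numeric(0),
    n_steps = k,
    fell = res$fell,
    fall_reason = res$fall_reason,
    hip_displacement = res$hip_displacement,
    eps_step = if (k > 0) res$eps_step[seq_len(k)] else numeric(0),
    td_post = res$td_post[seq_len(max(k, 1L)), , drop = FALSE],
    trajectory = res$trajectory,
    final_state = res$final_state,
    final_phi = res$final_phi,
    walker = walker, cpg = cpg, noise = noise, dt = dt,
    initial = initial, phi_init = phi_init
  ), class = "walk_trial")
  if (length(strides) && any(strides < 0.1))
    warning("stride interval(s) shorter than 0.1 s detected; ",
            "possible touchdown chattering")
  out
}

# x(i) = t(2i) - t(2i-2) on the touchdown time sequence (t(0) = 0 included):
# non-overlapping double-step intervals.
stride_from_touchdowns <- function(step_times) {
  n <- length(step_times)
  if (n < 3L) return(numeric(0))
  even <- seq(1L, n, by = 2L) # positions of t(0), t(2), t(4), ...
  diff(step_times[even])
}

#' @export
print.walk_trial <- function(x, ...) {
  cat(sprintf("Walking trial: %d steps (%d strides), mode = %s, xi = %g\n",
              x$n_steps, length(x$stride_intervals), x$cpg$mode,
              x$noise$xi))
  if (x$fell) cat("  FELL:", x$fall_reason, "\n")
  if (length(x$stride_intervals)) {
    cat(sprintf("  stride interval: mean %.4f s, sd %.4g s\n",
                mean(x$stride_intervals), stats::sd(x$stride_intervals)))
    cat(sprintf("  hip displacement: %.2f m in %.1f s\n",
                x$hip_displacement, x$step_times[length(x$step_times)]))
  }
  invisible(x)
}

#' @export
plot.walk_trial <- function(x, which = c("strides", "trajectory"), ...) {
  which <- match.arg(which)
  if (which == "strides") {
    plot(x$stride_intervals, type = "l", xlab = "stride number",
         ylab = "stride interval (s)",
         main = sprintf("%s mode, xi = %g", x$cpg$mode, x$noise$xi), ...)
  } else {
    if (is.null(x$trajectory))
      stop("trial was run without record = TRUE")
    tr <- x$trajectory
    plot(tr[, "t"], tr[, "theta1"], type = "l", xlab = "time (s)",
         ylab = "angle (rad)", ...)
    lines(tr[, "t"], tr[, "theta2"], lty = 2)
    legend("topright", legend = c("theta1", "theta2"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Extract the analysis window of a stride series
#'
#' Drops the first `discard` strides (transient behaviour due to the initial
#' condition) and keeps the next `keep` strides, the window analysed by
#' [dfa()].
#'
#' @param x a `walk_trial` object or a numeric stride-interval series.
#' @param discard number of leading strides to drop.
#' @param keep number of strides to keep after the discard.
#' @return Numeric vector of `keep` stride intervals.
#' @export
analysis_window <- function(x, discard = 150L, keep = 500L) {
  s <- if (inherits(x, "walk_trial")) x$stride_intervals else as.numeric(x)
  n <- length(s)
  if (n < discard + keep)
    stop("need ", discard + keep, " strides (", discard, " discarded + ",
         keep, " analysed) but only ", n, " are available",
         if (n > discard) paste0(" (", n - discard,
                                 " after the discard)") else "")
  s[seq(discard + 1L, discard + keep)]
}

#' Mean gait speed over the analysis window
#'
#' Forward hip displacement divided by elapsed time.  The per-step
#' displacement follows from the contact geometry: successive contact
#' points are `2 l |sin(theta1-)|` apart, with `theta1-` the stance angle
#' at touchdown.
#'
#' @param trial a `walk_trial` object (must not have fallen).
#' @param discard strides to drop from the start of the window.
#' @param keep strides in the window, or `Inf` for all remaining.
#' @return Speed in m/s.
#' @export
gait_speed <- function(trial, discard = 150L, keep = 500L) {
  stopifnot(inherits(trial, "walk_trial"))
  if (trial$fell) stop("cannot estimate gait speed: the trial fell (",
                       trial$fall_reason, ")")
  n_strides <- length(trial$stride_intervals)
  if (is.infinite(keep)) keep <- n_strides - discard
  if (n_strides < discard + keep || keep < 1L)
    stop("trial too short for the requested window")
  l <- trial$walker$l
  step_lo <- 2L * discard + 1L
  step_hi <- 2L * (discard + keep)
  disp <- sum(2 * l * abs(sin(trial$contact_angles[step_lo:step_hi])))
  tspan <- trial$step_times[step_hi + 1L] - trial$step_times[step_lo]
  disp / tspan
}
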