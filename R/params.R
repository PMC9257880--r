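#' Mechanical parameters of the compass-type walker
#'
#' The walker is a planar two-link inverted pendulum: point mass `M` at the
#' hip, one point mass `m` on each leg at distance `b` below the hip, legs of
#' length `l`, gravity `g`.  The defaults are anthropometric values for an
#' adult human.
#'
#' @param M hip (trunk) mass in kg.
#' @param m leg mass in kg.
#' @param l leg length in m.
#' @param b distance of the leg mass from the hip joint in m; must satisfy
#'   `b < l`.
#' @param g gravitational acceleration in m/s^2.
#' @return An object of class `"walker_params"`: a named list of the five
#'   parameters.
#' @examples
#' walker_params()
#' @export
walker_params <- function(M = 50, m = 11, l = 1, b = 0.4, g = 9.8) {
  stopifnot(is.numeric(M), is.numeric(m), is.numeric(l), is.numeric(b),
            is.numeric(g))
  if (any(c(M, m, l, b, g) <= 0))
    stop("all walker parameters must be strictly positive")
  if (b >= l) stop("leg mass offset 'b' must be smaller than leg length 'l'")
  structure(list(M = M, m = m, l = l, b = b, g = g),
            class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("Compass walker: M =", x$M, "kg, m =", x$m, "kg, l =", x$l,
      "m, b =", x$b, "m, g =", x$g, "m/s^2\n")
  invisible(x)
}

as_wp_vec <- function(walker) {
  if (!inherits(walker, "walker_params"))
    stop("'walker' must be a walker_params object")
  c(walker$M, walker$m, walker$l, walker$b, walker$g)
}

#' CPG controller parameters
#'
#' A single phase oscillator with intrinsic frequency `omega` produces
#' sinusoidal feedforward torques `u1 = A1 cos(phi)` at the ankle and
#' `u2 = A2 cos(phi + delta)` at the hip.  At each touchdown the phase is
#' either reset to the constant `phi0` (`mode = "resetting"`) or flipped by
#' half a cycle, `phi - pi` (`mode = "flip"`), which mirrors the torque
#' pattern exactly as the leg-swap mirrors the mechanical state.
#'
#' `phi0` is a derived quantity: the post-touchdown phase of the converged
#' noiseless flip-mode gait (see [calibrate_phi0()]).  It depends on
#' `(A1, A2, delta)` and must be recalibrated whenever they change.
#'
#' @param omega intrinsic oscillator frequency, rad/s.
#' @param A1 ankle torque amplitude, N m (non-negative).
#' @param A2 hip torque amplitude, N m (non-negative).
#' @param delta phase offset of the hip torque relative to the ankle torque,
#'   rad; stored modulo 2 pi.
#' @param phi0 reset phase in `[0, 2 pi)`, or `NA` if not yet calibrated.
#' @param mode `"resetting"` (phase reset to `phi0` at touchdown) or
#'   `"flip"` (phase advanced by `-pi` at touchdown).
#' @return An object of class `"cpg_params"`.
#' @seealso [calibrate_phi0()], [feedforward_torques()]
#' @examples
#' cpg_params(A1 = 4.9, A2 = 10, delta = 0.47)
#' @export
cpg_params <- function(omega = 4.8, A1, A2, delta, phi0 = NA_real_,
                       mode = c("resetting", "flip")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0,
            is.numeric(A1), A1 >= 0, is.numeric(A2), A2 >= 0,
            is.numeric(delta), length(delta) == 1L)
  if (!is.na(phi0)) phi0 <- wrap_phase(phi0)
  structure(list(omega = omega, A1 = A1, A2 = A2,
                 delta = wrap_phase(delta), phi0 = phi0, mode = mode),
            class = "cpg_params")
}

#' @export
print.cpg_params <- function(x, ...) {
  cat(sprintf(
    "CPG: omega = %g rad/s, A1 = %g, A2 = %g N m, delta = %g rad, mode = %s\n",
    x$omega, x$A1, x$A2, x$delta, x$mode))
  if (is.na(x$phi0)) cat("phi0: not calibrated\n")
  else cat(sprintf("phi0 = %.8f rad\n", x$phi0))
  invisible(x)
}

as_cpg_vec <- function(cpg) {
  if (!inherits(cpg, "cpg_params")) stop("'cpg' must be a cpg_params object")
  c(cpg$omega, cpg$A1, cpg$A2, cpg$delta,
    if (is.na(cpg$phi0)) 0 else cpg$phi0)
}

mode_code <- function(cpg) if (cpg$mode == "resetting") 0L else 1L

#' Joint torque noise specification
#'
#' Additive Gaussian torque noise `sigma_i = xi U_i` on each joint, with
#' `U_1`, `U_2` independent unit-variance streams.  Three discretizations
#' of the stochastic forcing are available:
#'
#' * `"cycle_hold"` (default): `U_i` is drawn once at the start of each
#'   step cycle and held constant until the next touchdown, i.e. a fresh
#'   motor-command error per movement with standard deviation `xi` N m.
#'   This reading reproduces the reference stride-interval variability
#'   (sd about 0.03 s at `xi = 1`, `v = 0.4` m/s) and keeps both reset
#'   modes walking for `xi <= 1`.
#' * `"wiener"`: SDE white noise; the Euler-Maruyama velocity update
#'   receives `xi * sqrt(dt) * N(0,1)` per joint channel per integrator
#'   step (through the inverse mass matrix).
#' * `"per_step"`: a unit-variance draw scaled by `dt` per integrator
#'   step; effective amplitude smaller by `sqrt(dt)` than `"wiener"`,
#'   retained for comparison only.
#'
#' Two independent deterministic Gaussian streams are derived from `seed`,
#' so a trial is exactly reproducible from `(seed, xi)` on any platform.
#'
#' @param xi noise amplitude (N m under `"cycle_hold"`; N m per sqrt(s)
#'   under `"wiener"`).
#' @param seed non-negative integer seed for the two noise streams.
#' @param discretization `"cycle_hold"`, `"wiener"` or `"per_step"`.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(xi = 0, seed = 1L,
                       discretization = c("cycle_hold", "wiener",
                                          "per_step")) {
  discretization <- match.arg(discretization)
  stopifnot(is.numeric(xi), length(xi) == 1L, xi >= 0,
            is.numeric(seed), length(seed) == 1L, seed >= 0)
  structure(list(xi = xi, seed = as.double(seed),
                 discretization = discretization),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Torque noise: xi = %g (%s discretization), seed = %.0f\n",
              x$xi, x$discretization, x$seed))
  invisible(x)
}

# Seeds for the two independent C++ Gaussian streams.  Offsetting the second
# stream by 2^32 keeps both inside the exactly-representable double range
# while guaranteeing distinct splitmix64 states.
noise_stream_seeds <- function(noise) {
  c(noise$seed, noise$seed + 4294967296)
}

#' Walker state vector
#'
#' Convenience constructor for the instantaneous mechanical state:
#' stance-leg angle `theta1` (rad, from vertical), inter-leg angle `theta2`
#' (rad), and their time derivatives (rad/s).
#'
#' @param theta1,theta2,dtheta1,dtheta2 numeric scalars.
#' @return A named numeric vector of length 4.
#' @export
walker_state <- function(theta1, theta2, dtheta1, dtheta2) {
  x <- c(theta1 = theta1, theta2 = theta2,
         dtheta1 = dtheta1, dtheta2 = dtheta2)
  if (!all(is.finite(x))) stop("walker state must be finite")
  x
}

wrap_phase <- function(phi) {
  phi <- phi %% (2 * pi)
  phi
}

#' Reference energy-optimal gait parameter sets
#'
#' The energy-optimal `(A1, A2, delta)` sets for gait speeds 0.3, 0.4 and
#' 0.5 m/s used throughout the package's replication experiments.  These are
#' the published optima for this model family; [optimize_for_speed()]
#' recomputes such sets from scratch by grid search.
#'
#' @return A data frame with columns `v`, `A1`, `A2`, `delta`.
#' @export
gait_presets <- function() {
  data.frame(v = c(0.3, 0.4, 0.5),
             A1 = c(1.3, 4.9, 14),
             A2 = c(6.1, 10, 15),
             delta = c(0.57, 0.47, 0.37))
}

#' CPG parameters for a preset gait speed
#'
#' Looks up the reference parameter set for one of the speeds in
#' [gait_presets()] and returns a [cpg_params()] object in the requested
#' mode (without a calibrated `phi0`; see [calibrate_phi0()]).
#'
#' @param v gait speed, one of 0.3, 0.4, 0.5 m/s.
#' @param mode reset mode, `"resetting"` or `"flip"`.
#' @param omega oscillator frequency, rad/s.
#' @return A `cpg_params` object.
#' @export
preset_cpg <- function(v = 0.4, mode = c("resetting", "flip"), omega = 4.8) {
  p <- gait_presets()
  i <- match(v, p$v)
  if (is.na(i)) stop("no preset for v = ", v,
                     "; available: ", paste(p$v, collapse = ", "))
  cpg_params(omega = omega, A1 = p$A1[i], A2 = p$A2[i], delta = p$delta[i],
             mode = match.arg(mode))
}
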