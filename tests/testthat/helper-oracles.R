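# Independent oracles, derived from the position-level model only (hip at
# l*(sin th1, cos th1) from the stance contact; leg masses at distance b
# below the hip on each leg).  These share no code with the package's
# closed-form dynamics.

oracle_positions <- function(q, p) {
  th1 <- q[1]; th2 <- q[2]
  hip <- p$l * c(sin(th1), cos(th1))
  m1 <- (p$l - p$b) * c(sin(th1), cos(th1))          # stance-leg mass
  m2 <- hip - p$b * c(sin(th1 - th2), cos(th1 - th2)) # swing-leg mass
  list(hip = hip, m1 = m1, m2 = m2)
}

# Jacobian of a mass position w.r.t. q by central differences.
oracle_jac <- function(fun, q, p, h = 1e-5) {
  vapply(1:2, function(j) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    (fun(qp, p) - fun(qm, p)) / (2 * h)
  }, numeric(2))
}

oracle_mass_matrix <- function(q, p) {
  Jh <- oracle_jac(function(q, p) oracle_positions(q, p)$hip, q, p)
  J1 <- oracle_jac(function(q, p) oracle_positions(q, p)$m1, q, p)
  J2 <- oracle_jac(function(q, p) oracle_positions(q, p)$m2, q, p)
  p$M * crossprod(Jh) + p$m * crossprod(J1) + p$m * crossprod(J2)
}

oracle_potential <- function(q, p) {
  pos <- oracle_positions(q, p)
  p$g * (p$M * pos$hip[2] + p$m * pos$m1[2] + p$m * pos$m2[2])
}

oracle_energy <- function(state, p) {
  state <- unname(state)
  q <- state[1:2]; qd <- state[3:4]
  0.5 * drop(t(qd) %*% oracle_mass_matrix(q, p) %*% qd) +
    oracle_potential(q, p)
}

# Accelerations from the Lagrangian in numeric form:
# M qdd + Mdot qd - (1/2) d/dq (qd' M qd) + dV/dq = u.
oracle_accel <- function(state, torques, p, h = 1e-5) {
  q <- state[1:2]; qd <- state[3:4]
  M <- oracle_mass_matrix(q, p)
  dM <- lapply(1:2, function(j) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    (oracle_mass_matrix(qp, p) - oracle_mass_matrix(qm, p)) / (2 * h)
  })
  Mdot <- dM[[1]] * qd[1] + dM[[2]] * qd[2]
  dT <- vapply(1:2, function(j)
    0.5 * drop(t(qd) %*% dM[[j]] %*% qd), numeric(1))
  dV <- vapply(1:2, function(j) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    (oracle_potential(qp, p) - oracle_potential(qm, p)) / (2 * h)
  }, numeric(1))
  drop(solve(M, torques - Mdot %*% qd + dT - dV))
}

# Touchdown collision from conservation laws: angular momentum of the whole
# walker about the new contact point, and of the trailing (old stance) leg
# about the hip, are conserved through the impact.
oracle_collision <- function(state, p) {
  a <- state[1]; w <- state[3:4]
  sa <- sin(a); ca <- cos(a)
  cross2 <- function(r, v) r[1] * v[2] - r[2] * v[1]
  pH <- p$l * c(sa, ca)
  p1 <- (p$l - p$b) * c(sa, ca)
  p2 <- c((p$l + p$b) * sa, (p$l - p$b) * ca)
  pc <- c(2 * p$l * sa, 0)
  vH <- p$l * w[1] * c(ca, -sa)
  v1 <- (p$l - p$b) * w[1] * c(ca, -sa)
  v2 <- vH - p$b * (w[1] - w[2]) * c(ca, sa)
  Lpre <- p$M * cross2(pH - pc, vH) + p$m * cross2(p1 - pc, v1) +
    p$m * cross2(p2 - pc, v2)
  Hpre <- p$m * cross2(p1 - pH, v1)
  A <- matrix(0, 2, 2)
  for (k in 1:2) {
    n <- c(0, 0); n[k] <- 1
    vHp <- p$l * n[1] * c(ca, sa)
    v2p <- (p$l - p$b) * n[1] * c(ca, sa)
    v1p <- vHp - p$b * (n[1] - n[2]) * c(ca, -sa)
    A[1, k] <- p$M * cross2(pH - pc, vHp) + p$m * cross2(p2 - pc, v2p) +
      p$m * cross2(p1 - pc, v1p)
    A[2, k] <- p$m * cross2(p1 - pH, v1p)
  }
  wp <- solve(A, c(Lpre, Hpre))
  unname(c(-state[1], -state[2], wp))
}

# Kinetic energy only (for impact-loss checks).
oracle_kinetic <- function(state, p) {
  state <- unname(state)
  q <- state[1:2]; qd <- state[3:4]
  0.5 * drop(t(qd) %*% oracle_mass_matrix(q, p) %*% qd)
}

# Brute-force DFA fluctuation via explicit per-segment regression.
oracle_fluctuation <- function(y, n) {
  k <- length(y) %/% n
  tot <- 0
  for (j in seq_len(k)) {
    seg <- y[((j - 1) * n + 1):(j * n)]
    s <- seq_len(n)
    fit <- stats::lm(seg ~ s)
    tot <- tot + mean(stats::residuals(fit)^2)
  }
  sqrt(tot / k)
}

# Shared fixtures (memoized across test files).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- compute()
  .fixtures[[name]]
}

v04_cycle <- function(dt = 1e-4) {
  fixture(paste0("cycle_", dt), function() {
    find_limit_cycle(walker_params(), preset_cpg(0.4, mode = "flip"),
                     dt = dt)
  })
}

v04_reset_cpg <- function(dt = 1e-4) {
  cyc <- v04_cycle(dt)
  cpg_params(A1 = 4.9, A2 = 10, delta = 0.47, phi0 = cyc$cpg$phi0,
             mode = "resetting")
}
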