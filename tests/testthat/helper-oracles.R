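# Independent oracles the unit and property tests compare the package
# against. Each is deliberately implemented by a different route than the
# code it checks.

# Standard bivariate normal lower quadrant mass P(X <= h, Y <= k) by the
# Plackett reduction to a one-dimensional integral over the correlation,
# evaluated with adaptive quadrature (independent of the package's CDF
# routine).
oracle_bvn_lower <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  integrand <- function(r) {
    exp(-(h^2 - 2 * h * k * r + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  pnorm(h) * pnorm(k) +
    stats::integrate(integrand, 0, rho, rel.tol = 1e-12,
                     abs.tol = 1e-13)$value
}

# 2x2 cell probabilities of the dichotomized latent bivariate normal,
# built entirely from the Plackett oracle
oracle_latent_cells <- function(p1_dot, p_dot1, rho) {
  h <- qnorm(1 - p1_dot)
  k <- qnorm(1 - p_dot1)
  p00 <- oracle_bvn_lower(h, k, rho)
  c(p00 = p00, p01 = (1 - p1_dot) - p00, p10 = (1 - p_dot1) - p00,
    p11 = p1_dot + p_dot1 - 1 + p00)
}

# Monte-Carlo estimate of the latent-normal cell probabilities from raw
# bivariate normal draws (no CDF at all)
oracle_latent_cells_mc <- function(p1_dot, p_dot1, rho, n = 1e6) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  s <- z1 > qnorm(1 - p1_dot)
  l <- z2 > qnorm(1 - p_dot1)
  c(p00 = mean(!s & !l), p01 = mean(!s & l), p10 = mean(s & !l),
    p11 = mean(s & l))
}

# Attainable phi range for fixed marginals by scanning every valid 2x2
# table: p11 ranges over [max(0, a + b - 1), min(a, b)] and phi is computed
# cell-wise on a fine grid
oracle_phi_range <- function(p1_dot, p_dot1, resolution = 1e-4) {
  lo <- max(0, p1_dot + p_dot1 - 1)
  hi <- min(p1_dot, p_dot1)
  p11 <- seq(lo, hi, by = resolution * (hi - lo))
  phi <- (p11 - p1_dot * p_dot1) /
    sqrt(p1_dot * (1 - p1_dot) * p_dot1 * (1 - p_dot1))
  range(phi)
}

# Monte-Carlo oracle for P(pi_E > pi_S + delta) from paired Beta draws
oracle_prob_exceeds_mc <- function(ae, be, as_, bs, delta, n = 1e6) {
  mean(rbeta(n, ae, be) > rbeta(n, as_, bs) + delta)
}

# Adaptive-quadrature route for P(pi_E > pi_S + delta), independent of the
# package's fixed-order Gauss-Legendre rule
oracle_prob_exceeds_quad <- function(ae, be, as_, bs, delta) {
  f <- function(u) {
    dbeta(u, as_, bs) * pbeta(u + delta, ae, be, lower.tail = FALSE)
  }
  stats::integrate(f, 0, 1 - delta, rel.tol = 1e-11, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# Brute-force recomputation of the control pool used at an analysis, from a
# replicate's participant ledger (naive filtering, no incremental counters)
oracle_control_pool <- function(participants, cohorts, cohort, week, lag,
                                cohort_size, concurrent) {
  own <- participants[participants$cohort == cohort &
                        participants$arm == "control" &
                        participants$enrollment_week + lag <= week, ]
  n <- nrow(own); s1 <- sum(own$s); s2 <- sum(own$l)
  if (concurrent) {
    mine <- participants[participants$cohort == cohort, ]
    first_w <- min(mine$enrollment_week)
    enrolled_before <- sum(mine$enrollment_week < week)
    enrolling <- enrolled_before < cohort_size
    win_hi <- if (enrolling) week else max(mine$enrollment_week)
    others <- participants[participants$cohort != cohort &
                             participants$arm == "control" &
                             participants$enrollment_week >= first_w &
                             participants$enrollment_week <= win_hi &
                             participants$enrollment_week + lag <= week, ]
    n <- n + nrow(others); s1 <- s1 + sum(others$s); s2 <- s2 + sum(others$l)
  }
  c(n = n, s1 = s1, s2 = s2)
}
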