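# Bivariate Bernoulli outcome distributions for the two binary co-primary
# endpoints: S = resolution of NASH without worsening of fibrosis (endpoint 1),
# L = >= 1-stage fibrosis improvement without worsening of NASH (endpoint 2).
# A distribution is fully described by the 2x2 cell table (p00, p01, p10, p11),
# indexed (S, L).

# tolerance for clipping cell probabilities that land epsilon outside [0, 1]
.CELL_TOL <- 1e-12

.clip_cell <- function(p, what) {
  bad <- p < -.CELL_TOL | p > 1 + .CELL_TOL
  if (any(bad)) {
    stop(sprintf("%s out of [0, 1]: %s", what,
                 paste(format(p[bad], digits = 10), collapse = ", ")),
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

new_joint_spec <- function(p00, p01, p10, p11) {
  p00 <- .clip_cell(p00, "p00")
  p01 <- .clip_cell(p01, "p01")
  p10 <- .clip_cell(p10, "p10")
  p11 <- .clip_cell(p11, "p11")
  s <- p00 + p01 + p10 + p11
  if (abs(s - 1) > 1e-12) {
    stop(sprintf("cell probabilities must sum to 1 (got %.15f)", s),
         call. = FALSE)
  }
  structure(
    list(p00 = p00, p01 = p01, p10 = p10, p11 = p11),
    class = "joint_bernoulli_spec"
  )
}

#' Marginal success probabilities of a joint Bernoulli specification
#'
#' @param spec A `joint_bernoulli_spec`.
#' @return Named numeric vector with `p1_dot` (marginal success probability
#'   of endpoint S) and `p_dot1` (marginal success probability of endpoint L).
#' @export
marginals_of <- function(spec) {
  stopifnot(inherits(spec, "joint_bernoulli_spec"))
  c(p1_dot = spec$p10 + spec$p11, p_dot1 = spec$p01 + spec$p11)
}

#' @export
print.joint_bernoulli_spec <- function(x, ...) {
  m <- marginals_of(x)
  cat("Bivariate Bernoulli distribution (rows S, cols L)\n")
  tab <- matrix(c(x$p00, x$p01, x$p10, x$p11), 2, 2, byrow = TRUE,
                dimnames = list(c("S=0", "S=1"), c("L=0", "L=1")))
  print(round(tab, 6))
  cat(sprintf("marginals: p1. = %.6f, p.1 = %.6f", m[1], m[2]))
  phi <- tryCatch(phi_of(x), error = function(e) NA_real_)
  if (!is.na(phi)) cat(sprintf(", phi = %.6f", phi))
  cat("\n")
  invisible(x)
}

#' Joint Bernoulli distribution from three cell probabilities
#'
#' Fixes `p00`, `p10` and `p01` directly; the double-success cell follows as
#' `p11 = 1 - (p00 + p10 + p01)`.
#'
#' @param p00,p10,p01 Cell probabilities, each in `[0, 1]` with sum at most 1.
#' @return A `joint_bernoulli_spec`.
#' @seealso [joint_spec_sens_spec()], [joint_spec_phi()], [joint_spec_latent()]
#' @examples
#' joint_spec_direct(0.42, 0.18, 0.28)
#' @export
joint_spec_direct <- function(p00, p10, p01) {
  for (nm in c("p00", "p10", "p01")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  if (p00 + p10 + p01 > 1 + .CELL_TOL) {
    stop(sprintf("p00 + p10 + p01 must not exceed 1 (got %.15f)",
                 p00 + p10 + p01), call. = FALSE)
  }
  new_joint_spec(p00, p01, p10, max(0, 1 - (p00 + p10 + p01)))
}

#' Joint Bernoulli distribution from a marginal plus sensitivity/specificity
#'
#' Specifies the marginal success probability of the S endpoint together with
#' the sensitivity and specificity of S in predicting L:
#' `p11 = sens_SL * p1_dot` and `p00 = spec_SL * (1 - p1_dot)`. Any triplet of
#' values in `[0, 1]` yields a valid table.
#'
#' @param p1_dot Marginal success probability of endpoint S.
#' @param sens_SL Sensitivity of S in predicting L, `P(L = 1 | S = 1)`
#'   reparameterized via `p11 / p1_dot`.
#' @param spec_SL Specificity of S in predicting L, `p00 / p0_dot`.
#' @return A `joint_bernoulli_spec`.
#' @examples
#' joint_spec_sens_spec(0.5, 0.8, 0.9)
#' @export
joint_spec_sens_spec <- function(p1_dot, sens_SL, spec_SL) {
  for (nm in c("p1_dot", "sens_SL", "spec_SL")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  p11 <- sens_SL * p1_dot
  p00 <- spec_SL * (1 - p1_dot)
  p10 <- p1_dot - p11
  p01 <- (1 - p1_dot) - p00
  new_joint_spec(p00, p01, p10, p11)
}

#' Attainable range of the phi correlation for fixed marginals
#'
#' For two Bernoulli variables with fixed marginal success probabilities the
#' Pearson phi coefficient cannot be chosen freely; it is bounded below by
#' `max(-sqrt(p1.p.1/((1-p1.)(1-p.1))), -sqrt((1-p1.)(1-p.1)/(p1.p.1)))`
#' and above by
#' `min(sqrt(p1.(1-p.1)/((1-p1.)p.1)), sqrt((1-p1.)p.1/(p1.(1-p.1))))`.
#'
#' @param p1_dot,p_dot1 Marginal success probabilities, strictly inside (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' phi_bounds(0.3, 0.4)
#' @export
phi_bounds <- function(p1_dot, p_dot1) {
  for (nm in c("p1_dot", "p_dot1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie strictly inside (0, 1); the phi bounds degenerate at 0 or 1",
                   nm), call. = FALSE)
    }
  }
  a <- p1_dot * p_dot1
  b <- (1 - p1_dot) * (1 - p_dot1)
  cc <- p1_dot * (1 - p_dot1)
  d <- (1 - p1_dot) * p_dot1
  lower <- max(-sqrt(a / b), -sqrt(b / a))
  upper <- min(sqrt(cc / d), sqrt(d / cc))
  c(lower = lower, upper = upper)
}

#' Joint Bernoulli distribution from marginals and a phi correlation
#'
#' Specifies both marginal success probabilities and the Pearson phi
#' correlation of the two binary endpoints:
#' `p11 = phi * sqrt(p0. p1. p.0 p.1) + p1. p.1`, with the remaining cells
#' from the marginals. `phi` must lie within [phi_bounds()] for the marginals.
#'
#' @param p1_dot,p_dot1 Marginal success probabilities, strictly inside (0, 1).
#' @param phi Pearson correlation of the two binary endpoints.
#' @return A `joint_bernoulli_spec` with the requested marginals and phi.
#' @examples
#' joint_spec_phi(0.3, 0.4, 0.7)
#' @export
joint_spec_phi <- function(p1_dot, p_dot1, phi) {
  bounds <- phi_bounds(p1_dot, p_dot1)
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi)) {
    stop("`phi` must be a single numeric value", call. = FALSE)
  }
  if (phi < bounds[1] - .CELL_TOL || phi > bounds[2] + .CELL_TOL) {
    stop(sprintf(paste0(
      "phi = %.6f is not attainable for marginals (p1. = %g, p.1 = %g); ",
      "the attainable interval is [%.6f, %.6f]"),
      phi, p1_dot, p_dot1, bounds[1], bounds[2]), call. = FALSE)
  }
  p11 <- phi * sqrt(p1_dot * (1 - p1_dot) * p_dot1 * (1 - p_dot1)) +
    p1_dot * p_dot1
  p01 <- p_dot1 - p11
  p10 <- p1_dot - p11
  p00 <- 1 - (p11 + p01 + p10)
  new_joint_spec(p00, p01, p10, p11)
}

#' Joint Bernoulli distribution from a dichotomized latent bivariate normal
#'
#' Generates the 2x2 table by thresholding a standard bivariate normal with
#' latent correlation `rho`: each endpoint succeeds when its latent variable
#' exceeds the standard-normal quantile of its failure probability, so the
#' requested marginals are preserved exactly. The double-failure cell is the
#' lower quadrant mass `Phi2(qnorm(1 - p1_dot), qnorm(1 - p_dot1); rho)`;
#' the remaining cells follow by inclusion-exclusion from the marginals.
#'
#' @param p1_dot,p_dot1 Marginal success probabilities, strictly inside (0, 1).
#' @param rho Latent bivariate-normal correlation in (-1, 1).
#' @return A `joint_bernoulli_spec`.
#' @examples
#' joint_spec_latent(0.3, 0.4, 0.7)
#' @export
joint_spec_latent <- function(p1_dot, p_dot1, rho) {
  for (nm in c("p1_dot", "p_dot1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie strictly inside (0, 1)", nm), call. = FALSE)
    }
  }
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) ||
      rho <= -1 || rho >= 1) {
    stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  p00 <- .bvn_lower(stats::qnorm(1 - p1_dot), stats::qnorm(1 - p_dot1), rho)
  p01 <- (1 - p1_dot) - p00
  p10 <- (1 - p_dot1) - p00
  p11 <- p1_dot + p_dot1 - 1 + p00
  new_joint_spec(p00, p01, p10, p11)
}

# standard bivariate normal lower quadrant mass P(X <= h, Y <= k), corr rho
.bvn_lower <- function(h, k, rho) {
  v <- mvtnorm::pmvnorm(
    lower = c(-Inf, -Inf), upper = c(h, k),
    corr = matrix(c(1, rho, rho, 1), 2, 2),
    algorithm = mvtnorm::GenzBretz(abseps = 1e-10)
  )
  as.numeric(v)
}

#' Pearson phi correlation of a joint Bernoulli specification
#'
#' `phi = (p11 - p1. p.1) / sqrt(p0. p1. p.0 p.1)`; zero exactly when the two
#' endpoints are independent.
#'
#' @param spec A `joint_bernoulli_spec` with non-degenerate marginals.
#' @return Correlation in `[-1, 1]`.
#' @export
phi_of <- function(spec) {
  stopifnot(inherits(spec, "joint_bernoulli_spec"))
  m <- marginals_of(spec)
  if (any(m <= 0) || any(m >= 1)) {
    stop("phi is undefined for degenerate marginals (0 or 1)", call. = FALSE)
  }
  (spec$p11 - m[[1]] * m[[2]]) /
    sqrt(m[[1]] * (1 - m[[1]]) * m[[2]] * (1 - m[[2]]))
}

#' Diagnostic profile of a joint Bernoulli specification
#'
#' Conditional proportions describing how well one endpoint predicts the
#' other: `sens_SL = p11/p1.`, `spec_SL = p00/p0.`, `sens_LS = p11/p.1`,
#' `spec_LS = p00/p.0`, plus the phi correlation.
#'
#' @param spec A `joint_bernoulli_spec`; every marginal entering a requested
#'   ratio must be nonzero.
#' @return Named list with `sens_SL`, `spec_SL`, `sens_LS`, `spec_LS`, `phi`.
#' @export
diagnostics_of <- function(spec) {
  stopifnot(inherits(spec, "joint_bernoulli_spec"))
  m <- marginals_of(spec)
  p1d <- m[[1]]; pd1 <- m[[2]]
  ratio <- function(num, den, what) {
    if (den <= 0) {
      stop(sprintf("%s is undefined: its conditioning marginal is zero", what),
           call. = FALSE)
    }
    num / den
  }
  list(
    sens_SL = ratio(spec$p11, p1d, "sens_SL"),
    spec_SL = ratio(spec$p00, 1 - p1d, "spec_SL"),
    sens_LS = ratio(spec$p11, pd1, "sens_LS"),
    spec_LS = ratio(spec$p00, 1 - pd1, "spec_LS"),
    phi = phi_of(spec)
  )
}

#' Phi correlation achieved by a latent-normal correlation
#'
#' Maps the latent bivariate-normal correlation `rho` to the phi correlation
#' of the dichotomized binary endpoints for given marginals. The map is
#' monotone in `rho`, sends 0 to 0, and its range is contained in
#' [phi_bounds()]; it reaches the full interval `[0, 1]` only when
#' `p1_dot = p_dot1 = 0.5`.
#'
#' @inheritParams joint_spec_latent
#' @return The achieved phi correlation.
#' @examples
#' rho_to_phi(0.3, 0.4, 0.7)
#' @export
rho_to_phi <- function(p1_dot, p_dot1, rho) {
  phi_of(joint_spec_latent(p1_dot, p_dot1, rho))
}

#' Sample correlated binary endpoint pairs
#'
#' Draws `n` i.i.d. `(s, l)` pairs from the four-cell distribution of `spec`
#' (one multinomial draw per participant), using R's global random number
#' stream.
#'
#' @param spec A `joint_bernoulli_spec`.
#' @param n Number of participants to draw.
#' @return Integer matrix with `n` rows and columns `s`, `l`.
#' @examples
#' set.seed(1)
#' colMeans(sample_joint(joint_spec_latent(0.3, 0.4, 0.7), 1000))
#' @export
sample_joint <- function(spec, n) {
  stopifnot(inherits(spec, "joint_bernoulli_spec"),
            is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  if (n == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("s", "l"))))
  }
  # cells in order (s, l): (0,0), (0,1), (1,0), (1,1)
  cell <- sample.int(4L, n, replace = TRUE,
                     prob = c(spec$p00, spec$p01, spec$p10, spec$p11))
  cbind(s = as.integer(cell >= 3L), l = as.integer(cell %% 2L == 0L))
}
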