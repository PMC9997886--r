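# Conjugate Beta machinery behind every decision probability: the posterior
# for a response rate after binomial data, its upper-tail probability, and the
# probability that one arm's rate exceeds the other's by at least a margin.

#' Beta distribution over a response rate
#'
#' @param alpha,beta Positive shape parameters. Non-integer values are
#'   permitted (an observed response rate of 0.5 with n = 75 updates a flat
#'   prior to Beta(38.5, 38.5)).
#' @return A `beta_posterior`.
#' @examples
#' beta_posterior(1, 1) # flat prior
#' @export
beta_posterior <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0 ||
      !is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta <= 0) {
    stop("`alpha` and `beta` must be positive scalars", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) [mean %.4f]\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Binomial counts for one arm and one endpoint
#'
#' @param successes Number of responders, `0 <= successes <= n`. Half-integer
#'   values are accepted so that a stated observed response rate can be
#'   combined with an odd sample size.
#' @param n Number of participants with observed outcomes.
#' @return An `arm_counts`.
#' @export
arm_counts <- function(successes, n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 ||
      !is.numeric(successes) || length(successes) != 1 || is.na(successes) ||
      successes < 0 || successes > n) {
    stop("need 0 <= successes <= n with n >= 0", call. = FALSE)
  }
  structure(list(successes = successes, n = n), class = "arm_counts")
}

#' Conjugate update of a Beta prior with binomial counts
#'
#' @param prior A `beta_posterior`.
#' @param counts An `arm_counts`.
#' @return `beta_posterior` with `alpha + successes`, `beta + (n - successes)`.
#' @examples
#' update_posterior(beta_posterior(1, 1), arm_counts(37.5, 75))
#' @export
update_posterior <- function(prior, counts) {
  stopifnot(inherits(prior, "beta_posterior"), inherits(counts, "arm_counts"))
  beta_posterior(prior$alpha + counts$successes,
                 prior$beta + (counts$n - counts$successes))
}

#' Posterior probability that a response rate reaches a threshold
#'
#' @param post A `beta_posterior`.
#' @param threshold Response-rate threshold in `[0, 1]`.
#' @return `P(pi >= threshold)` under `post`.
#' @examples
#' post <- update_posterior(beta_posterior(1, 1), arm_counts(37.5, 75))
#' prob_tail(post, 0.45)
#' @export
prob_tail <- function(post, threshold) {
  stopifnot(inherits(post, "beta_posterior"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a probability in [0, 1]", call. = FALSE)
  }
  stats::pbeta(threshold, post$alpha, post$beta, lower.tail = FALSE)
}

# Gauss-Legendre nodes/weights on [0, 1], computed once per order
.gl_env <- new.env(parent = emptyenv())
.gl_rule <- function(order = 256L) {
  key <- as.character(order)
  rule <- .gl_env[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(order, 0, 1)
    .gl_env[[key]] <- rule
  }
  rule
}

# memo cache for prob_exceeds_by keyed on the five parameters
.pe_cache <- new.env(parent = emptyenv(), hash = TRUE)

#' Clear the memoization cache of [prob_exceeds_by()]
#' @return Invisibly, the number of entries removed.
#' @export
clear_posterior_cache <- function() {
  n <- length(ls(.pe_cache, all.names = TRUE))
  rm(list = ls(.pe_cache, all.names = TRUE), envir = .pe_cache)
  invisible(n)
}

#' Posterior probability that one rate exceeds another by a margin
#'
#' For independent posteriors `pi_E ~ post_e` and `pi_S ~ post_s` computes
#' `P(pi_E > pi_S + delta)` by Gauss-Legendre quadrature of
#' `integral f_S(u) * (1 - F_E(u + delta)) du` over the effective support of
#' `f_S` intersected with `[0, 1 - delta]`, to absolute error well below 1e-6.
#' This single quantity drives every efficacy and futility gate of the
#' decision rules.
#'
#' @param post_e,post_s `beta_posterior` objects for the experimental and
#'   control (standard-of-care) arms.
#' @param delta Margin in `[0, 1]` by which `pi_E` must exceed `pi_S`.
#' @param cache Memoize on `(alpha_e, beta_e, alpha_s, beta_s, delta)`?
#'   Decisions are pure functions of counts, so caching is sound and makes
#'   large replicate runs fast.
#' @return The posterior probability.
#' @examples
#' post_e <- update_posterior(beta_posterior(), arm_counts(38, 75))
#' post_s <- update_posterior(beta_posterior(), arm_counts(8, 75))
#' prob_exceeds_by(post_e, post_s, delta = 0.25)
#' @export
prob_exceeds_by <- function(post_e, post_s, delta = 0, cache = TRUE) {
  stopifnot(inherits(post_e, "beta_posterior"),
            inherits(post_s, "beta_posterior"))
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1) {
    stop("`delta` must be a margin in [0, 1]", call. = FALSE)
  }
  if (cache) {
    key <- paste(post_e$alpha, post_e$beta, post_s$alpha, post_s$beta, delta,
                 sep = "|")
    hit <- .pe_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- .prob_exceeds_quad(post_e$alpha, post_e$beta,
                            post_s$alpha, post_s$beta, delta)
  if (cache) .pe_cache[[key]] <- val
  val
}

.prob_exceeds_quad <- function(ae, be, as_, bs, delta) {
  if (delta >= 1) return(0)
  # integrand vanishes for u > 1 - delta (pi_E cannot exceed 1)
  lo <- max(0, stats::qbeta(1e-14, as_, bs))
  hi <- min(1 - delta, stats::qbeta(1e-14, as_, bs, lower.tail = FALSE))
  if (hi <= lo) {
    # essentially all control mass sits above 1 - delta
    return(stats::pbeta(1 - delta, as_, bs) *
             stats::pbeta(lo + delta, ae, be, lower.tail = FALSE))
  }
  rule <- .gl_rule(256L)
  u <- lo + (hi - lo) * rule$x
  w <- (hi - lo) * rule$w
  val <- sum(w * stats::dbeta(u, as_, bs) *
               stats::pbeta(u + delta, ae, be, lower.tail = FALSE))
  min(max(val, 0), 1)
}
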