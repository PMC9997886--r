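# Multi-level Bayesian efficacy and futility gates. Per endpoint, efficacy is
# a conjunction of evidence levels (delta_l, gamma_l): declare the endpoint
# efficacious when P(pi_E > pi_S + delta_l) > gamma_l for every required
# level. Futility at an interim: P(pi_E > pi_S + delta_F) < gamma_F. The two
# endpoints combine under the FDA rule: graduate if EITHER endpoint is
# efficacious; drop at interim only if BOTH endpoints are futile. At the
# final analysis a cohort that does not graduate stops for futility.

#' One evidence level of the multi-level efficacy rule
#'
#' @param delta Margin in `[0, 1]` on the response-rate difference.
#' @param gamma Required posterior confidence in `(0, 1]`.
#' @return An `evidence_level`.
#' @export
evidence_level <- function(delta, gamma) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1) {
    stop("`delta` must be a margin in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma <= 0 || gamma > 1) {
    stop("`gamma` must be a confidence in (0, 1]", call. = FALSE)
  }
  structure(list(delta = delta, gamma = gamma), class = "evidence_level")
}

#' Interim futility gate for one endpoint
#'
#' A cohort's endpoint is flagged futile at interim analysis `T` when
#' `P(pi_E > pi_S + delta) < gamma_by_analysis[T]`. No futility gate exists
#' at the final analysis: failing efficacy there is itself futility.
#'
#' @param delta Futility margin in `[0, 1]`.
#' @param gamma_by_analysis Confidence thresholds in `[0, 1)`, one per interim
#'   analysis, in analysis order.
#' @return A `futility_gate`.
#' @export
futility_gate <- function(delta, gamma_by_analysis) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1) {
    stop("futility `delta` must be a margin in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(gamma_by_analysis) || length(gamma_by_analysis) < 1 ||
      anyNA(gamma_by_analysis) ||
      any(gamma_by_analysis < 0 | gamma_by_analysis >= 1)) {
    stop("futility `gamma_by_analysis` must be thresholds in [0, 1)",
         call. = FALSE)
  }
  structure(list(delta = delta, gamma_by_analysis = gamma_by_analysis),
            class = "futility_gate")
}

.validate_levels <- function(levels, endpoint) {
  if (!length(levels) || !all(vapply(levels, inherits, TRUE, "evidence_level"))) {
    stop(sprintf("endpoint %s: `levels` must be a list of evidence_level objects",
                 endpoint), call. = FALSE)
  }
  deltas <- vapply(levels, `[[`, 0, "delta")
  gammas <- vapply(levels, `[[`, 0, "gamma")
  if (length(deltas) > 1 &&
      (any(diff(deltas) <= 0) || any(diff(gammas) >= 0))) {
    stop(sprintf(paste0("endpoint %s: evidence levels must have strictly ",
                        "increasing deltas and strictly decreasing gammas"),
                 endpoint), call. = FALSE)
  }
  invisible(levels)
}

#' Decision rule set for a two-endpoint cohort
#'
#' Bundles, for each endpoint, the list of efficacy evidence levels (applied
#' identically at every analysis) and the interim futility gate, together
#' with the number of evidence levels that must hold simultaneously and the
#' endpoint combiners. The default efficacy combiner is `"any"` (graduate on
#' either endpoint); futility always requires every endpoint
#' (`futility_combiner = "all"`).
#'
#' @param e1_levels,e2_levels Lists of [evidence_level()] per endpoint, with
#'   strictly increasing deltas and strictly decreasing gammas.
#' @param e1_futility,e2_futility [futility_gate()] per endpoint.
#' @param evidence_level_required How many leading evidence levels must hold
#'   (hierarchical: requiring level 3 means levels 1-3 all hold).
#' @param efficacy_combiner `"any"` (FDA OR rule, default) or `"all"`.
#' @param prior Beta prior applied to every arm and endpoint; default flat
#'   `Beta(1, 1)`.
#' @return A `decision_rule_set`.
#' @seealso [default_decision_rules()] for the NASH phase 2b defaults.
#' @export
decision_rule_set <- function(e1_levels, e2_levels,
                              e1_futility, e2_futility,
                              evidence_level_required = 3L,
                              efficacy_combiner = c("any", "all"),
                              prior = beta_posterior(1, 1)) {
  .validate_levels(e1_levels, "1")
  .validate_levels(e2_levels, "2")
  stopifnot(inherits(e1_futility, "futility_gate"),
            inherits(e2_futility, "futility_gate"),
            inherits(prior, "beta_posterior"))
  efficacy_combiner <- match.arg(efficacy_combiner)
  req <- as.integer(evidence_level_required)
  if (is.na(req) || req < 1 ||
      req > min(length(e1_levels), length(e2_levels))) {
    stop("`evidence_level_required` must be between 1 and the number of levels",
         call. = FALSE)
  }
  rules <- structure(
    list(endpoints = list(
           list(levels = e1_levels, futility = e1_futility),
           list(levels = e2_levels, futility = e2_futility)),
         evidence_level_required = req,
         efficacy_combiner = efficacy_combiner,
         futility_combiner = "all",
         prior = prior),
    class = "decision_rule_set")
  .warn_if_overlapping(rules)
  rules
}

# A GO and a STOP condition could in principle both hold for some data.
# Overlap is ruled out for an endpoint exactly when some required efficacy
# level has delta_l >= delta_F and gamma_l >= gamma_F: then GO forces
# P(. > delta_F) >= P(. > delta_l) > gamma_l >= gamma_F, i.e. not futile.
# Efficacy takes precedence either way; warn at construction when the
# guarantee is absent.
.warn_if_overlapping <- function(rules) {
  req <- rules$evidence_level_required
  for (k in 1:2) {
    ep <- rules$endpoints[[k]]
    gate <- ep$futility
    lv <- ep$levels[seq_len(req)]
    deltas <- vapply(lv, `[[`, 0, "delta")
    gammas <- vapply(lv, `[[`, 0, "gamma")
    for (t in seq_along(gate$gamma_by_analysis)) {
      guarded <- any(deltas >= gate$delta &
                       gammas >= gate$gamma_by_analysis[t])
      if (!guarded) {
        warning(sprintf(paste0(
          "endpoint %d, interim %d: no required efficacy level dominates the ",
          "futility gate; GO and STOP conditions may hold simultaneously for ",
          "some data (efficacy takes precedence)"),
          k, t), call. = FALSE)
      }
    }
  }
  invisible(rules)
}

#' Default NASH phase 2b decision rules
#'
#' Endpoint 1 (NASH resolution) evidence levels `(0, 0.95)`, `(0.30, 0.85)`,
#' `(0.40, 0.60)`; endpoint 2 (fibrosis improvement) `(0, 0.95)`,
#' `(0.175, 0.85)`, `(0.25, 0.60)`. Futility margins 0.25 (endpoint 1) and
#' 0.10 (endpoint 2) with interim thresholds 0.20 (first interim) and 0.30
#' (second). By default all three evidence levels are required.
#'
#' @param evidence_level_required How many evidence levels must hold (1-3).
#' @return A `decision_rule_set`.
#' @export
default_decision_rules <- function(evidence_level_required = 3L) {
  decision_rule_set(
    e1_levels = list(evidence_level(0, 0.95),
                     evidence_level(0.30, 0.85),
                     evidence_level(0.40, 0.60)),
    e2_levels = list(evidence_level(0, 0.95),
                     evidence_level(0.175, 0.85),
                     evidence_level(0.25, 0.60)),
    e1_futility = futility_gate(0.25, c(0.20, 0.30)),
    e2_futility = futility_gate(0.10, c(0.20, 0.30)),
    evidence_level_required = evidence_level_required
  )
}

#' Efficacy check for a single endpoint
#'
#' @param post_e,post_s Posteriors for experimental and control response rate.
#' @param levels List of [evidence_level()].
#' @param required Number of leading levels that must all hold.
#' @return `TRUE` iff `P(pi_E > pi_S + delta_l) > gamma_l` for every
#'   `l <= required` (strict inequality).
#' @export
endpoint_efficacy <- function(post_e, post_s, levels, required) {
  required <- as.integer(required)
  stopifnot(required >= 1, required <= length(levels))
  for (l in seq_len(required)) {
    lv <- levels[[l]]
    if (!(prob_exceeds_by(post_e, post_s, lv$delta) > lv$gamma)) return(FALSE)
  }
  TRUE
}

#' Futility check for a single endpoint at an interim analysis
#'
#' @param post_e,post_s Posteriors for experimental and control response rate.
#' @param gate A [futility_gate()].
#' @param analysis_index Interim analysis index (1-based); the final analysis
#'   has no futility gate and is rejected.
#' @return `TRUE` iff `P(pi_E > pi_S + delta_F) < gamma_F[analysis_index]`.
#' @export
endpoint_futility <- function(post_e, post_s, gate, analysis_index) {
  stopifnot(inherits(gate, "futility_gate"))
  analysis_index <- as.integer(analysis_index)
  if (is.na(analysis_index) || analysis_index < 1 ||
      analysis_index > length(gate$gamma_by_analysis)) {
    stop("`analysis_index` must name an interim analysis with a futility gate",
         call. = FALSE)
  }
  prob_exceeds_by(post_e, post_s, gate$delta) <
    gate$gamma_by_analysis[analysis_index]
}

#' Evaluate a cohort's data against the decision rules
#'
#' Applies the two-endpoint rule: GO if the efficacy levels hold on either
#' endpoint (or on both, with `efficacy_combiner = "all"`); otherwise, at an
#' interim, STOP if the futility gate fires on both endpoints, else CONTINUE;
#' at the final analysis, STOP whenever not GO. Efficacy is evaluated before
#' futility, so GO and STOP are mutually exclusive by construction.
#'
#' @param data List of two per-endpoint lists, each with elements `treatment`
#'   and `control` of class [arm_counts()].
#' @param rules A [decision_rule_set()].
#' @param analysis_index Analysis index (1, 2 interim; 3 final by default).
#' @param is_final Is this the final analysis?
#' @return A `cohort_decision`: list with `verdict` (`"GO"`, `"STOP"` or
#'   `"CONTINUE"`) and `probs`, the per-endpoint efficacy-level and futility
#'   posterior probabilities for diagnostics.
#' @examples
#' data <- list(
#'   list(treatment = arm_counts(60, 75), control = arm_counts(8, 75)),
#'   list(treatment = arm_counts(15, 75), control = arm_counts(15, 75))
#' )
#' evaluate_cohort(data, default_decision_rules(), analysis_index = 1,
#'                 is_final = FALSE)$verdict
#' @export
evaluate_cohort <- function(data, rules, analysis_index, is_final) {
  stopifnot(inherits(rules, "decision_rule_set"), length(data) == 2)
  posts <- lapply(data, function(ep) {
    stopifnot(inherits(ep$treatment, "arm_counts"),
              inherits(ep$control, "arm_counts"))
    list(e = update_posterior(rules$prior, ep$treatment),
         s = update_posterior(rules$prior, ep$control))
  })
  req <- rules$evidence_level_required
  probs <- vector("list", 2)
  eff <- logical(2)
  for (k in 1:2) {
    lv <- rules$endpoints[[k]]$levels
    p <- vapply(seq_len(req), function(l) {
      prob_exceeds_by(posts[[k]]$e, posts[[k]]$s, lv[[l]]$delta)
    }, 0)
    eff[k] <- all(p > vapply(lv[seq_len(req)], `[[`, 0, "gamma"))
    probs[[k]] <- list(efficacy = p)
  }
  go <- if (rules$efficacy_combiner == "any") any(eff) else all(eff)
  verdict <- if (go) {
    "GO"
  } else if (is_final) {
    "STOP"
  } else {
    fut <- logical(2)
    for (k in 1:2) {
      gate <- rules$endpoints[[k]]$futility
      pf <- prob_exceeds_by(posts[[k]]$e, posts[[k]]$s, gate$delta)
      probs[[k]]$futility <- pf
      fut[k] <- pf < gate$gamma_by_analysis[analysis_index]
    }
    if (all(fut)) "STOP" else "CONTINUE"
  }
  structure(list(verdict = verdict, probs = probs,
                 analysis_index = analysis_index, is_final = is_final),
            class = "cohort_decision")
}

#' @export
print.cohort_decision <- function(x, ...) {
  cat(sprintf("Decision: %s (analysis %d%s)\n", x$verdict, x$analysis_index,
              if (x$is_final) ", final" else ""))
  for (k in 1:2) {
    cat(sprintf("  endpoint %d efficacy P: %s", k,
                paste(sprintf("%.4f", x$probs[[k]]$efficacy), collapse = " ")))
    if (!is.null(x$probs[[k]]$futility)) {
      cat(sprintf("  futility P: %.4f", x$probs[[k]]$futility))
    }
    cat("\n")
  }
  invisible(x)
}
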