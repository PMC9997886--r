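# Platform-level configuration: every design choice and assumption of the
# simulated phase 2b NASH platform in one validated record.

#' Platform trial configuration
#'
#' Collects all assumptions and design choices of the simulated platform:
#' cohort schedule, accrual, outcome lag, analysis timings, response-rate
#' scenario, endpoint correlation, data sharing and decision rules. Defaults
#' reproduce the base design: two initial cohorts, a new cohort every 24
#' weeks up to five, 6 participants/week accrual, 52-week outcome
#' observation, interim analyses at 50% and 75% of planned observed
#' outcomes, standard-of-care responder rates 10% (endpoint 1) and 20%
#' (endpoint 2), and the three-level decision rules.
#'
#' @param n_initial_cohorts Cohorts open at week 0.
#' @param max_cohorts Maximum number of cohorts entering the platform.
#' @param cohort_entry_interval_weeks Weeks between successive cohort entries
#'   after the initial ones.
#' @param accrual_per_week Participants entering the platform per week
#'   (deterministic).
#' @param outcome_lag_weeks Weeks from enrollment to outcome observation.
#' @param cohort_size Planned participants per cohort (both arms; must be
#'   even). The investigated designs use 150 or 250 (75 or 125 per arm).
#' @param interim_fractions Fractions of the planned cohort size, counted in
#'   observed outcomes, at which the interim analyses fire; strictly
#'   increasing, in (0, 1).
#' @param sharing_mode `"concurrent"` to pool concurrently enrolled control
#'   participants from other cohorts at analyses, `"cohort"` for no sharing.
#' @param soc_rates Standard-of-care responder rates `c(endpoint1, endpoint2)`.
#' @param trt_rates Investigational-treatment responder rates
#'   `c(endpoint1, endpoint2)`; defaults to `soc_rates` (global null).
#' @param rho Latent bivariate-normal correlation of the two endpoints.
#' @param time_trend_per_week Additive weekly drift of all response
#'   probabilities (default 0).
#' @param rules A [decision_rule_set()].
#' @param n_sims Default number of platform replicates for simulation runs.
#' @param seed Optional integer master seed.
#' @return A validated `platform_config`.
#' @examples
#' cfg <- platform_config(trt_rates = c(0.45, 0.45), rho = 0, seed = 1)
#' cohort_schedule(cfg)
#' @export
platform_config <- function(n_initial_cohorts = 2L,
                            max_cohorts = 5L,
                            cohort_entry_interval_weeks = 24L,
                            accrual_per_week = 6L,
                            outcome_lag_weeks = 52L,
                            cohort_size = 150L,
                            interim_fractions = c(0.5, 0.75),
                            sharing_mode = c("concurrent", "cohort"),
                            soc_rates = c(0.10, 0.20),
                            trt_rates = soc_rates,
                            rho = 0,
                            time_trend_per_week = 0,
                            rules = default_decision_rules(),
                            n_sims = 10000L,
                            seed = NULL) {
  sharing_mode <- match.arg(sharing_mode)
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != as.integer(x)) {
      stop(sprintf("`%s` must be an integer >= %d", nm, min), call. = FALSE)
    }
    as.integer(x)
  }
  n_initial_cohorts <- chk_count(n_initial_cohorts, "n_initial_cohorts")
  max_cohorts <- chk_count(max_cohorts, "max_cohorts")
  if (n_initial_cohorts > max_cohorts) {
    stop("`n_initial_cohorts` cannot exceed `max_cohorts`", call. = FALSE)
  }
  cohort_entry_interval_weeks <- chk_count(cohort_entry_interval_weeks,
                                           "cohort_entry_interval_weeks", 0)
  accrual_per_week <- chk_count(accrual_per_week, "accrual_per_week")
  outcome_lag_weeks <- chk_count(outcome_lag_weeks, "outcome_lag_weeks")
  cohort_size <- chk_count(cohort_size, "cohort_size", 2)
  if (cohort_size %% 2L != 0L) {
    stop("`cohort_size` must be even (1:1 allocation in blocks of two)",
         call. = FALSE)
  }
  if (!is.numeric(interim_fractions) || anyNA(interim_fractions) ||
      any(interim_fractions <= 0 | interim_fractions >= 1) ||
      (length(interim_fractions) > 1 && any(diff(interim_fractions) <= 0))) {
    stop("`interim_fractions` must be strictly increasing and inside (0, 1)",
         call. = FALSE)
  }
  chk_rates <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x) || any(x < 0 | x > 1)) {
      stop(sprintf("`%s` must be two probabilities in [0, 1]", nm),
           call. = FALSE)
    }
    as.numeric(x)
  }
  soc_rates <- chk_rates(soc_rates, "soc_rates")
  trt_rates <- chk_rates(trt_rates, "trt_rates")
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) ||
      rho <= -1 || rho >= 1) {
    stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (!is.numeric(time_trend_per_week) || length(time_trend_per_week) != 1 ||
      is.na(time_trend_per_week)) {
    stop("`time_trend_per_week` must be a single number", call. = FALSE)
  }
  if (!inherits(rules, "decision_rule_set")) {
    stop("`rules` must be a decision_rule_set", call. = FALSE)
  }
  n_sims <- chk_count(n_sims, "n_sims")
  if (!is.null(seed)) {
    seed <- chk_count(seed, "seed", 0)
  }
  cfg <- structure(
    list(n_initial_cohorts = n_initial_cohorts,
         max_cohorts = max_cohorts,
         cohort_entry_interval_weeks = cohort_entry_interval_weeks,
         accrual_per_week = accrual_per_week,
         outcome_lag_weeks = outcome_lag_weeks,
         cohort_size = cohort_size,
         interim_fractions = as.numeric(interim_fractions),
         sharing_mode = sharing_mode,
         soc_rates = soc_rates,
         trt_rates = trt_rates,
         rho = rho,
         time_trend_per_week = time_trend_per_week,
         rules = rules,
         n_sims = n_sims,
         seed = seed),
    class = "platform_config")
  # a nonzero trend must keep every rate inside [0, 1] over the whole
  # enrollment horizon of the platform
  if (time_trend_per_week != 0) {
    horizon <- .enrollment_horizon(cfg)
    shifted <- c(soc_rates, trt_rates) + time_trend_per_week * horizon
    if (any(shifted < 0 | shifted > 1)) {
      stop(sprintf(paste0("`time_trend_per_week` = %g drives a response rate ",
                          "outside [0, 1] within the %d-week enrollment ",
                          "horizon"), time_trend_per_week, horizon),
           call. = FALSE)
    }
  }
  cfg
}

# upper bound on the last possible enrollment week
.enrollment_horizon <- function(config) {
  last_entry <- max(cohort_schedule(config))
  last_entry + ceiling(config$max_cohorts * config$cohort_size /
                         config$accrual_per_week)
}

#' @export
print.platform_config <- function(x, ...) {
  cat("Platform trial configuration\n")
  cat(sprintf("  cohorts: %d initial, max %d, new every %d weeks, size %d\n",
              x$n_initial_cohorts, x$max_cohorts,
              x$cohort_entry_interval_weeks, x$cohort_size))
  cat(sprintf("  accrual %d/week, outcome lag %d weeks, interims at %s of size\n",
              x$accrual_per_week, x$outcome_lag_weeks,
              paste0(format(100 * x$interim_fractions), "%", collapse = ", ")))
  cat(sprintf("  SoC rates %s, treatment rates %s, rho = %g, sharing = %s\n",
              paste(x$soc_rates, collapse = "/"),
              paste(x$trt_rates, collapse = "/"), x$rho, x$sharing_mode))
  cat(sprintf("  evidence level required: %d; n_sims = %d%s\n",
              x$rules$evidence_level_required, x$n_sims,
              if (is.null(x$seed)) "" else sprintf("; seed = %d", x$seed)))
  invisible(x)
}
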