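# Aggregation of replicate results into operating characteristics, and
# scenario grids over the simulation parameters.

#' Operating characteristics of a simulated scenario
#'
#' Pools cohort decisions across replicates (all cohorts share one
#' treatment-effect scenario, so they are exchangeable) into the success
#' probability and cumulative early-decision probabilities, and averages
#' duration and enrollment per replicate. Monte-Carlo standard errors use the
#' binomial formula on the pooled evaluation count.
#'
#' @param sims A `platform_sims` from [simulate_platform()].
#' @return A one-row data frame of class `oc_summary` with scenario
#'   descriptors, `success_prob`, `futility_prob`, cumulative GO/STOP
#'   probabilities at the first and second interim, `avg_duration_weeks`,
#'   `avg_total_enrolled`, `participants_saved` (planned maximum minus mean
#'   enrolled), the evaluation counts and Monte-Carlo standard errors.
#' @export
summarize_oc <- function(sims) {
  stopifnot(inherits(sims, "platform_sims"))
  led <- sims$ledger
  if (nrow(led) == 0) stop("empty result ledger", call. = FALSE)
  cfg <- sims$config
  n_eval <- nrow(led)
  go <- led$decision == "GO"
  p_go <- mean(go)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  cum <- function(dec, idx) mean(led$decision == dec & led$analysis_index <= idx)
  planned <- cfg$max_cohorts * cfg$cohort_size
  out <- data.frame(
    trt_rate_e1 = cfg$trt_rates[1], trt_rate_e2 = cfg$trt_rates[2],
    soc_rate_e1 = cfg$soc_rates[1], soc_rate_e2 = cfg$soc_rates[2],
    rho = cfg$rho, cohort_size = cfg$cohort_size,
    sharing_mode = cfg$sharing_mode,
    evidence_level = cfg$rules$evidence_level_required,
    n_sims = sims$n_sims, n_evaluations = n_eval,
    success_prob = p_go, success_prob_se = se(p_go, n_eval),
    futility_prob = 1 - p_go,
    cum_go_ia1 = cum("GO", 1), cum_go_ia2 = cum("GO", 2),
    cum_stop_ia1 = cum("STOP", 1), cum_stop_ia2 = cum("STOP", 2),
    cum_stop_ia1_se = se(cum("STOP", 1), n_eval),
    cum_stop_ia2_se = se(cum("STOP", 2), n_eval),
    avg_duration_weeks = mean(sims$replicates$duration_weeks),
    avg_total_enrolled = mean(sims$replicates$total_enrolled),
    participants_saved = planned - mean(sims$replicates$total_enrolled),
    stringsAsFactors = FALSE)
  class(out) <- c("oc_summary", class(out))
  out
}

#' Scenario grid over the simulation parameters
#'
#' Builds the Cartesian product of treatment response rates, latent
#' correlations, cohort sizes, sharing modes and required evidence levels
#' over a base configuration, with a deterministic per-scenario seed derived
#' from the base seed.
#'
#' @param base A [platform_config()] supplying all other parameters
#'   (including the master seed).
#' @param e1_rates,e2_rates Treatment responder rates for endpoints 1 and 2.
#' @param rhos Latent correlations.
#' @param sizes Cohort sizes.
#' @param modes Sharing modes.
#' @param levels Required evidence levels.
#' @return List of `platform_config` objects, one per scenario, each with its
#'   own seed; duplicated values in any axis are dropped with a warning.
#' @examples
#' base <- platform_config(seed = 1)
#' length(scenario_grid(base, e1_rates = c(0.10, 0.45), e2_rates = 0.25,
#'                      rhos = c(0, 0.7), sizes = 150, modes = "concurrent",
#'                      levels = 3))
#' @export
scenario_grid <- function(base,
                          e1_rates = c(0.10, 0.35, 0.45, 0.55),
                          e2_rates = c(0.25, 0.35, 0.45, 0.55),
                          rhos = c(-0.3, 0, 0.3, 0.7),
                          sizes = c(150, 250),
                          modes = c("concurrent", "cohort"),
                          levels = 3) {
  stopifnot(inherits(base, "platform_config"))
  if (is.null(base$seed)) {
    stop("`base` must carry a master seed", call. = FALSE)
  }
  dedup <- function(x, nm) {
    if (anyDuplicated(x)) {
      warning(sprintf("duplicate values in `%s` dropped", nm), call. = FALSE)
      x <- unique(x)
    }
    if (length(x) == 0) stop(sprintf("`%s` is empty", nm), call. = FALSE)
    x
  }
  grid <- expand.grid(
    e1 = dedup(e1_rates, "e1_rates"), e2 = dedup(e2_rates, "e2_rates"),
    rho = dedup(rhos, "rhos"), size = dedup(sizes, "sizes"),
    mode = dedup(modes, "modes"), level = dedup(levels, "levels"),
    stringsAsFactors = FALSE)
  set.seed(base$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rules <- if (g$level == base$rules$evidence_level_required) {
      base$rules
    } else {
      rs <- base$rules
      rs$evidence_level_required <- as.integer(g$level)
      rs
    }
    platform_config(
      n_initial_cohorts = base$n_initial_cohorts,
      max_cohorts = base$max_cohorts,
      cohort_entry_interval_weeks = base$cohort_entry_interval_weeks,
      accrual_per_week = base$accrual_per_week,
      outcome_lag_weeks = base$outcome_lag_weeks,
      cohort_size = g$size,
      interim_fractions = base$interim_fractions,
      sharing_mode = g$mode,
      soc_rates = base$soc_rates,
      trt_rates = c(g$e1, g$e2),
      rho = g$rho,
      time_trend_per_week = base$time_trend_per_week,
      rules = rules,
      n_sims = base$n_sims,
      seed = seeds[i])
  })
}

#' Run a list of scenario configurations
#'
#' @param configs List of `platform_config` objects (e.g. from
#'   [scenario_grid()]).
#' @param n_sims Replicates per scenario (default each config's own).
#' @return Data frame with one `oc_summary` row per scenario.
#' @export
run_scenarios <- function(configs, n_sims = NULL) {
  stopifnot(length(configs) > 0)
  rows <- lapply(configs, function(cfg) {
    summarize_oc(simulate_platform(
      cfg, n_sims = if (is.null(n_sims)) cfg$n_sims else n_sims))
  })
  do.call(rbind, rows)
}

#' Write an operating-characteristics table to CSV
#'
#' Numeric columns are written at full double precision so that reading the
#' file back reproduces the values bit-exactly.
#'
#' @param summaries Data frame of `oc_summary` rows (may be empty).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_oc_table <- function(summaries, path) {
  out <- as.data.frame(summaries)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
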