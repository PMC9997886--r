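# Configuration files (YAML or JSON), defaults, and run manifests.

.CONFIG_KEYS <- c("n_initial_cohorts", "max_cohorts",
                  "cohort_entry_interval_weeks", "accrual_per_week",
                  "outcome_lag_weeks", "cohort_size", "interim_fractions",
                  "sharing_mode", "soc_rates", "trt_rates", "rho",
                  "time_trend_per_week", "decision_rules", "n_sims", "seed")

#' Load a platform configuration from a YAML or JSON file
#'
#' Missing keys take the package defaults (see [platform_config()]); the
#' decision rules default to [default_decision_rules()] unless a
#' `decision_rules` block overrides them. Unknown keys and invariant
#' violations raise an error naming the offending key.
#'
#' A `decision_rules` block has the shape (YAML):
#' ```yaml
#' decision_rules:
#'   evidence_level_required: 3
#'   e1:
#'     levels: [{delta: 0, gamma: 0.95}, {delta: 0.30, gamma: 0.85},
#'              {delta: 0.40, gamma: 0.60}]
#'     futility: {delta: 0.25, gamma_ia1: 0.20, gamma_ia2: 0.30}
#'   e2:
#'     levels: [{delta: 0, gamma: 0.95}, {delta: 0.175, gamma: 0.85},
#'              {delta: 0.25, gamma: 0.60}]
#'     futility: {delta: 0.10, gamma_ia1: 0.20, gamma_ia2: 0.30}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; an empty file yields
#'   the full default configuration.
#' @return A validated [platform_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' Build a platform configuration from a plain list
#'
#' @param raw Named list with any subset of the configuration keys.
#' @return A validated [platform_config()].
#' @export
config_from_list <- function(raw) {
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  args <- raw[setdiff(names(raw), "decision_rules")]
  # JSON parsers may hand scalar sequences back as lists; flatten them
  args <- lapply(args, function(x) {
    if (is.list(x) && length(x) > 0 && all(lengths(x) == 1)) unlist(x) else x
  })
  args$rules <- if (is.null(raw$decision_rules)) {
    default_decision_rules()
  } else {
    .rules_from_list(raw$decision_rules)
  }
  do.call(platform_config, args)
}

.rules_from_list <- function(dr) {
  parse_levels <- function(lv, nm) {
    if (is.data.frame(lv)) lv <- split(lv, seq_len(nrow(lv)))
    lv <- unname(lv)
    lapply(lv, function(x) {
      if (is.null(x$delta) || is.null(x$gamma)) {
        stop(sprintf("`decision_rules$%s$levels` entries need delta and gamma",
                     nm), call. = FALSE)
      }
      evidence_level(x$delta, x$gamma)
    })
  }
  parse_futility <- function(fu, nm) {
    if (is.null(fu$delta) || is.null(fu$gamma_ia1) || is.null(fu$gamma_ia2)) {
      stop(sprintf(
        "`decision_rules$%s$futility` needs delta, gamma_ia1 and gamma_ia2",
        nm), call. = FALSE)
    }
    futility_gate(fu$delta, c(fu$gamma_ia1, fu$gamma_ia2))
  }
  defaults <- default_decision_rules()
  e1 <- dr$e1; e2 <- dr$e2
  decision_rule_set(
    e1_levels = if (is.null(e1$levels)) defaults$endpoints[[1]]$levels
                else parse_levels(e1$levels, "e1"),
    e2_levels = if (is.null(e2$levels)) defaults$endpoints[[2]]$levels
                else parse_levels(e2$levels, "e2"),
    e1_futility = if (is.null(e1$futility)) defaults$endpoints[[1]]$futility
                  else parse_futility(e1$futility, "e1"),
    e2_futility = if (is.null(e2$futility)) defaults$endpoints[[2]]$futility
                  else parse_futility(e2$futility, "e2"),
    evidence_level_required =
      if (is.null(dr$evidence_level_required)) 3L
      else dr$evidence_level_required)
}

#' Serialize a platform configuration to a plain list
#'
#' Inverse of [config_from_list()]: `config_from_list(config_as_list(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [platform_config()].
#' @return Named list mirroring the configuration file schema.
#' @export
config_as_list <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  rules <- config$rules
  lv <- function(k) {
    lapply(rules$endpoints[[k]]$levels,
           function(x) list(delta = x$delta, gamma = x$gamma))
  }
  fu <- function(k) {
    g <- rules$endpoints[[k]]$futility
    list(delta = g$delta, gamma_ia1 = g$gamma_by_analysis[1],
         gamma_ia2 = g$gamma_by_analysis[2])
  }
  out <- config[setdiff(.CONFIG_KEYS, c("decision_rules", "seed"))]
  out$decision_rules <- list(
    evidence_level_required = rules$evidence_level_required,
    e1 = list(levels = lv(1), futility = fu(1)),
    e2 = list(levels = lv(2), futility = fu(2)))
  if (!is.null(config$seed)) out$seed <- config$seed
  out
}

#' Write a platform configuration to a YAML or JSON file
#'
#' @param config A [platform_config()].
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  lst <- config_as_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Default configuration and decision rules
#'
#' Prints the default platform configuration, decision-rule parameterization
#' and analysis thresholds.
#'
#' @return The default [platform_config()], invisibly.
#' @export
show_defaults <- function() {
  cfg <- platform_config()
  print(cfg)
  cat("\nEfficacy evidence levels (applied at every analysis):\n")
  for (k in 1:2) {
    lv <- cfg$rules$endpoints[[k]]$levels
    cat(sprintf("  endpoint %d: %s\n", k,
                paste(vapply(lv, function(x) {
                  sprintf("(delta=%g, gamma=%g)", x$delta, x$gamma)
                }, ""), collapse = " ")))
  }
  cat("Interim futility gates:\n")
  for (k in 1:2) {
    g <- cfg$rules$endpoints[[k]]$futility
    cat(sprintf("  endpoint %d: delta=%g, gamma IA1=%g, IA2=%g\n", k,
                g$delta, g$gamma_by_analysis[1], g$gamma_by_analysis[2]))
  }
  cat(sprintf("Analysis thresholds (observed outcomes): %s\n",
              paste(analysis_thresholds(cfg), collapse = ", ")))
  invisible(cfg)
}

#' Write a run manifest
#'
#' Records the resolved configuration, package version, master seed and any
#' per-scenario seeds so that a run can be reproduced bit-exactly.
#'
#' @param config A [platform_config()].
#' @param path Output JSON path.
#' @param scenario_seeds Optional named or unnamed vector of per-scenario
#'   seeds.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, path, scenario_seeds = NULL) {
  manifest <- list(
    package = "platnash",
    version = as.character(utils::packageVersion("platnash")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config_as_list(config))
  if (!is.null(scenario_seeds)) manifest$scenario_seeds <- scenario_seeds
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
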