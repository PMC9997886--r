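# Event-driven weekly simulation of the platform. Within a week, events are
# ordered: (1) outcomes enrolled `outcome_lag_weeks` ago mature, (2) analyses
# fire for cohorts whose observed-outcome count reached a threshold (in
# cohort-entry order), (3) the week's accrual is allocated to cohorts still
# open for enrollment. A cohort that receives a GO/STOP decision stops
# enrolling the same week, before that week's allocation.

#' Calendar of cohort entry weeks
#'
#' `n_initial_cohorts` cohorts enter at week 0; afterwards one cohort enters
#' every `cohort_entry_interval_weeks` until `max_cohorts` is reached. The
#' schedule is a fixed calendar, independent of earlier stopping decisions
#' (the platform always evaluates `max_cohorts` treatments).
#'
#' @param config A [platform_config()].
#' @return Integer vector of entry weeks, one per cohort.
#' @examples
#' cohort_schedule(platform_config()) # 0 0 24 48 72
#' @export
cohort_schedule <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  extra <- config$max_cohorts - config$n_initial_cohorts
  c(rep(0L, config$n_initial_cohorts),
    config$cohort_entry_interval_weeks * seq_len(extra))
}

#' Observed-outcome counts that trigger the analyses
#'
#' Interim analysis `T` fires in the first week a cohort's observed-outcome
#' count (both arms, own cohort) reaches `ceiling(fraction_T * cohort_size)`;
#' the final analysis fires at `cohort_size` observed.
#'
#' @param config A [platform_config()].
#' @return Integer vector of thresholds, interims then final.
#' @examples
#' analysis_thresholds(platform_config(cohort_size = 150)) # 75 113 150
#' @export
analysis_thresholds <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  as.integer(c(ceiling(config$interim_fractions * config$cohort_size),
               config$cohort_size))
}

#' Split a week's accrual across open cohorts
#'
#' The week's participants are divided as evenly as possible across cohorts
#' open for enrollment; the remainder goes to cohorts in round-robin order
#' starting at the carried rotation pointer, so that long-run allocation is
#' equal. Participants in excess of a cohort's remaining capacity roll over
#' to other open cohorts; accrual beyond the total open capacity is lost
#' (participants are not queued).
#'
#' @param open_capacity Integer vector of remaining enrollment slots per open
#'   cohort, in cohort order.
#' @param accrual Number of participants arriving this week.
#' @param carry Rotation pointer in `1..length(open_capacity)` carried over
#'   from the previous week.
#' @return List with `counts` (participants allocated per open cohort) and
#'   the updated `carry` pointer.
#' @examples
#' allocate_week(c(100, 100, 100, 100), 6, carry = 1)
#' @export
allocate_week <- function(open_capacity, accrual, carry = 1L) {
  k <- length(open_capacity)
  stopifnot(k >= 1, accrual >= 0, carry >= 1)
  carry <- ((as.integer(carry) - 1L) %% k) + 1L
  base <- accrual %/% k
  rem <- accrual %% k
  counts <- rep(base, k)
  if (rem > 0) {
    idx <- ((carry - 1L + seq_len(rem) - 1L) %% k) + 1L
    counts[idx] <- counts[idx] + 1L
  }
  new_carry <- ((carry - 1L + rem) %% k) + 1L
  # roll capacity overflow over to cohorts with spare slots, rotation order
  overflow <- sum(pmax(counts - open_capacity, 0))
  counts <- pmin(counts, open_capacity)
  if (overflow > 0) {
    order_idx <- ((new_carry - 1L + seq_len(k) - 1L) %% k) + 1L
    while (overflow > 0 && any(counts < open_capacity)) {
      for (i in order_idx) {
        if (overflow == 0) break
        if (counts[i] < open_capacity[i]) {
          counts[i] <- counts[i] + 1L
          overflow <- overflow - 1L
        }
      }
    }
  }
  list(counts = as.integer(counts), carry = new_carry)
}

#' Draw correlated binary outcomes for newly enrolled participants
#'
#' Outcomes are generated from the latent bivariate-normal construction with
#' the arm's marginal response rates (optionally shifted by a linear calendar
#' time trend) and the shared latent correlation.
#'
#' @param n Number of participants.
#' @param rates Length-2 response rates `c(endpoint1, endpoint2)` of the arm.
#' @param rho Latent correlation.
#' @param week Enrollment week (only relevant with a nonzero trend).
#' @param trend Additive response-rate drift per week.
#' @return Integer matrix with columns `s` (endpoint 1) and `l` (endpoint 2).
#' @export
draw_outcomes <- function(n, rates, rho, week = 0, trend = 0) {
  r <- rates + trend * week
  if (any(r < 0 | r > 1)) {
    stop("time trend drives a response rate outside [0, 1]", call. = FALSE)
  }
  sample_joint(joint_spec_latent(r[1], r[2], rho), n)
}

# count entries of the sorted vector v[1:n] that are <= x
.n_leq <- function(v, n, x) {
  if (n == 0L || x < v[1L]) return(0L)
  findInterval(x, v[seq_len(n)])
}

#' Simulate one platform trial replicate
#'
#' Runs the weekly event loop until every cohort has a GO or STOP decision.
#' Uses R's global random number stream; seed it for reproducibility.
#'
#' @param config A [platform_config()].
#' @param keep_participants Also return the per-participant ledger
#'   (enrollment week, cohort, arm, outcomes, outcome week)?
#' @return A `platform_result`: list with `cohorts` (one row per cohort:
#'   entry week, enrollment window, per-arm enrollment, decision, analysis
#'   index, decision week), `analyses` (one row per conducted analysis with
#'   the exact arm counts used, including shared controls),
#'   `platform_duration_weeks` (week of the last decision), `total_enrolled`
#'   (every randomized participant, observed or not), and optionally
#'   `participants`.
#' @examples
#' set.seed(42)
#' res <- run_platform(platform_config(trt_rates = c(0.55, 0.55), rho = 0.3))
#' res$cohorts
#' @export
run_platform <- function(config, keep_participants = FALSE,
                         keep_analyses = TRUE) {
  stopifnot(inherits(config, "platform_config"))
  entries <- cohort_schedule(config)
  K <- length(entries)
  m <- config$cohort_size %/% 2L
  lag <- config$outcome_lag_weeks
  thr <- analysis_thresholds(config)
  n_an <- length(thr)
  trend <- config$time_trend_per_week
  concurrent <- config$sharing_mode == "concurrent"

  # per-arm multinomial cell probabilities (p00, p01, p10, p11); fixed over
  # time when there is no trend. A degenerate marginal (0 or 1) pins the
  # joint distribution down to the product table, bypassing the latent copula
  cells_of <- function(rates, rho) {
    if (any(rates %in% c(0, 1))) {
      r1 <- rates[1]; r2 <- rates[2]
      c((1 - r1) * (1 - r2), (1 - r1) * r2, r1 * (1 - r2), r1 * r2)
    } else {
      spec <- joint_spec_latent(rates[1], rates[2], rho)
      c(spec$p00, spec$p01, spec$p10, spec$p11)
    }
  }
  if (trend == 0) {
    cells_t <- cells_of(config$trt_rates, config$rho)
    cells_s <- cells_of(config$soc_rates, config$rho)
  }
  arm_cells <- function(arm, week) {
    if (trend == 0) {
      if (arm == 1L) cells_t else cells_s
    } else {
      r <- (if (arm == 1L) config$trt_rates else config$soc_rates) +
        trend * week
      cells_of(r, config$rho)
    }
  }

  # preallocated per-cohort per-arm storage
  tw <- cw <- lapply(seq_len(K), function(i) numeric(m))
  ts1 <- ts2 <- cs1 <- cs2 <- lapply(seq_len(K), function(i) integer(m))
  nt <- nc <- integer(K)
  pending <- integer(K)            # 0 none, 1 treatment next, 2 control next
  first_enr <- last_enr <- rep(NA_integer_, K)
  decided <- logical(K)
  decision <- rep(NA_character_, K)
  dec_week <- dec_idx <- rep(NA_integer_, K)
  next_an <- rep(1L, K)
  carry <- 1L

  an_log <- list()
  week <- 0L
  max_week <- .enrollment_horizon(config) + lag + 104L

  while (!all(decided)) {
    if (week > max_week) {
      stop("platform failed to terminate within the expected horizon",
           call. = FALSE)
    }
    # --- analyses (cohort-entry order); none possible before the first
    # outcomes mature ----------------------------------------------------
    for (i in seq_len(K)) {
      if (week < lag || decided[i] || entries[i] > week) next
      obs_t <- .n_leq(tw[[i]], nt[i], week - lag)
      obs_c <- .n_leq(cw[[i]], nc[i], week - lag)
      while (!decided[i] && next_an[i] <= n_an &&
             obs_t + obs_c >= thr[next_an[i]]) {
        idx_t <- seq_len(obs_t)
        sE1 <- sum(ts1[[i]][idx_t]); sE2 <- sum(ts2[[i]][idx_t])
        idx_c <- seq_len(obs_c)
        sS1 <- sum(cs1[[i]][idx_c]); sS2 <- sum(cs2[[i]][idx_c])
        nS <- obs_c
        if (concurrent) {
          win_lo <- first_enr[i]
          enrolling <- !decided[i] && nt[i] + nc[i] < config$cohort_size
          win_hi <- if (enrolling) week else last_enr[i]
          hi <- min(win_hi, week - lag)
          for (j in seq_len(K)) {
            if (j == i || entries[j] > week || is.na(win_lo)) next
            a <- .n_leq(cw[[j]], nc[j], win_lo - 1L)
            b <- .n_leq(cw[[j]], nc[j], hi)
            if (b > a) {
              sl <- (a + 1L):b
              nS <- nS + (b - a)
              sS1 <- sS1 + sum(cs1[[j]][sl])
              sS2 <- sS2 + sum(cs2[[j]][sl])
            }
          }
        }
        is_final <- next_an[i] == n_an
        dec <- evaluate_cohort(
          list(list(treatment = arm_counts(sE1, obs_t),
                    control = arm_counts(sS1, nS)),
               list(treatment = arm_counts(sE2, obs_t),
                    control = arm_counts(sS2, nS))),
          config$rules, analysis_index = next_an[i], is_final = is_final)
        if (keep_analyses) {
          an_log[[length(an_log) + 1L]] <-
            list(i, week, next_an[i], obs_t, sE1, sE2, nS, sS1, sS2,
                 dec$verdict)
        }
        if (dec$verdict %in% c("GO", "STOP")) {
          decided[i] <- TRUE
          decision[i] <- dec$verdict
          dec_week[i] <- week
          dec_idx[i] <- next_an[i]
        } else {
          next_an[i] <- next_an[i] + 1L
        }
      }
    }
    # --- enrollment ----------------------------------------------------
    open <- which(entries <= week & !decided & (nt + nc) < config$cohort_size)
    if (length(open) > 0 && config$accrual_per_week > 0) {
      alloc <- allocate_week(config$cohort_size - (nt + nc)[open],
                             config$accrual_per_week, carry)
      carry <- alloc$carry
      for (oi in seq_along(open)) {
        n_new <- alloc$counts[oi]
        if (n_new == 0L) next
        i <- open[oi]
        # block randomization of length two, in aggregate: a leftover block
        # half is served first, full blocks contribute one participant per
        # arm, and a trailing half block starts with a coin flip whose
        # partner is carried to the next arrival
        n_rem <- n_new
        a_t <- 0L
        if (pending[i] != 0L) {
          if (pending[i] == 1L) a_t <- a_t + 1L
          pending[i] <- 0L
          n_rem <- n_rem - 1L
        }
        a_t <- a_t + n_rem %/% 2L
        if (n_rem %% 2L == 1L) {
          if (stats::runif(1) < 0.5) {
            a_t <- a_t + 1L
            pending[i] <- 2L
          } else {
            pending[i] <- 1L
          }
        }
        a_c <- n_new - a_t
        # capacity guard: shift any overflow to the other arm (total new
        # never exceeds the cohort's remaining capacity)
        ov <- nt[i] + a_t - m
        if (ov > 0L) {
          a_t <- a_t - ov; a_c <- a_c + ov; pending[i] <- 0L
        }
        ov <- nc[i] + a_c - m
        if (ov > 0L) {
          a_c <- a_c - ov; a_t <- a_t + ov; pending[i] <- 0L
        }
        if (a_t > 0L) {
          cell <- sample.int(4L, a_t, replace = TRUE,
                             prob = arm_cells(1L, week))
          sl <- nt[i] + seq_len(a_t)
          tw[[i]][sl] <- week
          ts1[[i]][sl] <- cell >= 3L
          ts2[[i]][sl] <- cell == 2L | cell == 4L
          nt[i] <- nt[i] + a_t
        }
        if (a_c > 0L) {
          cell <- sample.int(4L, a_c, replace = TRUE,
                             prob = arm_cells(2L, week))
          sl <- nc[i] + seq_len(a_c)
          cw[[i]][sl] <- week
          cs1[[i]][sl] <- cell >= 3L
          cs2[[i]][sl] <- cell == 2L | cell == 4L
          nc[i] <- nc[i] + a_c
        }
        if (is.na(first_enr[i])) first_enr[i] <- week
        last_enr[i] <- week
      }
    }
    week <- week + 1L
  }

  cohorts <- data.frame(
    cohort = seq_len(K), entry_week = entries,
    first_enrollment_week = first_enr, last_enrollment_week = last_enr,
    enrolled_treatment = nt, enrolled_control = nc,
    decision = decision, analysis_index = dec_idx, decision_week = dec_week)
  analyses <- NULL
  if (keep_analyses && length(an_log) > 0) {
    analyses <- data.frame(
      cohort = vapply(an_log, `[[`, 0, 1),
      week = vapply(an_log, `[[`, 0, 2),
      analysis_index = vapply(an_log, `[[`, 0, 3),
      n_treatment = vapply(an_log, `[[`, 0, 4),
      s1_treatment = vapply(an_log, `[[`, 0, 5),
      s2_treatment = vapply(an_log, `[[`, 0, 6),
      n_control = vapply(an_log, `[[`, 0, 7),
      s1_control = vapply(an_log, `[[`, 0, 8),
      s2_control = vapply(an_log, `[[`, 0, 9),
      verdict = vapply(an_log, `[[`, "", 10))
  }
  res <- list(cohorts = cohorts,
              analyses = analyses,
              platform_duration_weeks = max(dec_week),
              total_enrolled = sum(nt) + sum(nc))
  if (keep_participants) {
    parts <- lapply(seq_len(K), function(i) {
      rbind(
        if (nt[i] > 0) data.frame(cohort = i, arm = "treatment",
                                  enrollment_week = tw[[i]][seq_len(nt[i])],
                                  s = ts1[[i]][seq_len(nt[i])],
                                  l = ts2[[i]][seq_len(nt[i])]),
        if (nc[i] > 0) data.frame(cohort = i, arm = "control",
                                  enrollment_week = cw[[i]][seq_len(nc[i])],
                                  s = cs1[[i]][seq_len(nc[i])],
                                  l = cs2[[i]][seq_len(nc[i])]))
    })
    parts <- do.call(rbind, parts)
    parts$outcome_week <- parts$enrollment_week + lag
    res$participants <- parts
  }
  structure(res, class = "platform_result")
}

#' @export
print.platform_result <- function(x, ...) {
  cat(sprintf("Platform replicate: %d cohorts, duration %d weeks, %d enrolled\n",
              nrow(x$cohorts), x$platform_duration_weeks, x$total_enrolled))
  print(x$cohorts[, c("cohort", "entry_week", "decision", "analysis_index",
                      "decision_week")])
  invisible(x)
}

#' Simulate many platform replicates
#'
#' Runs [run_platform()] `n_sims` times with independent, reproducible
#' per-replicate seeds derived from the master seed, and collects the cohort
#' decisions into a ledger.
#'
#' @param config A [platform_config()].
#' @param n_sims Number of replicates (default from `config`).
#' @param seed Master seed (default from `config`; required).
#' @return A `platform_sims`: list with `ledger` (one row per cohort per
#'   replicate), `replicates` (duration and enrollment per replicate), the
#'   `config`, `n_sims` and `seed`.
#' @examples
#' cfg <- platform_config(trt_rates = c(0.55, 0.55), rho = 0.3, seed = 7)
#' sims <- simulate_platform(cfg, n_sims = 3)
#' sims$replicates
#' @export
simulate_platform <- function(config, n_sims = config$n_sims,
                              seed = config$seed) {
  stopifnot(inherits(config, "platform_config"))
  if (is.null(seed)) {
    stop("a master `seed` is required for reproducible replicates",
         call. = FALSE)
  }
  n_sims <- as.integer(n_sims)
  stopifnot(n_sims >= 1)
  # per-replicate seeds from the master seed: replicates are independent of
  # execution order and could be run in parallel
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  ledgers <- vector("list", n_sims)
  durations <- integer(n_sims)
  enrolled <- integer(n_sims)
  for (r in seq_len(n_sims)) {
    set.seed(rep_seeds[r])
    res <- run_platform(config, keep_analyses = FALSE)
    led <- res$cohorts[, c("cohort", "decision", "analysis_index",
                           "decision_week", "enrolled_treatment",
                           "enrolled_control")]
    led$replicate <- r
    ledgers[[r]] <- led
    durations[r] <- res$platform_duration_weeks
    enrolled[r] <- res$total_enrolled
  }
  ledger <- do.call(rbind, ledgers)
  ledger <- ledger[, c("replicate", "cohort", "decision", "analysis_index",
                       "decision_week", "enrolled_treatment",
                       "enrolled_control")]
  rownames(ledger) <- NULL
  structure(list(ledger = ledger,
                 replicates = data.frame(replicate = seq_len(n_sims),
                                         duration_weeks = durations,
                                         total_enrolled = enrolled),
                 config = config, n_sims = n_sims, seed = seed),
            class = "platform_sims")
}

#' @export
print.platform_sims <- function(x, ...) {
  cat(sprintf("Platform simulation: %d replicates (seed %d)\n",
              x$n_sims, x$seed))
  cat(sprintf("  GO fraction (pooled cohorts): %.4f\n",
              mean(x$ledger$decision == "GO")))
  cat(sprintf("  mean duration %.1f weeks, mean enrolled %.1f\n",
              mean(x$replicates$duration_weeks),
              mean(x$replicates$total_enrolled)))
  invisible(x)
}
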