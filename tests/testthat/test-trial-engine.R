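test_that("cohort entry schedule is a fixed calendar", {
  expect_equal(cohort_schedule(platform_config()), c(0, 0, 24, 48, 72))
  expect_equal(cohort_schedule(platform_config(max_cohorts = 2)), c(0, 0))
  expect_equal(
    cohort_schedule(platform_config(cohort_entry_interval_weeks = 0)),
    rep(0, 5))
})

test_that("analysis thresholds apply the ceiling to fractional counts", {
  expect_equal(analysis_thresholds(platform_config(cohort_size = 150)),
               c(75, 113, 150))
  expect_equal(analysis_thresholds(platform_config(cohort_size = 250)),
               c(125, 188, 250))
})

test_that("weekly allocation splits evenly with a rotating remainder", {
  a <- allocate_week(c(100, 100), 6)
  expect_equal(a$counts, c(3L, 3L))

  # four open cohorts: 2,2,1,1 this week, deficit rotates via the carry
  a <- allocate_week(rep(100L, 4), 6, carry = 1)
  expect_equal(a$counts, c(2L, 2L, 1L, 1L))
  b <- allocate_week(rep(100L, 4), 6, carry = a$carry)
  expect_equal(b$counts, c(1L, 1L, 2L, 2L))

  # long-run totals equal within 1
  totals <- integer(4); carry <- 1L
  for (w in 1:51) {
    al <- allocate_week(rep(1000L, 4), 6, carry)
    totals <- totals + al$counts
    carry <- al$carry
  }
  expect_lte(diff(range(totals)), 1L)

  # capacity: a nearly full cohort takes one, the excess rolls over
  a <- allocate_week(c(1L, 100L), 6)
  expect_equal(a$counts, c(1L, 5L))
  # accrual beyond total capacity is lost, not queued
  a <- allocate_week(c(1L, 2L), 6)
  expect_equal(sum(a$counts), 3L)
})

test_that("outcome drawing matches the arm's latent-normal distribution", {
  set.seed(407)
  n <- 1e5
  x <- draw_outcomes(n, c(0.10, 0.20), rho = 0)
  expect_lt(abs(mean(x[, "s"]) - 0.10), 4 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(mean(x[, "l"]) - 0.20), 4 * sqrt(0.2 * 0.8 / n))

  x <- draw_outcomes(n, c(0.55, 0.55), rho = 0.7)
  phi_hat <- cor(x[, "s"], x[, "l"])
  expect_lt(abs(phi_hat - rho_to_phi(0.55, 0.55, 0.7)), 4 / sqrt(n))

  # zero trend: the week is irrelevant
  set.seed(1); a <- draw_outcomes(100, c(0.3, 0.4), 0.3, week = 0)
  set.seed(1); b <- draw_outcomes(100, c(0.3, 0.4), 0.3, week = 100)
  expect_identical(a, b)
  expect_error(draw_outcomes(10, c(0.9, 0.9), 0, week = 100, trend = 0.01),
               "outside")
  expect_error(platform_config(time_trend_per_week = 0.01), "outside")
})

test_that("default platform enrolls exactly 750 and respects timing bounds", {
  cfg <- platform_config(trt_rates = c(0.35, 0.35), rho = 0.3)
  for (seed in 1:5) {
    set.seed(seed)
    res <- run_platform(cfg)
    expect_identical(res$total_enrolled, 750L)
    expect_equal(res$cohorts$enrolled_treatment, rep(75L, 5))
    expect_equal(res$cohorts$enrolled_control, rep(75L, 5))
    # the last cohort cannot decide before its first outcomes exist
    expect_gte(res$platform_duration_weeks, 72 + 52)
    # decisions require matured outcomes
    expect_true(all(res$cohorts$decision_week >=
                      res$cohorts$entry_week + 52))
    expect_true(all(res$cohorts$decision %in% c("GO", "STOP")))
  }
})

test_that("a single-cohort platform with certain outcomes is deterministic", {
  rules <- suppressWarnings(default_decision_rules(1))
  cfg <- platform_config(n_initial_cohorts = 1, max_cohorts = 1,
                         interim_fractions = numeric(0),
                         trt_rates = c(1, 1), soc_rates = c(0, 0),
                         rules = rules)
  set.seed(408)
  res <- run_platform(cfg)
  expect_equal(res$cohorts$decision, "GO")
  # 150 participants at 6/week finish enrolling in week 24; the final
  # analysis fires when their outcomes have matured
  expect_equal(res$platform_duration_weeks, 24 + 52)
  expect_equal(res$cohorts$analysis_index, 1L)
})

test_that("block randomization keeps weekly arm imbalance within one", {
  cfg <- platform_config(trt_rates = c(0.45, 0.45), rho = 0.3)
  set.seed(409)
  res <- run_platform(cfg, keep_participants = TRUE)
  parts <- res$participants
  for (i in unique(parts$cohort)) {
    p <- parts[parts$cohort == i, ]
    for (w in sort(unique(p$enrollment_week))) {
      nt <- sum(p$arm == "treatment" & p$enrollment_week <= w)
      nc <- sum(p$arm == "control" & p$enrollment_week <= w)
      expect_lte(abs(nt - nc), 1L)
    }
  }
  # conservation: ledger counts match the cohort totals
  expect_equal(nrow(parts), res$total_enrolled)
  tab <- table(parts$cohort, parts$arm)
  expect_equal(unname(tab[, "treatment"]), res$cohorts$enrolled_treatment)
  expect_equal(unname(tab[, "control"]), res$cohorts$enrolled_control)
})

test_that("analysis control pools match a brute-force ledger filter", {
  for (mode in c("concurrent", "cohort")) {
    cfg <- platform_config(trt_rates = c(0.35, 0.35), rho = 0.3,
                           sharing_mode = mode)
    set.seed(410)
    res <- run_platform(cfg, keep_participants = TRUE)
    for (r in seq_len(nrow(res$analyses))) {
      an <- res$analyses[r, ]
      oracle <- oracle_control_pool(res$participants, res$cohorts,
                                    an$cohort, an$week, 52,
                                    cfg$cohort_size, mode == "concurrent")
      expect_equal(unname(oracle["n"]), an$n_control)
      expect_equal(unname(oracle["s1"]), an$s1_control)
      expect_equal(unname(oracle["s2"]), an$s2_control)
    }
  }
})

test_that("concurrent pooling only ever enlarges the control pool", {
  cfg_c <- platform_config(trt_rates = c(0.35, 0.35), rho = 0.3)
  cfg_k <- platform_config(trt_rates = c(0.35, 0.35), rho = 0.3,
                           sharing_mode = "cohort")
  set.seed(411); res_c <- run_platform(cfg_c)
  set.seed(411); res_k <- run_platform(cfg_k)
  # first analysis of the first cohort sees identical own-cohort data in
  # both modes, so the concurrent pool must be a superset
  a_c <- res_c$analyses[1, ]
  a_k <- res_k$analyses[1, ]
  expect_identical(a_c$n_treatment, a_k$n_treatment)
  expect_gte(a_c$n_control, a_k$n_control)
})

test_that("replicates are bit-reproducible from the seed", {
  cfg <- platform_config(trt_rates = c(0.45, 0.45), rho = 0, seed = 99)
  s1 <- simulate_platform(cfg, n_sims = 8)
  s2 <- simulate_platform(cfg, n_sims = 8)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$replicates, s2$replicates)
})
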