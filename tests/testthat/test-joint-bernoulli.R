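test_that("direct specification fills in the fourth cell and validates", {
  s <- joint_spec_direct(0.25, 0.25, 0.25)
  expect_equal(s$p11, 0.25)

  s <- joint_spec_direct(1, 0, 0)
  expect_equal(s$p11, 0)

  s <- joint_spec_direct(0.42, 0.18, 0.28)
  expect_equal(s$p11, 0.12)
  m <- marginals_of(s)
  expect_equal(unname(m), c(0.30, 0.40))
  # p11 equals the product of the marginals, so the endpoints are independent
  expect_equal(phi_of(s), 0, tolerance = 1e-12)

  expect_error(joint_spec_direct(-0.1, 0.2, 0.2), "p00")
  expect_error(joint_spec_direct(0.5, 0.4, 0.2), "exceed 1")
})

test_that("sensitivity/specificity specification matches its defining identities", {
  s <- joint_spec_sens_spec(0.5, 1, 1)
  expect_equal(c(s$p11, s$p00, s$p10, s$p01), c(0.5, 0.5, 0, 0))

  s <- joint_spec_sens_spec(0.5, 0.8, 0.9)
  expect_equal(c(s$p11, s$p00, s$p10, s$p01), c(0.40, 0.45, 0.10, 0.05))
  # round trip through the diagnostic profile
  d <- diagnostics_of(s)
  expect_equal(d$sens_SL, 0.8)
  expect_equal(d$spec_SL, 0.9)

  # no S successes: p1. = 0 forces the first row to carry all mass
  for (st in list(c(0.3, 0.7), c(1, 0), c(0.5, 0.5))) {
    s <- joint_spec_sens_spec(0, st[1], st[2])
    expect_equal(s$p11 + s$p10, 0)
  }
})

test_that("phi bounds match the closed form and the brute-force table scan", {
  expect_equal(unname(phi_bounds(0.5, 0.5)), c(-1, 1))
  expect_equal(unname(phi_bounds(0.3, 0.4)),
               c(-sqrt(0.12 / 0.42), sqrt(0.18 / 0.28)), tolerance = 1e-12)
  expect_equal(unname(phi_bounds(0.1, 0.9)), c(-1, 1 / 9), tolerance = 1e-12)

  # against exhaustive scan of valid tables across a marginal grid
  grid <- seq(0.05, 0.95, by = 0.1)
  for (a in grid) {
    for (b in grid) {
      bounds <- phi_bounds(a, b)
      rng <- oracle_phi_range(a, b)
      expect_equal(unname(bounds), rng, tolerance = 1e-3)
      expect_true(bounds[1] < 0 && bounds[2] > 0)
    }
  }

  expect_error(phi_bounds(0, 0.5), "strictly inside")
  expect_error(phi_bounds(0.5, 1), "strictly inside")
})

test_that("phi specification hits the requested marginals and correlation", {
  s <- joint_spec_phi(0.5, 0.5, 0)
  expect_equal(s$p11, 0.25)

  s <- joint_spec_phi(0.3, 0.4, 0.7)
  expect_equal(s$p11, 0.7 * sqrt(0.7 * 0.3 * 0.6 * 0.4) + 0.12,
               tolerance = 1e-14)
  expect_equal(unname(marginals_of(s)), c(0.3, 0.4), tolerance = 1e-12)
  expect_equal(phi_of(s), 0.7, tolerance = 1e-12)

  err <- tryCatch(joint_spec_phi(0.3, 0.4, 0.9), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "attainable interval")
  expect_match(conditionMessage(err), "0.8017", fixed = TRUE)
})

test_that("phi round trips across the attainable interval", {
  grid <- seq(0.1, 0.9, by = 0.2)
  for (a in grid) {
    for (b in grid) {
      bounds <- phi_bounds(a, b)
      for (phi in seq(bounds[1] * 0.99, bounds[2] * 0.99, length.out = 5)) {
        expect_equal(phi_of(joint_spec_phi(a, b, phi)), phi,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("latent-normal construction preserves marginals and matches oracles", {
  # independence gives product cells
  s <- joint_spec_latent(0.3, 0.4, 0)
  expect_equal(s$p11, 0.12, tolerance = 1e-9)
  expect_equal(s$p00, 0.42, tolerance = 1e-9)

  # comonotone limit: p11 -> min marginal, off-diagonal -> 0
  s <- joint_spec_latent(0.3, 0.3, 0.9999)
  expect_equal(s$p11, 0.3, tolerance = 1e-2)
  expect_lt(s$p10, 1e-2)

  # quadrant masses against the independent Plackett-integral oracle
  cases <- list(c(0.3, 0.4, 0.7), c(0.1, 0.6, 0.7), c(0.5, 0.5, -0.5),
                c(0.8, 0.2, 0.3), c(0.10, 0.20, -0.3))
  for (cs in cases) {
    s <- joint_spec_latent(cs[1], cs[2], cs[3])
    oc <- oracle_latent_cells(cs[1], cs[2], cs[3])
    expect_equal(c(s$p00, s$p01, s$p10, s$p11), unname(oc),
                 tolerance = 1e-8)
    expect_equal(unname(marginals_of(s)), cs[1:2], tolerance = 1e-9)
  }

  # and against raw latent-normal Monte Carlo
  set.seed(401)
  mc <- oracle_latent_cells_mc(0.3, 0.4, 0.7, n = 1e6)
  s <- joint_spec_latent(0.3, 0.4, 0.7)
  for (cell in names(mc)) {
    se <- sqrt(mc[[cell]] * (1 - mc[[cell]]) / 1e6)
    expect_lt(abs(s[[cell]] - mc[[cell]]), 4 * se + 1e-9)
  }
})

test_that("phi computation flags degenerate tables and scores agreement", {
  expect_equal(phi_of(joint_spec_direct(0.5, 0, 0)), 1)          # p11 = 0.5
  expect_error(phi_of(joint_spec_direct(1, 0, 0)), "degenerate")
  s <- joint_spec_direct(0.42, 0.28, 0.18)                        # p11 = 0.12
  expect_equal(phi_of(s), 0, tolerance = 1e-12)
})

test_that("diagnostic profile inverts the constructions", {
  d <- diagnostics_of(joint_spec_direct(0.5, 0, 0))
  expect_equal(unlist(d[c("sens_SL", "spec_SL", "sens_LS", "spec_LS")]),
               c(sens_SL = 1, spec_SL = 1, sens_LS = 1, spec_LS = 1))

  # independence: conditional equals marginal
  d <- diagnostics_of(joint_spec_direct(0.42, 0.18, 0.28))
  expect_equal(d$sens_SL, 0.4, tolerance = 1e-12)

  expect_error(diagnostics_of(joint_spec_direct(0, 1, 0)), "undefined")
})

test_that("rho-to-phi map is anchored, monotone and bounded", {
  expect_equal(rho_to_phi(0.5, 0.5, 0), 0, tolerance = 1e-9)
  expect_gt(rho_to_phi(0.5, 0.5, 0.9999), 0.98)

  for (ab in list(c(0.3, 0.4), c(0.1, 0.6), c(0.55, 0.55))) {
    rhos <- seq(-0.95, 0.95, by = 0.19)
    phis <- vapply(rhos, function(r) rho_to_phi(ab[1], ab[2], r), 0)
    expect_true(all(diff(phis) > -1e-9))
    bounds <- phi_bounds(ab[1], ab[2])
    expect_true(all(phis >= bounds[1] - 1e-9 & phis <= bounds[2] + 1e-9))
  }

  # spot value against the Plackett oracle
  oc <- oracle_latent_cells(0.1, 0.6, 0.7)
  phi_oracle <- (oc[["p11"]] - 0.1 * 0.6) / sqrt(0.1 * 0.9 * 0.6 * 0.4)
  expect_equal(rho_to_phi(0.1, 0.6, 0.7), phi_oracle, tolerance = 1e-7)
  b <- phi_bounds(0.1, 0.6)
  expect_true(phi_oracle > b[1] && phi_oracle < b[2])
})

test_that("sensitivity/specificity attainability is capped by the marginals", {
  # when p1. < p.1 the latent construction cannot reach spec_SL = 1; when
  # p1. > p.1 it cannot reach sens_SL = 1
  rhos <- seq(-0.9, 0.9, by = 0.3)
  d_less <- vapply(rhos, function(r) {
    diagnostics_of(joint_spec_latent(0.3, 0.6, r))$spec_SL
  }, 0)
  expect_true(all(d_less < 1 - 1e-6))
  d_more <- vapply(rhos, function(r) {
    diagnostics_of(joint_spec_latent(0.6, 0.3, r))$sens_SL
  }, 0)
  expect_true(all(d_more < 1 - 1e-6))
})

test_that("sampling reproduces the cell distribution", {
  s <- joint_spec_latent(0.3, 0.4, 0.3)
  expect_identical(nrow(sample_joint(s, 0)), 0L)

  deg <- joint_spec_direct(0, 0, 0)   # p11 = 1
  x <- sample_joint(deg, 50)
  expect_true(all(x == 1L))

  set.seed(402)
  n <- 1e6
  x <- sample_joint(s, n)
  p11_hat <- mean(x[, "s"] == 1 & x[, "l"] == 1)
  se <- sqrt(s$p11 * (1 - s$p11) / n)
  expect_lt(abs(p11_hat - s$p11), 4 * se)
  expect_lt(abs(mean(x[, "s"]) - 0.3), 4 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(mean(x[, "l"]) - 0.4), 4 * sqrt(0.4 * 0.6 / n))
})
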