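test_that("relative viscosity is a guarded division", {
  expect_equal(relative_viscosity(0.896, 0.881), 0.896 / 0.881)
  expect_equal(relative_viscosity(0.915, 0.897), 1.02007, tolerance = 1e-5)
  expect_equal(relative_viscosity(0.9, 0.9), 1)
  expect_error(relative_viscosity(0.9, 0), "eta0")
})

test_that("Jones-Dole fit equals the closed-form through-origin oracle", {
  cc <- c(0.001, 0.005, 0.012, 0.02, 0.03)
  f <- jones_dole_fit(cc, 1 + 0.5 * cc)
  expect_equal(f$B, 0.5, tolerance = 1e-12)
  expect_equal(f$sd_fit, 0, tolerance = 1e-10)
  expect_true(is.na(f$A))

  set.seed(23)
  for (i in 1:20) {
    x <- sort(runif(sample(3:7, 1), 0.001, 0.05))
    y <- 1 + rnorm(1, 0, 2) * x + rnorm(length(x), 0, 1e-3)
    f <- jones_dole_fit(x, y)
    expect_equal(f$B, origin_slope_oracle(x, y - 1), tolerance = 1e-12)
    # with the Falkenhagen term: two-regressor normal-equation oracle
    fa <- jones_dole_fit(x, y, include_A = TRUE)
    o <- two_term_origin_oracle(sqrt(x), x, y - 1)
    expect_equal(unname(fa$A), unname(o[1]), tolerance = 1e-10)
    expect_equal(unname(fa$B), unname(o[2]), tolerance = 1e-10)
  }

  expect_error(jones_dole_fit(c(0.01, 0.02), c(1.1, 1.2)), "insufficient")
  expect_error(jones_dole_fit(c(-0.01, 0.02, 0.03), c(1, 1.1, 1.2)),
               "concentrations")
})

test_that("B is invariant to rescaling viscosities jointly", {
  m <- c(0.002, 0.008, 0.015, 0.025, 0.03)
  eta0 <- 0.881
  eta <- eta0 * (1 + 0.85 * m) + c(1, -1, 2, 0, -2) * 1e-4
  b1 <- jones_dole_fit(m, relative_viscosity(eta, eta0))$B
  b2 <- jones_dole_fit(m, relative_viscosity(10 * eta, 10 * eta0))$B
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("B sign and magnitude recover from synthetic series", {
  m <- seq(0.001, 0.03, length.out = 5)
  # noiseless, unrounded: exact recovery
  tr <- synthetic_truth(B = -2.7, seed = 5, noise_sd = list(viscosity = 0),
                        rounding = list(viscosity = NA))
  s <- generate_viscosity_series(tr, m)
  pts <- solute_points(s)
  b <- jones_dole_fit(molality_to_molarity(pts$molality, tr$rho0),
                      relative_viscosity(pts$value, solvent_reference(s)))$B
  expect_equal(b, -2.7, tolerance = 1e-8)

  # at measurement noise + 3-d.p. rounding: sign recovery above 95%
  for (B_true in c(-2, -1, 1, 2)) {
    hits <- 0L
    for (i in 1:500) {
      tr <- synthetic_truth(B = B_true, seed = 7000 + i,
                            noise_sd = list(viscosity = 0.002))
      s <- generate_viscosity_series(tr, m)
      pts <- solute_points(s)
      bh <- jones_dole_fit(molality_to_molarity(pts$molality, tr$rho0),
                           relative_viscosity(pts$value,
                                              solvent_reference(s)))$B
      hits <- hits + (sign(bh) == sign(B_true))
    }
    expect_gt(hits / 500, 0.95)
  }
})

test_that("Falkenhagen estimate is centered on zero when truth has A = 0", {
  m <- seq(0.002, 0.03, length.out = 6)
  n_rep <- 300
  a_hat <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- synthetic_truth(A = 0, B = 1, seed = 400 + i,
                          noise_sd = list(viscosity = 0.001),
                          rounding = list(viscosity = NA))
    s <- generate_viscosity_series(tr, m)
    pts <- solute_points(s)
    a_hat[i] <- jones_dole_fit(molality_to_molarity(pts$molality, tr$rho0),
                               relative_viscosity(pts$value,
                                                  solvent_reference(s)),
                               include_A = TRUE)$A
  }
  mc_se <- sd(a_hat) / sqrt(n_rep)
  expect_lt(abs(mean(a_hat)), 2 * mc_se + 1e-12)
})

test_that("viscometric analysis demands a solvent reference", {
  vser <- fixture_series("viscosity")
  r <- viscosity_analysis(vser[["betaine 0.01"]])
  expect_s3_class(r, "viscosity_result")
  expect_gt(r$B, 0)   # betaine series are kosmotropic in sign
  expect_false(r$eta0_supplied)
  expect_equal(r$per_point$eta_rel, r$per_point$eta / 0.881)

  # ionic-liquid series: reference garbled in the source, must be supplied
  expect_error(viscosity_analysis(vser[["il 0.05"]]), "missing")
  r2 <- viscosity_analysis(vser[["il 0.05"]], eta0 = 0.8988)
  expect_true(r2$eta0_supplied)

  # molarity mode switches the regressor
  r3 <- viscosity_analysis(vser[["betaine 0.01"]], molarity_mode = "exact",
                           M_solute = GBP_M)
  expect_true(all(r3$per_point$c < r$per_point$c))
})
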