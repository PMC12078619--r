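test_that("apparent molar volume matches hand arithmetic and limits", {
  # zero density increment leaves only the intrinsic M/rho term
  expect_equal(apparent_molar_volume(0.02, 0.999, 0.999, 171.237),
               171.237 / 0.999)
  # hand evaluation: 100/1 - 1000*0.001/(0.01*1*0.999)
  expect_equal(apparent_molar_volume(0.01, 1.00000, 0.99900, 100.0),
               100 - 1 / (0.01 * 0.999), tolerance = 1e-12)
  expect_lt(apparent_molar_volume(0.01, 1.00000, 0.99900, 100.0), 0)
  # printed reference value, limited by 5-d.p. density rounding
  v <- apparent_molar_volume(0.0293, 0.99907, 0.99819, GBP_M)
  expect_equal(v, 141.21, tolerance = 1e-3)
  expect_error(apparent_molar_volume(0, 0.999, 0.998, 171.237),
               "zero molality")
  expect_error(apparent_molar_volume(0.01, -1, 0.998, 171.237), "> 0")
})

test_that("Masson fit equals the closed-form normal-equation oracle", {
  # exact recovery on a noiseless line
  m <- c(0.002, 0.005, 0.01, 0.02, 0.03)
  f <- masson_fit(m, 140 + 50 * m)
  expect_equal(f$Vphi0, 140, tolerance = 1e-10)
  expect_equal(f$Sv, 50, tolerance = 1e-9)
  expect_equal(f$sd_fit, 0, tolerance = 1e-9)

  # random instances against the independent oracle
  set.seed(11)
  for (i in 1:20) {
    mm <- sort(runif(sample(3:8, 1), 0.001, 0.05))
    while (length(unique(mm)) < 3) mm <- sort(runif(5, 0.001, 0.05))
    vv <- 140 + rnorm(1, 0, 30) * mm + rnorm(length(mm), 0, 0.5)
    f <- masson_fit(mm, vv)
    o <- ols_oracle(mm, vv)
    expect_equal(f$Vphi0, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(f$Sv, unname(o["slope"]), tolerance = 1e-10)
  }

  expect_error(masson_fit(c(0.01, 0.02), c(140, 141)), "insufficient")
  expect_error(masson_fit(rep(0.01, 4), c(140, 141, 142, 141)),
               "rank|duplicate")
  # molality floor drops low-m points
  f2 <- masson_fit(c(0.001, 0.005, 0.01, 0.02, 0.03),
                   c(120, 140.25, 140.5, 141, 141.5), min_molality = 0.002)
  expect_equal(f2$n, 4)
  expect_equal(f2$Vphi0, 140, tolerance = 1e-8)
})

test_that("Masson slope of the printed betaine series matches its table", {
  # intercepts are known not to reproduce (fits were on unrounded data);
  # the slope does to well under a percent
  d <- fixture_series("density")[["betaine 0.01"]]
  vp <- attr(d, "vphi_printed")
  f <- masson_fit(vp$m, vp$vphi_printed)
  expect_equal(f$Sv, 64.835, tolerance = 0.005)
})

test_that("ASV and taste classification follow the reference bands", {
  expect_equal(apparent_specific_volume(143.048, GBP_M), 0.835,
               tolerance = 1e-3)
  expect_equal(apparent_specific_volume(143.911, GBP_M), 0.840,
               tolerance = 1e-3)
  expect_equal(apparent_specific_volume(171.237, 171.237), 1.0)

  # brute-force nearest-center oracle over a grid
  centers <- c(salty = 0.33, sour = 0.52, sweet = 0.72, bitter = 0.93)
  grid <- seq(0.05, 1.5, by = 0.025)
  got <- classify_taste(grid)
  for (i in seq_along(grid)) {
    d <- abs(grid[i] - centers)
    want <- names(centers)[max(which(d == min(d)))]
    expect_equal(as.character(got$taste[i]), want)
  }
  expect_equal(got$sweet_window, grid > 0.5 & grid < 0.7)

  # study-range value classifies bitter, outside the sweetness window
  r <- classify_taste(0.835)
  expect_equal(as.character(r$taste), "bitter")
  expect_false(r$sweet_window)
  expect_equal(as.character(classify_taste(0.33)$taste), "salty")
  r2 <- classify_taste(0.625)
  expect_equal(as.character(r2$taste), "sweet")
  expect_true(r2$sweet_window)
  expect_error(classify_taste(-0.1), "> 0")
})

test_that("hydration-number decomposition reproduces its algebra", {
  h <- hydration_number(138.677, GBP_M, GBP_DCRYST)
  # independent evaluation of the chain
  v_cryst <- GBP_M / GBP_DCRYST
  v_int <- (0.7 / 0.634) * v_cryst
  expect_equal(h$Vphi0_cryst, v_cryst)
  expect_equal(h$Vphi0_int, v_int)
  expect_gt(h$Vphi0_int, h$Vphi0_cryst)
  expect_equal(h$n_H, (138.677 - v_int) / (-3.3), tolerance = 1e-12)
  expect_equal(h$n_H, 3.556, tolerance = 2e-3)
  expect_equal(hydration_number(142.407, GBP_M, GBP_DCRYST)$n_H, 2.425,
               tolerance = 2e-3)
  # zero electrostriction gives zero hydration
  expect_equal(hydration_number(v_int, GBP_M, GBP_DCRYST)$n_H, 0)
  expect_error(hydration_number(140, GBP_M, d_cryst = -1), "> 0")

  # strictly decreasing in Vphi0 at fixed M and d_cryst
  grid <- seq(120, 160, by = 0.5)
  nh <- hydration_number(grid, GBP_M, GBP_DCRYST)$n_H
  expect_true(all(diff(nh) < 0))
})

test_that("Vphi uncertainty shows the low-molality rounding blow-up", {
  # 5-d.p. printed densities: worst-case propagated error huge at m = 0.001,
  # small at m = 0.03
  u_low <- vphi_uncertainty(0.001, 0.99822, 0.99819, GBP_M, mode = "rounding")
  u_high <- vphi_uncertainty(0.03, 0.99907, 0.99819, GBP_M, mode = "rounding")
  expect_gt(u_low, 10)
  expect_lt(u_high, 0.5)
  # gaussian mode scales linearly in sigma
  g1 <- vphi_uncertainty(0.01, 0.999, 0.998, GBP_M, sigma_rho = 4e-5)
  g2 <- vphi_uncertainty(0.01, 0.999, 0.998, GBP_M, sigma_rho = 8e-5)
  expect_equal(g2 / g1, 2, tolerance = 1e-12)
})

test_that("volumetric stage recovers synthetic truth within its errors", {
  # 500 replicates at instrument density noise: intercept bias below its mean
  # standard error, propagated-CI coverage near nominal
  m <- seq(0.005, 0.03, length.out = 6)
  n_rep <- 500
  est <- se_ols <- numeric(n_rep)
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- synthetic_truth(Vphi0 = 142.9, Sv = 8.2, seed = 1000 + i,
                          rounding = list(density = NA))
    s <- generate_density_series(tr, m)
    pts <- solute_points(s)
    rho0 <- solvent_reference(s)
    vphi <- apparent_molar_volume(pts$molality, pts$value, rho0, tr$M)
    u <- vphi_uncertainty(pts$molality, pts$value, rho0, tr$M,
                          sigma_rho = 4e-5)
    f <- masson_fit(pts$molality, vphi, vphi_u = u)
    est[i] <- f$Vphi0
    se_ols[i] <- f$Vphi0_se
    cover[i] <- abs(f$Vphi0 - 142.9) < 1.96 * f$Vphi0_se_prop
  }
  expect_lt(abs(mean(est) - 142.9), mean(se_ols))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("full volumetric analysis chain is internally consistent", {
  d <- fixture_series("density")[["betaine 0.05"]]
  r <- volumetric_analysis(d, M = GBP_M)
  expect_s3_class(r, "volumetric_result")
  # ASV column is Vphi/M pointwise
  expect_equal(r$per_point$ASV, r$per_point$Vphi / GBP_M)
  # hydration decomposition invariants
  expect_equal(r$hydration$Vphi0_int,
               (0.7 / 0.634) * r$hydration$Vphi0_cryst)
  expect_equal(r$hydration$n_H, r$hydration$Vphi0_elect / (-3.3))
  expect_equal(r$taste, "bitter")
  expect_error(volumetric_analysis(fixture_series("viscosity")[[1]], GBP_M),
               "density series")
})
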