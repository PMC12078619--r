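test_that("surface pressure is the reference difference, flagged if negative", {
  expect_equal(surface_pressure(72.0, 56.3), 15.7)
  expect_equal(surface_pressure(65.4, 56.3), 9.1)
  expect_equal(surface_pressure(70, 70), 0)
  expect_warning(surface_pressure(60, 61), "negative surface pressure")
  expect_error(surface_pressure(-1, 60), "> 0")
})

test_that("Gibbs surface excess recovers a known isotherm slope", {
  C <- c(0.002, 0.004, 0.006, 0.009, 0.012)
  # gamma = a - b ln C with b = 2.4776e-3 N/m -> Gamma = b / RT = 1.000e-6
  gam_mN <- 60 - 2.4776 * log(C)
  g <- gibbs_surface_excess(C, gam_mN, temperature = 298, n_species = 1)
  expect_equal(g$Gamma_max, 2.4776e-3 / (8.314 * 298), tolerance = 1e-10)
  expect_equal(g$Gamma_max, 1.000e-6, tolerance = 1e-4)
  # flat isotherm: zero excess
  expect_equal(gibbs_surface_excess(C, rep(55, 5), 298)$Gamma_max, 0)
  # doubling the dissociation number halves the excess
  expect_equal(gibbs_surface_excess(C, gam_mN, 298, n_species = 2)$Gamma_max,
               g$Gamma_max / 2)
  expect_error(gibbs_surface_excess(C[1:2], gam_mN[1:2]), "window too small")
  expect_warning(gibbs_surface_excess(C, gam_mN, cmc = 0.005), "spans the CMC")

  # recovery of a tabulated-magnitude excess from its own forward model
  G_true <- 1.858e-6
  slope <- -G_true * 8.314 * 298           # N/m per ln-unit
  gam2 <- 70 + slope * 1e3 * log(C / C[1])
  g2 <- gibbs_surface_excess(C, gam2, 298)
  expect_equal(g2$Gamma_max, G_true, tolerance = 1e-2)
})

test_that("minimum molecular area inverts the surface excess", {
  expect_equal(min_area_per_molecule(2.039e-3), 0.081, tolerance = 1e-2)
  expect_equal(min_area_per_molecule(1.858e-3), 0.089, tolerance = 1e-2)
  expect_equal(min_area_per_molecule(1e20 / 6.022e23), 1.0, tolerance = 1e-12)
  # algebraic inverse pair over a grid
  G <- 10^seq(-8, -2, length.out = 25)
  expect_equal(min_area_per_molecule(G) * G * 6.022e23, rep(1e20, 25))
  expect_error(min_area_per_molecule(0), "Gamma_max")
  expect_error(min_area_per_molecule(-1e-6), "Gamma_max")
})

test_that("breakpoint detection finds an exact two-segment isotherm", {
  C <- sort(unique(c(exp(seq(log(0.002), log(0.08), length.out = 9)), 0.0125)))
  tr <- synthetic_truth(cmc = 0.0125, gamma0 = 72,
                        pre_slope = -9 / log(10), post_slope = 0, seed = 1,
                        noise_sd = list(surface_tension = 0),
                        rounding = list(surface_tension = NA))
  iso <- generate_tension_isotherm(tr, C)
  d <- detect_cmc(iso$points$molality, iso$points$value)
  expect_true(d$detected)
  expect_equal(d$cmc, 0.0125, tolerance = 1e-9)
  expect_equal(d$slope_post, 0, tolerance = 1e-9)
  # per-decade pre slope on the log10 axis
  expect_equal(d$slope_pre, -9, tolerance = 1e-6)

  # a single-slope isotherm has no detectable CMC (a result, not an error)
  C2 <- exp(seq(log(0.002), log(0.05), length.out = 9))
  d2 <- detect_cmc(C2, 70 - 5 * log10(C2))
  expect_false(d2$detected)
  expect_true(is.na(d2$cmc))
  expect_error(detect_cmc(C2[1:4], (70 - 5 * log10(C2))[1:4]), ">= 5 points")
})

test_that("breakpoint detection is scale-equivariant and shift-invariant", {
  C <- exp(seq(log(0.003), log(0.06), length.out = 10))
  tr <- synthetic_truth(cmc = 0.015, gamma0 = 70, pre_slope = -4,
                        post_slope = -0.4, seed = 9,
                        noise_sd = list(surface_tension = 0.01),
                        rounding = list(surface_tension = NA))
  iso <- generate_tension_isotherm(tr, C)
  g <- iso$points$value
  d0 <- detect_cmc(C, g)
  # concentration rescaling rescales the CMC by the same factor
  d_scaled <- detect_cmc(3.7 * C, g)
  expect_equal(d_scaled$cmc, 3.7 * d0$cmc, tolerance = 1e-9)
  # constant tension offset leaves the CMC, shifts gamma_cmc by the offset
  d_shift <- detect_cmc(C, g + 5)
  expect_equal(d_shift$cmc, d0$cmc, tolerance = 1e-12)
  expect_equal(d_shift$gamma_cmc, d0$gamma_cmc + 5, tolerance = 1e-9)
})

test_that("CMC recovery at tensiometer noise stays within a few percent", {
  C <- exp(seq(log(0.002), log(0.08), length.out = 9))
  err <- numeric(200)
  for (i in 1:200) {
    tr <- synthetic_truth(cmc = 0.0125, gamma0 = 72,
                          pre_slope = -9 / log(10), post_slope = 0,
                          seed = 100 + i)
    iso <- generate_tension_isotherm(tr, C)
    d <- detect_cmc(iso$points$molality, iso$points$value)
    err[i] <- abs(d$cmc - 0.0125) / 0.0125
  }
  expect_lt(median(err), 0.05)
})

test_that("micellization free energy follows RT ln X", {
  k <- st_constants()
  # independent symbolic evaluation
  for (cmc in c(0.0148, 0.0125, 0.005)) {
    X <- cmc / (cmc + 1000 / k$M_water)
    expect_equal(delta_g_mic(cmc, 298), 8.314 * 298 * log(X) / 1000,
                 tolerance = 1e-9)
  }
  expect_equal(delta_g_mic(0.0148, 298), -20.39, tolerance = 1e-3)
  expect_lt(delta_g_mic(0.04, 298), 0)
  # X -> 1 limit drives the free energy to zero
  expect_equal(delta_g_mic(1e9, 298), 0, tolerance = 1e-4)
  expect_error(delta_g_mic(0), "> 0")
})

test_that("adsorption free energy supports both sign conventions", {
  # tabulation convention reproduces the printed ladder
  expect_equal(delta_g_ads(-21.369, 15.7, 1.858e-6), -12.917,
               tolerance = 3e-4)
  # work term vanishes with the surface pressure
  expect_equal(delta_g_ads(-20, 0, 1.8e-6), -20)
  # literal (textbook) convention subtracts the work term
  expect_equal(delta_g_ads(-21.369, 15.7, 1.858e-6, "literal"),
               -21.369 - 0.0157 / 1.858e-6 / 1000, tolerance = 1e-9)
  expect_equal(delta_g_ads(-21.369, 15.7, 1.858e-6, "literal"), -29.82,
               tolerance = 1e-3)
  expect_error(delta_g_ads(-20, 10, 0), "non-zero")
})

test_that("end-to-end isotherm analysis recovers generating truth", {
  C <- exp(seq(log(0.002), log(0.08), length.out = 11))
  tr <- synthetic_truth(cmc = 0.0125, gamma0 = 72, pre_slope = -4.6,
                        post_slope = -0.2, seed = 77)
  n_rep <- 200
  cmc_err <- gam_err <- dg_err <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tri <- synthetic_truth(cmc = 0.0125, gamma0 = 72, pre_slope = -4.6,
                           post_slope = -0.2, seed = 500 + i)
    iso <- generate_tension_isotherm(tri, C)
    r <- suppressWarnings(isotherm_analysis(iso, gamma0 = 72))
    cmc_err[i] <- abs(r$cmc - tri$cmc) / tri$cmc
    gam_err[i] <- abs(r$Gamma_max - tri$Gamma_max_implied) /
      tri$Gamma_max_implied
    dg_err[i] <- abs(r$dG_mic_at_cmc - delta_g_mic(tri$cmc, 298))
  }
  expect_lt(median(cmc_err), 0.05)
  expect_lt(median(gam_err), 0.05)
  expect_lt(median(dg_err), 0.5)

  # per-point ladder invariants on one realization
  iso <- generate_tension_isotherm(tr, C)
  r <- suppressWarnings(isotherm_analysis(iso, gamma0 = 72))
  expect_equal(r$per_point$Pi, 72 - r$per_point$gamma)
  pos <- which(r$per_point$Gamma_local > 0)
  expect_equal(r$per_point$A_min_local[pos] * r$per_point$Gamma_local[pos] *
                 6.022e23, rep(1e20, length(pos)))
  expect_equal(r$A_min * r$Gamma_max * 6.022e23, 1e20)
  expect_equal(r$per_point$dG_mic, delta_g_mic(C, 298))
})
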