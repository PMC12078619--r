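# Independent closed-form oracles and small builders shared across tests.

# straight-line OLS by explicit normal equations (independent of lm)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# through-origin OLS slope, closed form
origin_slope_oracle <- function(x, y) sum(x * y) / sum(x^2)

# two-regressor no-intercept OLS by explicit normal equations
two_term_origin_oracle <- function(x1, x2, y) {
  X <- cbind(x1, x2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

make_density_series <- function(m, rho, rho0, additive = "betaine",
                                additive_m = 0.01) {
  concentration_series(c(0, m), c(rho0, rho), property = "density",
                       solvent = solvent_spec(additive, additive_m, 298))
}

GBP_M <- 171.237       # gabapentin molar mass, g/mol
GBP_DCRYST <- 1.257    # gabapentin crystalline density, g/cm^3
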