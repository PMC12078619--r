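#' Relative viscosity
#'
#' eta_r = eta / eta0, the solution viscosity scaled by the solvent viscosity.
#'
#' @param eta solution viscosity, mPa s (vectorized).
#' @param eta0 solvent viscosity, mPa s (> 0).
#' @return dimensionless relative viscosity.
#' @export
relative_viscosity <- function(eta, eta0) {
  if (any(!is.finite(eta0)) || any(eta0 <= 0))
    stop("solvent viscosity eta0 must be finite and > 0")
  eta / eta0
}

#' Fit the Jones-Dole equation
#'
#' The Jones-Dole expansion \eqn{\eta_r = 1 + A \sqrt{c} + B c} relates the
#' relative viscosity to molar concentration; B > 0 marks structure-making
#' (kosmotropic) solutes, B < 0 structure-breaking ones. The default fit drops
#' the Falkenhagen term A (negligible for weak solute-solute interactions) and
#' regresses (eta_r - 1) on c through the origin, the literal form of the
#' simplified equation. With `include_A = TRUE` the regression is on
#' (sqrt(c), c) without intercept. A free intercept is available as a
#' diagnostic only.
#'
#' @param c molar concentrations, mol dm^-3 (>= 3 distinct positive values).
#' @param eta_rel relative viscosities.
#' @param include_A also estimate the Falkenhagen coefficient A.
#' @param free_intercept add an intercept as a lack-of-fit diagnostic
#'   (not part of the model; default `FALSE`).
#' @return list with `B` (dm^3 mol^-1), `B_se`, `A` (dm^3/2 mol^-1/2, `NA`
#'   unless requested), `A_se`, `intercept` (`NA` unless requested), `sd_fit`,
#'   `n`, and the `lm` fit.
#' @export
#' @examples
#' cc <- c(0.005, 0.01, 0.02, 0.03)
#' jones_dole_fit(cc, 1 + 0.5 * cc)$B  # 0.5
jones_dole_fit <- function(c, eta_rel, include_A = FALSE,
                           free_intercept = FALSE) {
  if (length(c) != length(eta_rel)) stop("'c' and 'eta_rel' lengths differ")
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0))
    stop("concentrations must be finite and > 0")
  if (length(c) < 3L || length(unique(c)) < 3L)
    stop("insufficient data: Jones-Dole fit needs >= 3 distinct points")
  y <- eta_rel - 1
  df <- data.frame(y = y, c = c, sqrtc = sqrt(c))
  form <- if (include_A && free_intercept) y ~ sqrtc + c
          else if (include_A) y ~ 0 + sqrtc + c
          else if (free_intercept) y ~ c
          else y ~ 0 + c
  fit <- stats::lm(form, data = df)
  smry <- suppressWarnings(summary(fit))
  sm <- smry$coefficients
  pick <- function(term) {
    if (term %in% rownames(sm))
      c(sm[term, "Estimate"], sm[term, "Std. Error"])
    else c(NA_real_, NA_real_)
  }
  b <- pick("c"); a <- pick("sqrtc"); ic <- pick("(Intercept)")
  list(B = b[1], B_se = b[2], A = a[1], A_se = a[2],
       intercept = ic[1], intercept_se = ic[2],
       sd_fit = smry$sigma, n = length(c), fit = fit)
}

#' Full viscometric analysis of a viscosity series
#'
#' Converts molalities to molarities, forms relative viscosities against the
#' solvent reference and fits the Jones-Dole equation.
#'
#' @param series a viscosity [concentration_series()].
#' @param eta0 solvent viscosity override, mPa s; required when the series
#'   carries no molality-0 reference (it is then flagged as supplied).
#' @param rho0 solvent density for the molality-to-molarity conversion,
#'   g cm^-3 (defaults to the solvent spec's density; 1.0 if absent, with the
#'   sub-percent dilute-regime error that implies).
#' @param molarity_mode `"dilute"` or `"exact"` (see
#'   [molality_to_molarity()]).
#' @param M_solute solute molar mass, needed for exact conversion.
#' @param include_A fit the Falkenhagen A term as well.
#' @return object of class `"viscosity_result"`: list with `per_point`
#'   (m, c, eta, eta_rel), `A`, `B`, their standard errors, `sd_fit`,
#'   `eta0`, `eta0_supplied` flag and metadata.
#' @export
viscosity_analysis <- function(series, eta0 = NULL, rho0 = NULL,
                               molarity_mode = c("dilute", "exact"),
                               M_solute = NULL, include_A = FALSE) {
  stopifnot(inherits(series, "concentration_series"))
  molarity_mode <- match.arg(molarity_mode)
  if (series$property != "viscosity")
    stop("viscometric analysis needs a viscosity series")
  eta0_supplied <- !is.null(eta0)
  if (is.null(eta0)) eta0 <- solvent_reference(series)
  if (is.null(eta0) || is.na(eta0))
    stop("solvent viscosity eta0 is missing for this series; ",
         "supply it explicitly via 'eta0'")
  if (is.null(rho0)) rho0 <- series$solvent$density
  if (is.null(rho0) || is.na(rho0)) rho0 <- 1.0
  pts <- solute_points(series)
  if (nrow(pts) < 3L) stop("insufficient data: need >= 3 solute points")
  cc <- molality_to_molarity(pts$molality, rho0, M_solute, molarity_mode)
  eta_rel <- relative_viscosity(pts$value, eta0)
  fit <- jones_dole_fit(cc, eta_rel, include_A = include_A)
  structure(list(
    per_point = data.frame(m = pts$molality, c = cc, eta = pts$value,
                           eta_rel = eta_rel),
    A = fit$A, A_se = fit$A_se, B = fit$B, B_se = fit$B_se,
    sd_fit = fit$sd_fit, eta0 = eta0, eta0_supplied = eta0_supplied,
    molarity_mode = molarity_mode, solvent = series$solvent
  ), class = "viscosity_result")
}

#' @export
print.viscosity_result <- function(x, ...) {
  cat(sprintf("<viscosity_result> %s %.4g mol/kg\n",
              x$solvent$additive_name, x$solvent$additive_molality))
  cat(sprintf("  B = %.3f +/- %.3f dm^3/mol (eta0 = %.4g%s)\n",
              x$B, x$B_se, x$eta0,
              if (x$eta0_supplied) ", supplied" else ""))
  if (!is.na(x$A)) cat(sprintf("  A = %.4f +/- %.4f\n", x$A, x$A_se))
  invisible(x)
}
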