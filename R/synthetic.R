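#' Ground-truth parameter record for synthetic measurement series
#'
#' Collects the generating parameters of one synthetic campaign so that every
#' generated dataset is paired with the truth needed for parameter-recovery
#' tests. Noise standard deviations default to the instrument standard
#' uncertainties of the reference study's bench (densitometer 4e-5 g cm^-3,
#' rolling-ball viscometer 0.001 mPa s, Wilhelmy-plate tensiometer
#' 0.01 mN m^-1) and rounding defaults to the printed table precision
#' (5 / 3 / 1 decimals). Both effects can be switched off independently.
#'
#' @param Vphi0,Sv volumetric truth: Masson intercept (cm^3 mol^-1) and slope.
#' @param M,rho0 solute molar mass (g mol^-1) and solvent density (g cm^-3).
#' @param A,B,eta0 viscometric truth: Jones-Dole coefficients and solvent
#'   viscosity (mPa s).
#' @param cmc,gamma0,pre_slope,post_slope interfacial truth: breakpoint
#'   (mol kg^-1), solvent surface tension (mN m^-1) and segment slopes in
#'   mN m^-1 per ln-unit of concentration.
#' @param temperature,n_species conditions for the implied Gibbs excess.
#' @param noise_sd named noise overrides (`density`, `viscosity`,
#'   `surface_tension`); 0 disables noise.
#' @param rounding named decimal-place overrides; `NA` disables rounding.
#' @param seed integer seed; fully determines the generated series.
#' @return object of class `"synthetic_truth"`; includes `Gamma_max_implied`
#'   = -pre_slope(N m^-1) / (n R T), recorded at construction rather than
#'   re-derived downstream.
#' @export
synthetic_truth <- function(Vphi0 = 140, Sv = 50, M = 171.237, rho0 = 0.99819,
                            A = 0, B = 0.85, eta0 = 0.881,
                            cmc = 0.0125, gamma0 = 72.0,
                            pre_slope = -9 / log(10), post_slope = 0,
                            temperature = 298, n_species = 1,
                            noise_sd = list(), rounding = list(),
                            seed = 1L) {
  ns <- list(density = 4e-5, viscosity = 0.001, surface_tension = 0.01)
  rd <- list(density = 5L, viscosity = 3L, surface_tension = 1L)
  for (nm in names(noise_sd)) {
    if (!nm %in% names(ns)) stop("unknown noise_sd name: ", nm)
    ns[[nm]] <- noise_sd[[nm]]
  }
  for (nm in names(rounding)) {
    if (!nm %in% names(rd)) stop("unknown rounding name: ", nm)
    rd[[nm]] <- rounding[[nm]]
  }
  k <- st_constants()
  structure(list(
    Vphi0 = Vphi0, Sv = Sv, M = M, rho0 = rho0,
    A = A, B = B, eta0 = eta0,
    cmc = cmc, gamma0 = gamma0, pre_slope = pre_slope,
    post_slope = post_slope, temperature = temperature,
    n_species = n_species,
    Gamma_max_implied = -(pre_slope * 1e-3) / (n_species * k$R * temperature),
    noise_sd = ns, rounding = rd, seed = as.integer(seed)
  ), class = "synthetic_truth")
}

.with_truth_seed <- function(truth, offset) {
  set.seed(truth$seed + offset)  # per-series derived substream
}

.apply_noise_round <- function(x, sd, digits) {
  if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
  if (!is.na(digits)) x <- round(x, digits)
  x
}

#' Generate a synthetic density series
#'
#' Forward model: Vphi(m) = Vphi0 + Sv m is inverted to the unique density
#' satisfying the apparent-molar-volume relation,
#' rho = (M + 1000/m) / (Vphi + 1000 / (m rho0)), then Gaussian instrument
#' noise and decimal rounding are applied. The molality-0 solvent reference
#' row is included.
#'
#' @param truth a [synthetic_truth()].
#' @param m_grid positive increasing solute molalities, mol kg^-1.
#' @return a density [concentration_series()].
#' @export
generate_density_series <- function(truth, m_grid) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(m_grid <= 0) || is.unsorted(m_grid, strictly = TRUE))
    stop("'m_grid' must be positive and strictly increasing")
  vphi <- truth$Vphi0 + truth$Sv * m_grid
  rho <- (truth$M + 1000 / m_grid) / (vphi + 1000 / (m_grid * truth$rho0))
  if (any(rho <= 0))
    stop("generation error: parameters yield non-positive density")
  .with_truth_seed(truth, 101L)
  # the solvent reference row is a measurement like any other
  both <- .apply_noise_round(c(truth$rho0, rho), truth$noise_sd$density,
                             truth$rounding$density)
  rho0 <- both[1]; rho <- both[-1]
  concentration_series(
    c(0, m_grid), c(rho0, rho), property = "density",
    solvent = solvent_spec("synthetic", 0, truth$temperature,
                           density = rho0),
    uncertainty = max(truth$noise_sd$density, 4e-5)
  )
}

#' Generate a synthetic viscosity series
#'
#' Forward Jones-Dole model eta = eta0 (1 + A sqrt(c) + B c) with c from the
#' dilute molality-to-molarity conversion, plus Gaussian noise and rounding.
#' Draws yielding non-positive viscosities are resampled a bounded number of
#' times before erroring.
#'
#' @inheritParams generate_density_series
#' @return a viscosity [concentration_series()].
#' @export
generate_viscosity_series <- function(truth, m_grid) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(m_grid <= 0) || is.unsorted(m_grid, strictly = TRUE))
    stop("'m_grid' must be positive and strictly increasing")
  cc <- molality_to_molarity(m_grid, truth$rho0)
  eta_clean <- truth$eta0 * (1 + truth$A * sqrt(cc) + truth$B * cc)
  if (any(eta_clean <= 0))
    stop("generation error: parameters yield non-positive viscosity")
  .with_truth_seed(truth, 202L)
  for (try in 1:25) {
    eta <- .apply_noise_round(eta_clean, truth$noise_sd$viscosity,
                              truth$rounding$viscosity)
    if (all(eta > 0)) break
    if (try == 25) stop("generation error: viscosity non-positive after ",
                        "bounded resampling")
  }
  eta0 <- if (is.na(truth$rounding$viscosity)) truth$eta0
          else round(truth$eta0, truth$rounding$viscosity)
  concentration_series(
    c(0, m_grid), c(eta0, eta), property = "viscosity",
    solvent = solvent_spec("synthetic", 0, truth$temperature,
                           viscosity = eta0),
    uncertainty = max(truth$noise_sd$viscosity, 0.001)
  )
}

#' Generate a synthetic surface-tension isotherm
#'
#' Two-regime forward model: below the CMC the tension falls linearly in
#' ln C from gamma0 at the smallest grid point (the ln reference, an
#' arbitrary constant absorbed by gamma0), with slope `pre_slope`
#' (mN m^-1 per ln-unit); above the CMC the line continues continuously with
#' slope `post_slope`. Gaussian tensiometer noise and display rounding are
#' then applied. The grid must span the CMC with at least two points on each
#' side.
#'
#' @param truth a [synthetic_truth()].
#' @param C_grid positive increasing additive molalities, mol kg^-1.
#' @return a surface-tension [concentration_series()] over additive molality;
#'   its solvent spec carries gamma0 (the value at the reference
#'   concentration, not a molality-0 row, since tension diverges
#'   logarithmically at C = 0).
#' @export
generate_tension_isotherm <- function(truth, C_grid) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(C_grid <= 0) || is.unsorted(C_grid, strictly = TRUE))
    stop("'C_grid' must be positive and strictly increasing")
  if (sum(C_grid < truth$cmc) < 2 || sum(C_grid > truth$cmc) < 2)
    stop("grid must span the CMC with >= 2 points per side")
  C_ref <- C_grid[1]
  lc <- log(C_grid / C_ref)
  lb <- log(truth$cmc / C_ref)
  gamma <- ifelse(lc <= lb,
                  truth$gamma0 + truth$pre_slope * lc,
                  truth$gamma0 + truth$pre_slope * lb +
                    truth$post_slope * (lc - lb))
  .with_truth_seed(truth, 303L)
  gamma <- .apply_noise_round(gamma, truth$noise_sd$surface_tension,
                              truth$rounding$surface_tension)
  if (any(gamma <= 0))
    stop("generation error: parameters yield non-positive surface tension")
  concentration_series(
    C_grid, gamma, property = "surface_tension",
    solvent = solvent_spec("synthetic", 0, truth$temperature,
                           surface_tension = truth$gamma0),
    uncertainty = max(truth$noise_sd$surface_tension, 0.01)
  )
}
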