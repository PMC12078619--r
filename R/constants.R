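#' Physical constants used throughout the package
#'
#' Returns the constant set used by every analysis stage. Values follow the
#' conventions of solution thermodynamics at the bench: densities in g cm^-3,
#' molalities in mol kg^-1, molar volumes in cm^3 mol^-1, surface tensions in
#' mN m^-1, energies in kJ mol^-1. Conversions to SI happen only inside the
#' formulas that need them.
#'
#' @param overrides named list of constants to override (e.g.
#'   `list(temperature = 310)` is not a constant here, but `M_water` or
#'   `V_E_minus_V_B` are). Unknown names are an error.
#' @param file optional path to a YAML or JSON file whose top-level keys
#'   override constants; `overrides` is applied after the file.
#'
#' @return A named list with components:
#' \describe{
#'   \item{R}{gas constant, J mol^-1 K^-1 (8.314)}
#'   \item{N_A}{Avogadro number, mol^-1 (6.022e23)}
#'   \item{M_water}{molar mass of water, g mol^-1 (18.015)}
#'   \item{packing_organic}{packing density of molecules in organic
#'     crystals, dimensionless (0.7)}
#'   \item{packing_spheres}{packing density of randomly packed spheres,
#'     dimensionless (0.634)}
#'   \item{V_E_minus_V_B}{molar-volume difference between electrostricted
#'     and bulk water, cm^3 mol^-1 (-3.3)}
#' }
#' @export
#' @examples
#' k <- st_constants()
#' k$packing_organic / k$packing_spheres  # intrinsic-volume expansion ratio
st_constants <- function(overrides = NULL, file = NULL) {
  k <- list(
    R = 8.314,
    N_A = 6.022e23,
    M_water = 18.015,
    packing_organic = 0.7,
    packing_spheres = 0.634,
    V_E_minus_V_B = -3.3
  )
  apply_over <- function(k, ov, what) {
    if (is.null(ov)) return(k)
    if (!is.list(ov) || is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("constant overrides must be a named list (", what, ")")
    unknown <- setdiff(names(ov), names(k))
    if (length(unknown))
      stop("unknown constant name(s): ", paste(unknown, collapse = ", "))
    k[names(ov)] <- ov
    k
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("constants file not found: ", file)
    ov <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(file)
    }
    k <- apply_over(k, as.list(ov), file)
  }
  k <- apply_over(k, overrides, "overrides")
  validate_constants(k)
  k
}

validate_constants <- function(k) {
  pos <- c("R", "N_A", "M_water", "packing_organic", "packing_spheres")
  for (nm in pos) {
    if (!is.numeric(k[[nm]]) || length(k[[nm]]) != 1L || !is.finite(k[[nm]]) ||
        k[[nm]] <= 0)
      stop("constant '", nm, "' must be a single positive number")
  }
  if (!is.numeric(k$V_E_minus_V_B) || length(k$V_E_minus_V_B) != 1L ||
      !is.finite(k$V_E_minus_V_B) || k$V_E_minus_V_B >= 0)
    stop("constant 'V_E_minus_V_B' must be strictly negative")
  if (k$packing_organic <= k$packing_spheres)
    stop("'packing_organic' must exceed 'packing_spheres'")
  invisible(k)
}

#' Describe the solvent of a concentration series
#'
#' A solvent specification records the aqueous medium a solute series was
#' measured in: the additive (e.g. a betaine-based compound), its molality,
#' the temperature, and the pure-solvent reference properties used by the
#' analysis stages (density rho0, viscosity eta0, surface tension gamma0).
#'
#' @param additive_name name of the additive, e.g. `"betaine"`.
#' @param additive_molality additive molality in the aqueous solvent,
#'   mol kg^-1 (>= 0).
#' @param temperature absolute temperature, K.
#' @param density solvent density rho0, g cm^-3 (optional).
#' @param viscosity solvent viscosity eta0, mPa s (optional).
#' @param surface_tension solvent surface tension gamma0, mN m^-1 (optional).
#'
#' @return an object of class `"solvent_spec"` (a named list).
#' @export
solvent_spec <- function(additive_name = "water", additive_molality = 0,
                         temperature = 298, density = NA_real_,
                         viscosity = NA_real_, surface_tension = NA_real_) {
  stopifnot(is.character(additive_name), length(additive_name) == 1L)
  num1 <- function(x, nm, allow_na = FALSE) {
    if (length(x) != 1L || !is.numeric(x))
      stop("'", nm, "' must be a single number")
    if (is.na(x)) {
      if (!allow_na) stop("'", nm, "' may not be NA")
      return(NA_real_)
    }
    as.numeric(x)
  }
  additive_molality <- num1(additive_molality, "additive_molality")
  if (additive_molality < 0) stop("'additive_molality' must be >= 0")
  temperature <- num1(temperature, "temperature")
  if (temperature <= 0) stop("'temperature' must be > 0")
  for (nm in c("density", "viscosity", "surface_tension")) {
    v <- num1(get(nm), nm, allow_na = TRUE)
    if (!is.na(v) && v <= 0) stop("'", nm, "' must be > 0 when given")
    assign(nm, v)
  }
  structure(list(
    additive_name = additive_name,
    additive_molality = additive_molality,
    temperature = temperature,
    density = density,
    viscosity = viscosity,
    surface_tension = surface_tension
  ), class = "solvent_spec")
}

#' Convert molality to mole fraction
#'
#' Treats the aqueous medium as water on a binary basis: for a solute at
#' molality m (mol per kg of water), X = m / (m + 1000 / M_water). This is the
#' mole-fraction scale used in the micellization free energy
#' \eqn{\Delta G_{mic} = RT \ln X_{cmc}}.
#'
#' @param m molality, mol kg^-1 (vectorized, all >= 0).
#' @param M_water molar mass of water, g mol^-1.
#' @return mole fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' molality_to_mole_fraction(0.0148)  # ~2.665e-4
molality_to_mole_fraction <- function(m, M_water = st_constants()$M_water) {
  if (!is.numeric(m) || any(!is.finite(m))) stop("'m' must be finite numeric")
  if (any(m < 0)) stop("molality must be >= 0")
  m / (m + 1000 / M_water)
}

#' Convert mole fraction back to molality
#'
#' Inverse of [molality_to_mole_fraction()]; used to reconstruct concentration
#' grids from tabulated RT ln X free energies.
#'
#' @param X mole fraction(s), in `[0, 1)`.
#' @inheritParams molality_to_mole_fraction
#' @return molality, mol kg^-1.
#' @export
mole_fraction_to_molality <- function(X, M_water = st_constants()$M_water) {
  if (!is.numeric(X) || any(!is.finite(X))) stop("'X' must be finite numeric")
  if (any(X < 0) || any(X >= 1)) stop("mole fraction must be in [0, 1)")
  X * (1000 / M_water) / (1 - X)
}

#' Convert molality to molarity
#'
#' The Jones-Dole equation is written in molar concentration c (mol dm^-3)
#' while bench data are molal. In dilute mode c = m * rho (rho the solvent
#' density); in exact mode the solute mass is accounted for,
#' c = m * rho / (1 + m * M_solute / 1000). At the molalities typical of these
#' studies (<= 0.05 mol kg^-1) the two agree to well under 1%.
#'
#' @param m molality, mol kg^-1 (vectorized, >= 0).
#' @param rho solution (or solvent, dilute mode) density, g cm^-3.
#' @param M_solute solute molar mass, g mol^-1; required for `mode = "exact"`.
#' @param mode `"dilute"` (default) or `"exact"`.
#' @return molar concentration, mol dm^-3.
#' @export
#' @examples
#' molality_to_molarity(0.03, 1.000, 171.237, "exact")  # 0.029847
molality_to_molarity <- function(m, rho, M_solute = NULL,
                                 mode = c("dilute", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
    stop("molality must be finite and >= 0")
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0))
    stop("density must be > 0")
  if (mode == "dilute") return(m * rho)
  if (is.null(M_solute) || !is.numeric(M_solute) || any(M_solute <= 0))
    stop("'M_solute' (> 0) is required for exact conversion")
  m * rho / (1 + m * M_solute / 1000)
}
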