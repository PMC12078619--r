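#' Build a concentration series
#'
#' The central data container: one measured property (density, viscosity or
#' surface tension) as a function of solute molality at fixed solvent
#' composition and temperature. Rows are sorted by molality on construction;
#' duplicate molalities are an error. A molality-0 row, when present, is the
#' pure-solvent reference (rho0 / eta0) and is never passed to fits.
#'
#' @param molality solute molalities, mol kg^-1 (>= 0; the value at 0 is the
#'   solvent reference).
#' @param value measured property values, same length as `molality`; units are
#'   g cm^-3 (density), mPa s (viscosity) or mN m^-1 (surface tension).
#' @param property one of `"density"`, `"viscosity"`, `"surface_tension"`.
#' @param solvent a [solvent_spec()].
#' @param uncertainty instrument standard uncertainty of the property, in the
#'   property's units (defaults per property: 4e-5 g cm^-3, 0.001 mPa s,
#'   0.01 mN m^-1).
#'
#' @return object of class `"concentration_series"`: a list with `points`
#'   (data.frame molality/value), `property`, `solvent`, `uncertainty`.
#' @export
concentration_series <- function(molality, value,
                                 property = c("density", "viscosity",
                                              "surface_tension"),
                                 solvent = solvent_spec(),
                                 uncertainty = NULL) {
  property <- match.arg(property)
  if (!inherits(solvent, "solvent_spec")) stop("'solvent' must be a solvent_spec")
  if (length(molality) != length(value))
    stop("'molality' and 'value' must have equal length")
  if (!is.numeric(molality) || any(!is.finite(molality)) || any(molality < 0))
    stop("molalities must be finite and >= 0")
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("property values must be finite and > 0")
  ord <- order(molality)
  molality <- molality[ord]; value <- value[ord]
  if (any(duplicated(molality)))
    stop("duplicate molality in series (validation error)")
  if (is.null(uncertainty)) {
    uncertainty <- switch(property, density = 4e-5, viscosity = 0.001,
                          surface_tension = 0.01)
  }
  structure(list(
    points = data.frame(molality = molality, value = value),
    property = property,
    solvent = solvent,
    uncertainty = uncertainty
  ), class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %s, %d points, %s %.4g mol/kg, T = %g K\n",
              x$property, nrow(x$points), x$solvent$additive_name,
              x$solvent$additive_molality, x$solvent$temperature))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Solvent reference value of a series
#'
#' Returns the property value at molality 0 (the pure-solvent row) if present,
#' otherwise the value stored in the solvent spec, otherwise `NA`.
#'
#' @param series a [concentration_series()].
#' @return scalar reference value (rho0, eta0 or gamma0) or `NA`.
#' @export
solvent_reference <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  p <- series$points
  if (nrow(p) && p$molality[1] == 0) return(p$value[1])
  switch(series$property,
         density = series$solvent$density,
         viscosity = series$solvent$viscosity,
         surface_tension = series$solvent$surface_tension)
}

#' Solute rows of a series
#'
#' The points with molality > 0, i.e. those that enter fits.
#' @param series a [concentration_series()].
#' @return data.frame with columns `molality`, `value`.
#' @export
solute_points <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  series$points[series$points$molality > 0, , drop = FALSE]
}

# metadata keys written to / required from the '#' header block
.series_meta_keys <- c("property", "units", "additive_name",
                       "additive_molality", "temperature")

.property_units <- c(density = "g/cm^3", viscosity = "mPa.s",
                     surface_tension = "mN/m")

#' Read a concentration series from a self-describing CSV
#'
#' The format is a block of `# key: value` metadata lines (property, units,
#' additive_name, additive_molality, temperature, optionally uncertainty and
#' solvent reference properties), then a `molality,value` header and the data
#' rows. Rows may appear in any order; they are sorted on read. Duplicate
#' molalities and missing metadata are errors.
#'
#' @param path file to read.
#' @return a [concentration_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("format error: empty series file: ", path)
  is_meta <- grepl("^\\s*#", lines)
  meta_lines <- lines[is_meta]
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    meta[[key]] <- val
  }
  missing <- setdiff(.series_meta_keys, names(meta))
  if (length(missing))
    stop("format error: missing metadata field(s): ",
         paste(missing, collapse = ", "))
  property <- meta$property
  if (!property %in% names(.property_units))
    stop("format error: unknown property '", property, "'")
  if (!identical(meta$units, .property_units[[property]]))
    stop("format error: units '", meta$units, "' do not match property '",
         property, "' (expected ", .property_units[[property]], ")")
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("format error: no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("molality", "value") %in% names(df)))
    stop("format error: data columns must be 'molality' and 'value'")
  num_or_na <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  }
  sol <- solvent_spec(
    additive_name = meta$additive_name,
    additive_molality = as.numeric(meta$additive_molality),
    temperature = as.numeric(meta$temperature),
    density = num_or_na("solvent_density"),
    viscosity = num_or_na("solvent_viscosity"),
    surface_tension = num_or_na("solvent_surface_tension")
  )
  unc <- if (is.null(meta$uncertainty)) NULL else as.numeric(meta$uncertainty)
  concentration_series(df$molality, df$value, property = property,
                       solvent = sol, uncertainty = unc)
}

#' Write a concentration series to the self-describing CSV format
#'
#' @param series a [concentration_series()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "concentration_series"))
  s <- series$solvent
  meta <- c(
    sprintf("# property: %s", series$property),
    sprintf("# units: %s", .property_units[[series$property]]),
    sprintf("# additive_name: %s", s$additive_name),
    sprintf("# additive_molality: %.10g", s$additive_molality),
    sprintf("# temperature: %.10g", s$temperature),
    sprintf("# uncertainty: %.10g", series$uncertainty)
  )
  for (key in c("density", "viscosity", "surface_tension")) {
    if (!is.na(s[[key]]))
      meta <- c(meta, sprintf("# solvent_%s: %.10g", key, s[[key]]))
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("molality,value", con)
  writeLines(sprintf("%.12g,%.12g", series$points$molality,
                     series$points$value), con)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a result object (any list of named numeric fields and
#' data.frames) to JSON (versioned schema `soluthermo-report/1`) or, for a
#' single data.frame, to CSV. JSON keeps full precision and round-trips with
#' [read_report()].
#'
#' @param results result object (list or data.frame).
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results))
      stop("csv format requires a data.frame result")
    ok <- try(utils::write.csv(results, path, row.names = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write to ", path)
    return(invisible(path))
  }
  payload <- list(schema = "soluthermo-report/1", results = strip_classes(results))
  ok <- try(jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                                 na = "null", dataframe = "columns"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (inherits(x, "solvent_spec")) x <- unclass(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Read a report written by [write_report()]
#'
#' @param path JSON or CSV report file.
#' @return for JSON, the `results` component; for CSV, a data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    return(utils::read.csv(path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "soluthermo-report/1"))
    stop("unrecognized report schema in ", path)
  payload$results
}

#' Load a packaged reference table
#'
#' The package ships the study's printed reference tables, transcribed as
#' plain CSV with a provenance column naming the source table: densities and
#' apparent molar volumes (`"densities"`), Masson fit parameters (`"masson"`),
#' apparent specific volumes (`"asv"`), hydration numbers (`"hydration"`),
#' viscosities (`"viscosities"`), Jones-Dole B coefficients (`"jones_dole"`)
#' and the interfacial parameter ladder (`"interfacial"`).
#'
#' The interfacial table gains derived columns on load: `gamma_max_amin`
#' (mol m^-2 at the 1e-3 scale that reproduces the printed minimum areas),
#' `gamma_max_si` (mol m^-2 at the physically standard 1e-6 scale that
#' reproduces the printed adsorption free energies) and `C_reconstructed`
#' (additive molality recovered by inverting RT ln X from the printed
#' micellization free energy; the raw per-row concentrations were published
#' only as supplementary material).
#'
#' @param name table name, see above.
#' @return a data.frame.
#' @export
#' @examples
#' head(st_fixture("hydration"))
st_fixture <- function(name = c("densities", "masson", "asv", "hydration",
                                "viscosities", "jones_dole", "interfacial")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "soluthermo")
  if (!nzchar(path)) stop("fixture not found: ", name)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (name == "interfacial") {
    k <- st_constants()
    df$gamma_max_amin <- df$gamma_max_printed * 1e-3
    df$gamma_max_si <- df$gamma_max_printed * 1e-6
    X <- exp(df$dG_mic * 1000 / (k$R * df$temperature))
    df$C_reconstructed <- mole_fraction_to_molality(X)
  }
  df
}

#' Packaged measurement series
#'
#' Builds the nine density or viscosity series of the reference study (three
#' betaine-based additives at three nominal molalities each) as
#' [concentration_series()] objects. Density series carry the printed apparent
#' molar volumes as attribute `"vphi_printed"`. Viscosity series for the ionic
#' liquid have no usable solvent reference (the printed solvent row is
#' unreliable); their eta0 is `NA` and downstream fits require a supplied
#' value.
#'
#' @param property `"density"` or `"viscosity"`.
#' @return named list of nine [concentration_series()].
#' @export
fixture_series <- function(property = c("density", "viscosity")) {
  property <- match.arg(property)
  tab <- st_fixture(if (property == "density") "densities" else "viscosities")
  out <- list()
  for (key in unique(paste(tab$system, tab$solvent_molality_nominal))) {
    block <- tab[paste(tab$system, tab$solvent_molality_nominal) == key, ]
    ref_row <- block[block$m == 0, , drop = FALSE]
    ref <- if (nrow(ref_row) && !is.na(ref_row$value[1])) ref_row$value[1] else NA_real_
    sol <- solvent_spec(
      additive_name = block$system[1],
      additive_molality = block$solvent_molality[1],
      temperature = 298,
      density = if (property == "density") ref else NA_real_,
      viscosity = if (property == "viscosity") ref else NA_real_
    )
    keep <- block$m > 0 | (block$m == 0 & !is.na(block$value))
    ser <- concentration_series(block$m[keep], block$value[keep],
                                property = property, solvent = sol)
    if (property == "density") {
      attr(ser, "vphi_printed") <-
        block[block$m > 0, c("m", "vphi_printed"), drop = FALSE]
    }
    out[[paste(block$system[1], format(block$solvent_molality_nominal[1],
                                       nsmall = 2))]] <- ser
  }
  out
}
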