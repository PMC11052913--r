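#' Solvent description
#'
#' Molar mass and critical constants of the supercritical solvent.  The
#' critical constants are used to form the reduced variables
#' \eqn{T_r = T/T_c}, \eqn{P_r = P/P_c} and \eqn{\rho_r = \rho/\rho_c}
#' that several correlation models depend on.
#'
#' @param molar_mass Molar mass, g/mol.
#' @param T_c Critical temperature, K.
#' @param P_c Critical pressure, MPa.
#' @param rho_c Critical density, kg/m3.
#' @param name Solvent name.
#' @return An object of class `scf_solvent`.
#' @export
#' @examples
#' co2_solvent()
scf_solvent <- function(molar_mass, T_c, P_c, rho_c, name = "solvent") {
  vals <- c(molar_mass = molar_mass, T_c = T_c, P_c = P_c, rho_c = rho_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("scf_solvent: molar_mass, T_c, P_c and rho_c must be strictly positive")
  structure(list(name = name, molar_mass = molar_mass,
                 T_c = T_c, P_c = P_c, rho_c = rho_c),
            class = "scf_solvent")
}

#' Carbon dioxide solvent constants
#'
#' CO2 with M = 44.01 g/mol, T_c = 304.12 K, P_c = 7.39 MPa and
#' rho_c = 467.6 kg/m3.
#'
#' @return An `scf_solvent` object.
#' @export
co2_solvent <- function() {
  scf_solvent(molar_mass = 44.01, T_c = 304.12, P_c = 7.39,
              rho_c = 467.6, name = "CO2")
}

#' Solute description
#'
#' @param name Solute name.
#' @param molar_mass Molar mass, g/mol.
#' @param lambda_max Optional UV absorption maximum, nm (informational).
#' @return An object of class `scf_solute`.
#' @export
#' @examples
#' reg_solute()
scf_solute <- function(name, molar_mass, lambda_max = NA_real_) {
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("scf_solute: molar_mass must be strictly positive")
  structure(list(name = name, molar_mass = molar_mass, lambda_max = lambda_max),
            class = "scf_solute")
}

#' Regorafenib monohydrate solute constants
#'
#' Crystalline Regorafenib monohydrate (REG), M = 500.83 g/mol,
#' UV maximum at 275 nm.
#'
#' @return An `scf_solute` object.
#' @export
reg_solute <- function() {
  scf_solute("Regorafenib monohydrate", molar_mass = 500.83, lambda_max = 275)
}

REQUIRED_COLS <- c("T_K", "P_bar", "rho_kg_m3", "y2")
OPTIONAL_COLS <- c("S_gL", "sd", "U")

validate_records <- function(df, where = "records") {
  miss <- setdiff(REQUIRED_COLS, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")))
  if (nrow(df) < 1L) stop(sprintf("%s: at least one record required", where))
  chk <- function(col, ok, what) {
    bad <- which(!ok(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: row %d violates invariant on '%s' (%s)",
                   where, bad[1L], col, what))
  }
  pos <- function(x) is.finite(x) & x > 0
  chk("T_K", pos, "must be > 0")
  chk("P_bar", pos, "must be > 0")
  chk("rho_kg_m3", pos, "must be > 0")
  chk("y2", function(x) is.finite(x) & x > 0 & x < 1,
      "mole fraction must lie in (0, 1)")
  if ("S_gL" %in% names(df))
    chk("S_gL", function(x) is.na(x) | x > 0, "must be > 0 when present")
  key <- paste(df$T_K, df$P_bar)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicated (T, P) pair at row %d", where,
                 anyDuplicated(key)))
  invisible(df)
}

#' Solubility dataset
#'
#' An ordered collection of equilibrium solubility records together with
#' the solute and solvent they refer to.  Each record holds temperature
#' (K), pressure (bar), solvent density (kg/m3) and the solute mole
#' fraction `y2`; optional columns carry the gravimetric solubility
#' `S_gL` (g/L), the experimental standard deviation `sd` and the
#' expanded uncertainty `U` of `y2`.
#'
#' @param records Data frame with columns `T_K`, `P_bar`, `rho_kg_m3`,
#'   `y2` and optionally `S_gL`, `sd`, `U`.
#' @param solute An [scf_solute()] object.
#' @param solvent An [scf_solvent()] object.
#' @return An object of class `scf_dataset`.
#' @export
scf_dataset <- function(records, solute, solvent) {
  stopifnot(inherits(solute, "scf_solute"), inherits(solvent, "scf_solvent"))
  records <- as.data.frame(records)
  validate_records(records)
  keep <- intersect(c(REQUIRED_COLS, OPTIONAL_COLS), names(records))
  structure(list(records = records[keep], solute = solute, solvent = solvent),
            class = "scf_dataset")
}

#' @export
print.scf_dataset <- function(x, ...) {
  iso <- sort(unique(x$records$T_K))
  cat(sprintf("<scf_dataset> %s in %s\n", x$solute$name, x$solvent$name))
  cat(sprintf("  %d records, %d isotherm(s): %s K\n", nrow(x$records),
              length(iso), paste(iso, collapse = ", ")))
  cat(sprintf("  P: %g-%g bar,  y2: %.3g-%.3g\n",
              min(x$records$P_bar), max(x$records$P_bar),
              min(x$records$y2), max(x$records$y2)))
  invisible(x)
}

#' Number of records in a dataset
#' @param dataset An `scf_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(dataset) nrow(dataset$records)

#' Split a dataset into isotherms
#'
#' Records are grouped by exact temperature equality, in increasing
#' temperature order.
#'
#' @param dataset An `scf_dataset`.
#' @return Named list of data frames, one per temperature.
#' @export
isotherms <- function(dataset) {
  r <- dataset$records
  split(r, factor(r$T_K, levels = sort(unique(r$T_K))))
}

#' Read a solubility dataset from a delimited file
#'
#' The file must be comma-separated with a single header line carrying
#' at least the columns `T_K`, `P_bar`, `rho_kg_m3`, `y2` (optionally
#' `S_gL`, `sd`, `U`), dot decimal separator, UTF-8.
#'
#' @param path Path to a CSV file.
#' @inheritParams scf_dataset
#' @return An `scf_dataset`.
#' @export
read_solubility <- function(path, solute, solvent) {
  if (!file.exists(path)) stop(sprintf("read_solubility: no such file: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("read_solubility: parse error in '%s': %s",
                                path, conditionMessage(e))))
  for (col in intersect(c(REQUIRED_COLS, OPTIONAL_COLS), names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("read_solubility: malformed value in column '%s' at line %d of %s",
                   col, bad + 1L, path))
    }
  }
  scf_dataset(df, solute, solvent)
}

#' Write a solubility dataset to CSV
#'
#' Mirrors [read_solubility()]: a dataset written and read back is
#' value-identical.
#'
#' @param dataset An `scf_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solubility <- function(dataset, path) {
  write.csv(format(dataset$records, scientific = FALSE, trim = TRUE, digits = 15),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled Regorafenib monohydrate / ScCO2 dataset
#'
#' The 24-point equilibrium solubility table for crystalline Regorafenib
#' monohydrate in supercritical CO2: four isotherms (308, 318, 328,
#' 338 K) at six pressures (120-270 bar), with NIST CO2 densities, mole
#' fractions, experimental standard deviations and expanded
#' uncertainties (coverage factor k = 2).  The `S_gL` column is stored
#' as published but is informational; see [solubility_from_y2()] to
#' recompute it consistently from `y2`.
#'
#' @return An `scf_dataset` with 24 records.
#' @export
#' @examples
#' reg_dataset()
reg_dataset <- function() {
  path <- system.file("extdata", "reg_scco2.csv", package = "scfsolub",
                      mustWork = TRUE)
  read_solubility(path, reg_solute(), co2_solvent())
}

#' Sampling-loop setup
#'
#' Geometry and measured concentration of the dynamic sampling chain: a
#' loop of volume `V1` (L) filled with saturated supercritical solution
#' is flushed into a collection vial of volume `V_col` (L), and the
#' solute concentration `C` (g/L) in the vial is measured (typically by
#' UV spectrophotometry).
#'
#' @param V1 Sampling loop volume, L.
#' @param V_col Collection vial volume, L.
#' @param C Measured solute concentration in the vial, g/L.
#' @return An object of class `scf_sampling`.
#' @export
sampling_setup <- function(V1, V_col, C) {
  if (!is.finite(V1) || V1 <= 0 || !is.finite(V_col) || V_col <= 0)
    stop("sampling_setup: volumes must be strictly positive")
  if (!is.finite(C) || C < 0) stop("sampling_setup: concentration must be >= 0")
  structure(list(V1 = V1, V_col = V_col, C = C), class = "scf_sampling")
}

#' Mole fraction from a sampling measurement
#'
#' Converts a measured vial concentration to the equilibrium solute mole
#' fraction: moles of solute `n2 = C * V_col / M2` are compared with
#' moles of solvent held by the loop, `n1 = V1 * rho1 / M1`, giving
#' `y2 = n2 / (n1 + n2)`.  Density in kg/m3 is numerically equal to g/L.
#'
#' @param setup A [sampling_setup()] object.
#' @param rho1 Solvent density at the sampling state, kg/m3.
#' @param M1 Solvent molar mass, g/mol.
#' @param M2 Solute molar mass, g/mol.
#' @return Mole fraction `y2` (dimensionless).
#' @export
mole_fraction_from_sampling <- function(setup, rho1, M1, M2) {
  stopifnot(inherits(setup, "scf_sampling"))
  if (!is.finite(rho1) || rho1 <= 0)
    stop("mole_fraction_from_sampling: density must be strictly positive")
  if (M1 <= 0 || M2 <= 0)
    stop("mole_fraction_from_sampling: molar masses must be strictly positive")
  n2 <- setup$C * setup$V_col / M2
  n1 <- setup$V1 * rho1 / M1
  n2 / (n1 + n2)
}

#' Gravimetric solubility from mole fraction
#'
#' `S = rho1 * (M2 / M1) * y2 / (1 - y2)` in g of solute per litre of
#' solvent.
#'
#' @param rho1 Solvent density, kg/m3 (= g/L).
#' @param y2 Solute mole fraction, in `[0, 1)`.
#' @param M1,M2 Solvent and solute molar masses, g/mol.
#' @return Solubility in g/L.
#' @seealso [y2_from_solubility()] for the exact inverse.
#' @export
solubility_from_y2 <- function(rho1, y2, M1, M2) {
  if (any(y2 >= 1) || any(y2 < 0))
    stop("solubility_from_y2: y2 must lie in [0, 1)")
  rho1 * (M2 / M1) * y2 / (1 - y2)
}

#' Mole fraction from gravimetric solubility
#'
#' Exact inverse of [solubility_from_y2()].
#'
#' @param rho1 Solvent density, kg/m3.
#' @param S Solubility, g/L.
#' @param M1,M2 Solvent and solute molar masses, g/mol.
#' @return Mole fraction `y2`.
#' @export
y2_from_solubility <- function(rho1, S, M1, M2) {
  if (any(S < 0)) stop("y2_from_solubility: S must be >= 0")
  r <- S * M1 / (rho1 * M2)
  r / (1 + r)
}

#' Expanded uncertainty by combined relative propagation
#'
#' Combines relative standard uncertainties `u(x_i)/x_i` with
#' sensitivity coefficients `P_i` into
#' `u_c / y = sqrt(sum((P_i * u_i)^2))` and scales by the coverage
#' factor: `U = k * y * u_c/y`.  The default `k = 2` corresponds to an
#' approximately 95 percent confidence level.
#'
#' @param sensitivities Data frame (or list coercible to one) with
#'   columns `P` (sensitivity coefficient) and `u_rel` (relative
#'   standard uncertainty of the input).
#' @param y The measured value the uncertainty refers to.
#' @param k Coverage factor, > 0.
#' @return Expanded uncertainty `U`, in the units of `y`.
#' @export
#' @examples
#' expanded_uncertainty(data.frame(P = 1, u_rel = 0.01), y = 100)  # 2
expanded_uncertainty <- function(sensitivities, y, k = 2) {
  s <- as.data.frame(sensitivities)
  if (nrow(s) == 0L)
    stop("expanded_uncertainty: empty sensitivity list")
  if (!all(c("P", "u_rel") %in% names(s)))
    stop("expanded_uncertainty: sensitivities need columns 'P' and 'u_rel'")
  if (k <= 0) stop("expanded_uncertainty: coverage factor must be > 0")
  if (any(s$u_rel < 0))
    stop("expanded_uncertainty: relative uncertainties must be >= 0")
  u_rel_combined <- sqrt(sum((s$P * s$u_rel)^2))
  k * abs(y) * u_rel_combined
}
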