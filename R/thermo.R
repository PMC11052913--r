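# Enthalpy extraction, self-consistency diagnostics and crossover
# detection.

# Deterministic single-start fit used for enthalpies and the
# self-consistency linearization: exact OLS in the model's native space,
# then a Nelder-Mead polish of the AARD objective in mole-fraction
# space.  No random starts, so no seed sensitivity.
det_fit <- function(name, dataset) {
  fit_model(name, dataset,
            fit_config(objective = "aard", n_starts = 1L, seed = 1L,
                       maxit = 20000L, polish_rounds = 8L))
}

#' Sublimation/solvation enthalpies from fitted 1/T coefficients
#'
#' The 1/T coefficient `c` of the Chrastil and Kumar-Johnston
#' correlations estimates the total enthalpy of dissolution,
#' `dH_tot = -c * R`, and the same coefficient of the Bartle
#' correlation estimates the vaporization (sublimation) enthalpy,
#' `dH_vap = -c * R`.  The solvation enthalpy follows as the
#' difference `dH_sol = mean(dH_tot) - dH_vap`; it is negative
#' (solvation is exothermic) and conventionally reported as a
#' magnitude.
#'
#' The three fits are deterministic: exact least squares in each
#' model's native space followed by an AARD-objective polish in
#' mole-fraction space.
#'
#' @param dataset An `scf_dataset`.
#' @return Object of class `scf_enthalpy` with components (kJ/mol):
#'   `dH_tot_chrastil`, `dH_tot_kumar_johnston`, `dH_tot_mean`,
#'   `dH_vap`, `dH_sol` (signed) and `dH_sol_magnitude`, plus the
#'   fitted 1/T coefficients (K) and the gas constant used.
#' @export
#' @examples
#' enthalpies(reg_dataset())
enthalpies <- function(dataset) {
  f_ch <- det_fit("chrastil", dataset)
  f_kj <- det_fit("kumar_johnston", dataset)
  f_ba <- det_fit("bartle", dataset)
  cc <- c(chrastil = unname(f_ch$params["c"]),
          kumar_johnston = unname(f_kj$params["c"]),
          bartle = unname(f_ba$params["c"]))
  if (any(!is.finite(cc))) stop("enthalpies: missing 1/T coefficient")
  dh <- -cc * R_GAS / 1000  # kJ/mol
  tot_mean <- mean(dh[c("chrastil", "kumar_johnston")])
  sol <- tot_mean - dh[["bartle"]]
  structure(list(
    dH_tot_chrastil = dh[["chrastil"]],
    dH_tot_kumar_johnston = dh[["kumar_johnston"]],
    dH_tot_mean = tot_mean,
    dH_vap = dh[["bartle"]],
    dH_sol = sol,
    dH_sol_magnitude = abs(sol),
    coefficients = cc,
    R = R_GAS,
    fits = list(chrastil = f_ch, kumar_johnston = f_kj, bartle = f_ba)
  ), class = "scf_enthalpy")
}

#' @export
print.scf_enthalpy <- function(x, ...) {
  cat("<scf_enthalpy> (kJ/mol)\n")
  cat(sprintf("  dH_tot:  %.2f (Chrastil)   %.2f (Kumar-Johnston)   mean %.2f\n",
              x$dH_tot_chrastil, x$dH_tot_kumar_johnston, x$dH_tot_mean))
  cat(sprintf("  dH_vap:  %.2f (Bartle)\n", x$dH_vap))
  cat(sprintf("  dH_sol:  %.2f (signed %.2f; solvation exothermic)\n",
              x$dH_sol_magnitude, x$dH_sol))
  invisible(x)
}

# Linearizing coordinates for the self-consistency plot of each model:
# x is the density-like regressor, y the response with the fitted
# temperature term removed, so that all isotherms should collapse onto
# one straight line when the model describes the data.
consistency_coords <- function(model, st, y2, cpar) {
  switch(model,
    chrastil = list(x = st$lr,
                    y = log(solubility_from_y2(st$rho, y2, st$M1, st$M2)) -
                      cpar / st$T,
                    xlab = "ln rho", ylab = "ln S - c/T"),
    kumar_johnston = list(x = st$rho, y = log(y2) - cpar / st$T,
                          xlab = "rho", ylab = "ln y2 - c/T"),
    bartle = list(x = st$rho - 700,
                  y = log(y2 * st$P / 0.1) - cpar / st$T,
                  xlab = "rho - rho_ref", ylab = "ln(y2 P/Pref) - c/T"),
    mendez_teja = list(x = st$rho, y = st$T * log(y2 * st$P) - cpar * st$T,
                       xlab = "rho", ylab = "T ln(y2 P) - c T"),
    stop(sprintf("self_consistency: unsupported model '%s'", model))
  )
}

#' Isotherm self-consistency diagnostic
#'
#' Transforms every record into the linearizing coordinates of one of
#' the classical correlations (Chrastil, Kumar-Johnston, Bartle,
#' Mendez-Santiago-Teja), removes the fitted temperature term, and fits
#' a single straight line through all isotherms pooled.  Data that the
#' model describes consistently collapse onto that line; the pooled R2
#' quantifies the collapse.
#'
#' @param dataset An `scf_dataset` with at least two isotherms.
#' @param model One of `"chrastil"`, `"kumar_johnston"`, `"bartle"`,
#'   `"mendez_teja"`.
#' @return Object of class `scf_consistency`: pooled `r2`, line
#'   coefficients, per-point coordinates, residuals and isotherm labels.
#' @export
#' @examples
#' self_consistency(reg_dataset(), "bartle")$r2
self_consistency <- function(dataset,
                             model = c("chrastil", "kumar_johnston",
                                       "bartle", "mendez_teja")) {
  model <- match.arg(model)
  if (length(unique(dataset$records$T_K)) < 2L)
    stop("self_consistency: diagnostic requires at least two isotherms")
  st <- as_state(dataset)
  cpar <- unname(linear_fit(model, dataset)["c"])
  co <- consistency_coords(model, st, dataset$records$y2, cpar)
  line <- lm(co$y ~ co$x)
  res <- unname(residuals(line))
  r2 <- 1 - sum(res^2) / sum((co$y - mean(co$y))^2)
  structure(list(model = model, c = cpar, x = co$x, y = co$y,
                 xlab = co$xlab, ylab = co$ylab,
                 intercept = unname(coef(line)[1L]),
                 slope = unname(coef(line)[2L]),
                 r2 = r2, residuals = res,
                 isotherm = dataset$records$T_K),
            class = "scf_consistency")
}

#' @export
print.scf_consistency <- function(x, ...) {
  cat(sprintf("<scf_consistency> %s coordinates: pooled R2 = %.4f over %d points (%d isotherms)\n",
              x$model, x$r2, length(x$x), length(unique(x$isotherm))))
  invisible(x)
}

#' @importFrom stats residuals
#' @importFrom graphics plot legend abline
#' @export
plot.scf_consistency <- function(x, ...) {
  iso <- factor(x$isotherm)
  plot(x$x, x$y, col = as.integer(iso), pch = 19,
       xlab = x$xlab, ylab = x$ylab,
       main = sprintf("Self-consistency (%s), pooled R2 = %.3f", x$model, x$r2),
       ...)
  abline(x$intercept, x$slope, lty = 2)
  legend("bottomright", legend = paste(levels(iso), "K"),
         col = seq_along(levels(iso)), pch = 19, bty = "n")
  invisible(x)
}

# Piecewise-linear interpolant of ln y2 vs P for one isotherm.
iso_interp <- function(df) {
  o <- order(df$P_bar)
  list(P = df$P_bar[o], lny = log(df$y2[o]))
}

eval_pl <- function(f, p) {
  stats::approx(f$P, f$lny, xout = p, method = "linear", rule = 1)$y
}

#' Solubility crossover-pressure detection
#'
#' Solubility isotherms of a solid in a supercritical solvent cross:
#' below the crossover pressure the solvent-density effect dominates
#' and solubility falls with temperature; above it the solute vapor
#' pressure dominates and solubility rises with temperature.  For every
#' isotherm pair this interpolates `ln y2` against pressure piecewise
#' linearly (no splines, to avoid spurious crossings on short
#' isotherms), locates sign changes of the difference on the common
#' pressure range, and reports the intersection pressures and their
#' envelope.
#'
#' @param dataset An `scf_dataset` with at least two isotherms of at
#'   least three points each.
#' @return Object of class `scf_crossover`: `crossings` (data frame
#'   with `T1`, `T2`, `P_cross`), `band` (min, max of all crossing
#'   pressures), `degenerate_pairs` and `skipped_pairs`.
#' @export
#' @examples
#' crossover(reg_dataset())$band
crossover <- function(dataset) {
  iso <- isotherms(dataset)
  if (length(iso) < 2L)
    stop("crossover: need at least two isotherms")
  if (any(vapply(iso, nrow, 1L) < 3L))
    stop("crossover: each isotherm needs at least three points")
  temps <- as.numeric(names(iso))
  crossings <- list(); degenerate <- character(); skipped <- character()
  for (i in seq_len(length(iso) - 1L)) for (j in seq(i + 1L, length(iso))) {
    fi <- iso_interp(iso[[i]]); fj <- iso_interp(iso[[j]])
    lo <- max(min(fi$P), min(fj$P)); hi <- min(max(fi$P), max(fj$P))
    pair <- sprintf("%g/%g", temps[i], temps[j])
    if (lo >= hi) { skipped <- c(skipped, pair); next }
    grid <- sort(unique(c(fi$P[fi$P >= lo & fi$P <= hi],
                          fj$P[fj$P >= lo & fj$P <= hi], lo, hi)))
    d <- eval_pl(fi, grid) - eval_pl(fj, grid)
    if (all(abs(d) < 1e-12)) { degenerate <- c(degenerate, pair); next }
    for (k in seq_len(length(grid) - 1L)) {
      d1 <- d[k]; d2 <- d[k + 1L]
      pc <- if (d1 == 0) grid[k]
            else if (d1 * d2 < 0) grid[k] - d1 * (grid[k + 1L] - grid[k]) / (d2 - d1)
            else NA_real_
      if (!is.na(pc))
        crossings[[length(crossings) + 1L]] <-
          data.frame(T1 = temps[i], T2 = temps[j], P_cross = pc)
    }
    if (d[length(d)] == 0)
      crossings[[length(crossings) + 1L]] <-
        data.frame(T1 = temps[i], T2 = temps[j], P_cross = grid[length(grid)])
  }
  crossings <- if (length(crossings)) unique(do.call(rbind, crossings))
               else data.frame(T1 = numeric(), T2 = numeric(),
                               P_cross = numeric())
  band <- if (nrow(crossings)) range(crossings$P_cross) else c(NA_real_, NA_real_)
  structure(list(crossings = crossings, band = band,
                 degenerate_pairs = degenerate, skipped_pairs = skipped),
            class = "scf_crossover")
}

#' @export
print.scf_crossover <- function(x, ...) {
  cat(sprintf("<scf_crossover> %d crossing(s)", nrow(x$crossings)))
  if (nrow(x$crossings))
    cat(sprintf("; band %.1f-%.1f bar", x$band[1L], x$band[2L]))
  cat("\n")
  if (nrow(x$crossings)) print(x$crossings, row.names = FALSE)
  if (length(x$degenerate_pairs))
    cat("degenerate (identical) pairs:",
        paste(x$degenerate_pairs, collapse = ", "), "\n")
  if (length(x$skipped_pairs))
    cat("skipped (non-overlapping) pairs:",
        paste(x$skipped_pairs, collapse = ", "), "\n")
  invisible(x)
}
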