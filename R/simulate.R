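# Synthetic solubility data with the structure the analysis assumes:
# a T x P grid, a physically shaped rho(T, P) surface, and mole
# fractions generated from any registered model with multiplicative
# lognormal noise.

reg_density_grid <- function() {
  r <- reg_dataset()$records
  Ts <- sort(unique(r$T_K)); Ps <- sort(unique(r$P_bar))
  z <- matrix(NA_real_, length(Ts), length(Ps))
  for (i in seq_along(Ts)) for (j in seq_along(Ps))
    z[i, j] <- r$rho_kg_m3[r$T_K == Ts[i] & r$P_bar == Ps[j]]
  list(T = Ts, P = Ps, rho = z)
}

#' Bilinear CO2 density interpolator over the bundled grid
#'
#' Returns a function `rho(T, P)` that bilinearly interpolates the
#' bundled 4 x 6 density table (308-338 K, 120-270 bar) and reproduces
#' the tabulated densities exactly at the grid nodes.  Extrapolation
#' outside the grid is refused.
#'
#' @param table Optional data frame with columns `T_K`, `P_bar`,
#'   `rho_kg_m3` forming a complete rectangular grid; defaults to the
#'   bundled table.
#' @return Vectorized function of `(T, P)` returning density in kg/m3.
#' @export
#' @examples
#' co2_density()(318, 210)  # 824, a grid node
co2_density <- function(table = NULL) {
  g <- if (is.null(table)) reg_density_grid() else {
    table <- as.data.frame(table)
    Ts <- sort(unique(table$T_K)); Ps <- sort(unique(table$P_bar))
    z <- matrix(NA_real_, length(Ts), length(Ps))
    for (i in seq_along(Ts)) for (j in seq_along(Ps)) {
      v <- table$rho_kg_m3[table$T_K == Ts[i] & table$P_bar == Ps[j]]
      if (length(v) != 1L)
        stop("co2_density: density table must form a complete T x P grid")
      z[i, j] <- v
    }
    list(T = Ts, P = Ps, rho = z)
  }
  function(T, P) {
    n <- max(length(T), length(P))
    T <- rep_len(T, n); P <- rep_len(P, n)
    if (any(T < min(g$T) | T > max(g$T) | P < min(g$P) | P > max(g$P)))
      stop(sprintf("co2_density: refusing to extrapolate outside %g-%g K, %g-%g bar",
                   min(g$T), max(g$T), min(g$P), max(g$P)))
    out <- numeric(n)
    for (k in seq_len(n)) {
      i <- max(1L, min(findInterval(T[k], g$T), length(g$T) - 1L))
      j <- max(1L, min(findInterval(P[k], g$P), length(g$P) - 1L))
      tT <- (T[k] - g$T[i]) / (g$T[i + 1L] - g$T[i])
      tP <- (P[k] - g$P[j]) / (g$P[j + 1L] - g$P[j])
      out[k] <- (1 - tT) * (1 - tP) * g$rho[i, j] +
        (1 - tT) * tP * g$rho[i, j + 1L] +
        tT * (1 - tP) * g$rho[i + 1L, j] +
        tT * tP * g$rho[i + 1L, j + 1L]
    }
    out
  }
}

#' Simulation configuration
#'
#' @param model Registry name of the generating model.
#' @param params True parameter vector of the generating model.
#' @param T Temperatures of the design grid, K.
#' @param P Pressures of the design grid, bar.  The full `T` x `P`
#'   grid is simulated, mirroring the 4 x 6 design of the bundled
#'   dataset.
#' @param sigma Multiplicative lognormal noise level: observed
#'   `y2 = true * exp(e)` with `e ~ N(0, sigma^2)`.  `sigma = 0` gives
#'   noise-free data.
#' @param seed Integer seed.
#' @param density `NULL` for the bundled density interpolator, a
#'   density table for [co2_density()], or a function `(T, P) -> rho`.
#' @return A list of class `scf_sim_config`.
#' @export
simulation_config <- function(model, params,
                              T = c(308, 318, 328, 338),
                              P = c(120, 150, 180, 210, 240, 270),
                              sigma = 0, seed = 1L, density = NULL) {
  if (sigma < 0) stop("simulation_config: sigma must be >= 0")
  if (!length(T) || !length(P)) stop("simulation_config: empty design grid")
  get_model(model)  # validate registration
  structure(list(model = model, params = as.numeric(params), T = T, P = P,
                 sigma = sigma, seed = as.integer(seed), density = density),
            class = "scf_sim_config")
}

#' Simulate a solubility dataset from a registered model
#'
#' Generates `y2(T, P) = model prediction * exp(e)`,
#' `e ~ N(0, sigma^2)`, over the configured grid.  The multiplicative
#' noise preserves positivity and matches the roughly constant relative
#' scatter of replicate solubility measurements.  Records carry the
#' density actually used, so fits see exactly the simulated state.
#'
#' @param config A [simulation_config()].
#' @param solute,solvent Solute/solvent constants; default REG in CO2.
#' @return An `scf_dataset`, seed-reproducible.
#' @export
#' @examples
#' cfg <- simulation_config("chrastil", c(7, 5.5, -4950), sigma = 0.05)
#' simulate_dataset(cfg)
simulate_dataset <- function(config, solute = reg_solute(),
                             solvent = co2_solvent()) {
  stopifnot(inherits(config, "scf_sim_config"))
  spec <- get_model(config$model)
  grid <- expand.grid(P_bar = config$P, T_K = config$T)[, c("T_K", "P_bar")]
  dens <- config$density
  rho_fun <- if (is.null(dens)) co2_density()
             else if (is.function(dens)) dens
             else co2_density(dens)
  grid$rho_kg_m3 <- rho_fun(grid$T_K, grid$P_bar)
  if (any(!is.finite(grid$rho_kg_m3) | grid$rho_kg_m3 <= 0))
    stop("simulate_dataset: density source returned a non-positive value")
  st <- dataset_state(grid, solute, solvent)
  f <- native_value(spec, config$params, st)
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1L]
    stop(sprintf("simulate_dataset: %s prediction non-finite at grid point (T = %g K, P = %g bar)",
                 spec$name, grid$T_K[bad], grid$P_bar[bad]))
  }
  y_true <- y2_from_native(spec$space, f, st)
  if (any(!is.finite(y_true) | y_true <= 0)) {
    bad <- which(!is.finite(y_true) | y_true <= 0)[1L]
    stop(sprintf("simulate_dataset: %s gives non-positive y2 at (T = %g K, P = %g bar)",
                 spec$name, grid$T_K[bad], grid$P_bar[bad]))
  }
  set.seed(config$seed)
  grid$y2 <- y_true * exp(rnorm(nrow(grid), 0, config$sigma))
  grid$S_gL <- solubility_from_y2(grid$rho_kg_m3, grid$y2,
                                  solvent$molar_mass, solute$molar_mass)
  scf_dataset(grid, solute, solvent)
}

#' Parameter-recovery study by simulation
#'
#' Repeats simulate-then-fit `n_replicates` times (replicate `r` uses
#' seed `seed + r - 1`) and summarizes, per parameter, the relative
#' bias and relative RMSE of the estimates around the generating truth,
#' together with the distribution of fitted AARDs.  Replicates whose
#' fit fails are recorded, not fatal.
#'
#' @param config A [simulation_config()]; its `params` are the truth.
#' @param n_replicates Number of replicates, >= 1.
#' @param config_fit A [fit_config()] for the per-replicate fits.
#' @return Object of class `scf_recovery`: `table` (per-parameter
#'   truth, mean estimate, relative bias, relative RMSE), `aard`
#'   (per-replicate fitted AARD), `estimates` matrix and `failures`.
#' @export
recovery_study <- function(config, n_replicates,
                           config_fit = fit_config(n_starts = 8L)) {
  stopifnot(inherits(config, "scf_sim_config"))
  if (n_replicates < 1L) stop("recovery_study: n_replicates must be >= 1")
  spec <- get_model(config$model)
  est <- matrix(NA_real_, n_replicates, spec$n_params,
                dimnames = list(NULL, spec$params))
  aards <- rep(NA_real_, n_replicates)
  failures <- character()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config; cfg_r$seed <- config$seed + r - 1L
    out <- tryCatch({
      d <- simulate_dataset(cfg_r)
      f <- fit_model(spec, d, config_fit)
      list(par = unname(f$params), aard = f$stats$aard)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(out)))
    } else {
      est[r, ] <- out$par
      aards[r] <- out$aard
    }
  }
  truth <- config$params
  ok <- stats::complete.cases(est)
  rel <- sweep(est[ok, , drop = FALSE], 2, truth, "-")
  rel <- sweep(rel, 2, abs(truth), "/")
  table <- data.frame(
    param = spec$params, truth = truth,
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    rel_bias = colMeans(rel),
    rel_rmse = sqrt(colMeans(rel^2)),
    median_abs_rel_error = apply(abs(rel), 2, median),
    stringsAsFactors = FALSE)
  structure(list(model = spec$name, table = table, aard = aards,
                 estimates = est, failures = failures,
                 n_replicates = n_replicates),
            class = "scf_recovery")
}

#' @export
print.scf_recovery <- function(x, ...) {
  cat(sprintf("<scf_recovery> %s, %d replicate(s), %d failure(s)\n",
              x$model, x$n_replicates, length(x$failures)))
  print(format(x$table, digits = 3), row.names = FALSE)
  cat(sprintf("AARD: median %.3g%%, range %.3g-%.3g%%\n",
              median(x$aard, na.rm = TRUE), min(x$aard, na.rm = TRUE),
              max(x$aard, na.rm = TRUE)))
  invisible(x)
}
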