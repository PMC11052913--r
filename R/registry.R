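# Model registry.
#
# Each entry is a small spec object describing one correlation equation:
# its native prediction space, parameter metadata, and a design-matrix
# builder when the equation is linear in its parameters in that space
# (after an optional fixed offset and an invertible reparameterization
# beta <-> params).  Pressure enters every formula in MPa, temperature
# in K, density in kg/m3 unless the formula says otherwise (mol/mL for
# the association models, reduced variables where noted).
#
# Several source renderings of these equations are typographically
# ambiguous in the literature; the forms below are the canonical
# published ones:
#   Chrastil            ln S = a + b ln(rho) + c/T
#   Kumar-Johnston      ln y2 = a + b rho + c/T
#   Bartle              ln(y2 P / Pref) = a + b (rho - rho_ref) + c/T
#   Mendez-Santiago-Teja T ln(y2 P) = a + b rho + c T
#   Keshmiri            ln y2 = a + b/T + c P^2 + (d + e/T) ln(rho)
#   Sung-Shim           ln y2 = (a + b/T) ln(rho) + c/T + d
#   Del Valle-Aguilera  ln y2 = a + b/T + c/T^2 + d ln(rho)
#   Sparks              ln S = (a + b rho_r + c ln Tr) ln(rho_r) + d + e/Tr + f/Tr^2
#   Mitra-Wilson        ln S = a ln P + b T + c P T + d P + e
#   Reddy               ln y2 = (a + b Pr) Tr^2 + (c + d Pr) Tr + e
# with Pref = 0.1 MPa and rho_ref = 700 kg/m3 fixed.

new_model <- function(name, label, group, family, space, params, n_indep,
                      formula, design = NULL, offset = NULL,
                      to_beta = identity, from_beta = identity,
                      native = NULL, init = NULL, bounds = NULL) {
  k <- length(params)
  if (is.null(bounds)) bounds <- rbind(lower = rep(-1e6, k), upper = rep(1e6, k))
  spec <- list(name = name, label = label, group = group, family = family,
               space = space, params = params, n_params = k, n_indep = n_indep,
               formula = formula, design = design, offset = offset,
               to_beta = to_beta, from_beta = from_beta,
               linear = !is.null(design) && is.null(init),
               native = native, init = init, bounds = bounds)
  if (is.null(native) && is.null(design))
    stop("model must define either a design matrix or a native() evaluator")
  structure(spec, class = "scf_model")
}

#' @export
print.scf_model <- function(x, ...) {
  cat(sprintf("<scf_model> %s (group %s, %d parameters%s)\n  %s\n",
              x$label, x$group, x$n_params,
              if (x$linear) ", linear in parameters" else "", x$formula))
  invisible(x)
}

# Native-space evaluation used for every model; for linear models it is
# design %*% beta (+ offset).
native_value <- function(spec, params, st) {
  if (!is.null(spec$native)) return(spec$native(params, st))
  beta <- spec$to_beta(params)
  f <- drop(spec$design(st) %*% beta)
  if (!is.null(spec$offset)) f <- f + spec$offset(st)
  f
}

build_registry <- function() {
  m <- list()
  add <- function(spec) m[[spec$name]] <<- spec

  ## ---- Group I: f(T, P, rho) -------------------------------------------
  add(new_model("mendez_teja", "Mendez-Santiago-Teja", "I", "density", "mst",
    c("a", "b", "c"), 3, "T ln(y2 P) = a + b rho + c T",
    design = function(st) cbind(1, st$rho, st$T)))
  add(new_model("bartle", "Bartle et al.", "I", "density", "bartle",
    c("a", "b", "c"), 3, "ln(y2 P / Pref) = a + b (rho - 700) + c / T",
    design = function(st) cbind(1, st$rho - 700, 1 / st$T)))
  add(new_model("jafari", "Jafari et al.", "I", "density", "lny",
    c("a", "b", "c", "d"), 3, "ln y2 = a + b P^2 + c T^2 + d ln(rho)",
    design = function(st) cbind(1, st$P^2, st$T^2, st$lr)))
  add(new_model("hozhabr", "Hozhabr et al.", "I", "density", "lny",
    c("a", "b", "c", "d"), 3, "ln y2 = a + b / T + c rho / T + d ln P",
    design = function(st) cbind(1, 1 / st$T, st$rho / st$T, log(st$P))))
  add(new_model("keshmiri", "Keshmiri et al.", "I", "density", "lny",
    c("a", "b", "c", "d", "e"), 3,
    "ln y2 = a + b / T + c P^2 + (d + e / T) ln(rho)",
    design = function(st) cbind(1, 1 / st$T, st$P^2, st$lr, st$lr / st$T)))
  add(new_model("khansary", "Khansary et al.", "I", "density", "lny",
    c("a", "b", "c", "d", "e"), 3,
    "ln y2 = a / T + b P + c P^2 / T + (d + e P) ln(rho)",
    design = function(st) cbind(1 / st$T, st$P, st$P^2 / st$T, st$lr,
                                st$P * st$lr)))
  add(new_model("jouyban", "Jouyban et al.", "I", "density", "lny",
    c("a", "b", "c", "d", "e", "f"), 3,
    "ln y2 = a + b P + c P^2 + d P T + e T / P + f ln(rho)",
    design = function(st) cbind(1, st$P, st$P^2, st$P * st$T, st$T / st$P,
                                st$lr)))
  add(new_model("sodeifian", "Sodeifian et al.", "I", "density", "lny",
    c("a", "b", "c", "d", "e", "f"), 3,
    "ln y2 = a + b P^2 / T + c ln(rho T) + d rho ln(rho) + e P ln T + f rho / T",
    design = function(st) cbind(1, st$P^2 / st$T, log(st$rho * st$T),
                                st$rho * st$lr, st$P * log(st$T),
                                st$rho / st$T)))

  ## ---- Group II: f(T, rho) ---------------------------------------------
  add(new_model("kumar_johnston", "Kumar-Johnston", "II", "density", "lny",
    c("a", "b", "c"), 2, "ln y2 = a + b rho + c / T",
    design = function(st) cbind(1, st$rho, 1 / st$T)))
  add(new_model("alwi_garlapati", "Alwi-Garlapati", "II", "density", "lny",
    c("a", "b", "c"), 2, "y2 = (1 / (rho_r Tr)) exp(a + b / Tr + c rho_r)",
    design = function(st) cbind(1, 1 / st$Tr, st$rho_r),
    offset = function(st) -log(st$rho_r * st$Tr)))
  add(new_model("chrastil", "Chrastil", "II", "density", "lnS",
    c("a", "b", "c"), 2, "ln S = a + b ln(rho) + c / T",
    design = function(st) cbind(1, st$lr, 1 / st$T)))
  add(new_model("andonova_garlapati", "Andonova-Garlapati", "II", "density",
    "lny", c("a", "b", "c"), 2, "y2 = a rho_r^b Tr^c",
    design = function(st) cbind(1, log(st$rho_r), log(st$Tr)),
    to_beta = function(p) c(log(p[1]), p[2], p[3]),
    from_beta = function(b) c(exp(b[1]), b[2], b[3]),
    bounds = rbind(lower = c(1e-30, -1e6, -1e6), upper = c(1e6, 1e6, 1e6))))
  add(new_model("sung_shim", "Sung-Shim", "II", "density", "lny",
    c("a", "b", "c", "d"), 2, "ln y2 = (a + b / T) ln(rho) + c / T + d",
    design = function(st) cbind(st$lr, st$lr / st$T, 1 / st$T, 1)))
  add(new_model("garlapati_madras", "Garlapati-Madras", "II", "density", "lny",
    c("a", "b", "c", "d", "e"), 2,
    "ln y2 = a + (b + c rho) ln(rho) + d / T + e ln(rho T)",
    design = function(st) cbind(1, st$lr, st$rho * st$lr, 1 / st$T,
                                log(st$rho * st$T))))
  add(new_model("del_valle_aguilera", "Del Valle-Aguilera", "II", "density",
    "lny", c("a", "b", "c", "d"), 2,
    "ln y2 = a + b / T + c / T^2 + d ln(rho)",
    design = function(st) cbind(1, 1 / st$T, 1 / st$T^2, st$lr),
    # the 1/T^2 coefficient is O(10^6-10^7) on physical data
    bounds = rbind(lower = c(-1e6, -1e6, -1e9, -1e6),
                   upper = c(1e6, 1e6, 1e9, 1e6))))
  add(new_model("bian", "Bian et al.", "II", "density", "lny",
    c("a", "b", "c", "d", "e"), 2,
    "ln y2 = a + b / T + c rho / T + (d + e rho) ln(rho)",
    design = function(st) cbind(1, 1 / st$T, st$rho / st$T, st$lr,
                                st$rho * st$lr)))
  add(new_model("adachi_lu", "Adachi-Lu", "II", "density", "lny",
    c("a", "b", "c", "d", "e"), 2,
    "ln y2 = a + (b + c rho + d rho^2) ln(rho) + e / T",
    design = function(st) cbind(1, st$lr, st$rho * st$lr, st$rho^2 * st$lr,
                                1 / st$T)))
  add(new_model("sparks", "Sparks et al.", "II", "density", "lnS",
    c("a", "b", "c", "d", "e", "f"), 2,
    "ln S = (a + b rho_r + c ln Tr) ln(rho_r) + d + e / Tr + f / Tr^2",
    design = function(st) {
      lrr <- log(st$rho_r)
      cbind(lrr, st$rho_r * lrr, log(st$Tr) * lrr, 1, 1 / st$Tr, 1 / st$Tr^2)
    }))
  add(new_model("si_moussa", "Si-Moussa et al.", "II", "density", "lny",
    c("a", "b", "c", "d", "e", "f"), 2,
    "ln y2 = a + b rho + c rho^2 + d rho / T + e T / rho + f ln(rho)",
    design = function(st) cbind(1, st$rho, st$rho^2, st$rho / st$T,
                                st$T / st$rho, st$lr)))
  add(new_model("belghait", "Belghait et al.", "II", "density", "lny",
    c("a", "b", "c", "d", "e", "f", "g", "h"), 2,
    "ln y2 = a + b rho + c rho^2 + d rho / T + e T + f T^2 + g ln(rho) + h / T",
    design = function(st) cbind(1, st$rho, st$rho^2, st$rho / st$T, st$T,
                                st$T^2, st$lr, 1 / st$T)))

  ## ---- Group III: f(T, P) ----------------------------------------------
  add(new_model("reddy", "Reddy et al.", "III", "density", "lny",
    c("a", "b", "c", "d", "e"), 2,
    "ln y2 = (a + b Pr) Tr^2 + (c + d Pr) Tr + e",
    design = function(st) cbind(st$Tr^2, st$Pr * st$Tr^2, st$Tr,
                                st$Pr * st$Tr, 1)))
  add(new_model("mitra_wilson", "Mitra-Wilson", "III", "density", "lnS",
    c("a", "b", "c", "d", "e"), 2,
    "ln S = a ln P + b T + c P T + d P + e",
    design = function(st) cbind(log(st$P), st$T, st$P * st$T, st$P, 1)))
  add(new_model("reddy_garlapati", "Reddy-Garlapati", "III", "density", "y",
    c("a", "b", "c", "d", "e", "f"), 2,
    "y2 = (a + b Pr + c Pr^2) Tr + d + e Pr + f Pr^2",
    design = function(st) cbind(st$Tr, st$Pr * st$Tr, st$Pr^2 * st$Tr, 1,
                                st$Pr, st$Pr^2)))
  add(new_model("gordillo", "Gordillo et al.", "III", "density", "lny",
    c("a", "b", "c", "d", "e", "f"), 2,
    "ln y2 = a + b P + c P^2 + d P T + e T + f T^2",
    design = function(st) cbind(1, st$P, st$P^2, st$P * st$T, st$T, st$T^2)))
  add(new_model("yu", "Yu et al.", "III", "density", "y",
    c("a", "b", "c", "d", "e", "f"), 2,
    "y2 = a + b P + c P^2 + d P T (1 - y2) + e T + f T^2",
    native = function(p, st) {
      den <- 1 + p[4] * st$P * st$T
      num <- p[1] + p[2] * st$P + p[3] * st$P^2 + p[4] * st$P * st$T +
        p[5] * st$T + p[6] * st$T^2
      num / den
    },
    init = function(st, y2) {
      # Implicit in y2 but closed-form given d: profile d over a signed
      # log-spaced grid with an exact least-squares solve for the rest.
      grid <- c(0, outer(c(-1, 1), 10^seq(-10, -4, length.out = 25)))
      best <- NULL
      for (d in grid) {
        den <- 1 + d * st$P * st$T
        if (any(abs(den) < 1e-8)) next
        X <- cbind(1, st$P, st$P^2, st$T, st$T^2)
        z <- y2 * den - d * st$P * st$T
        b <- tryCatch(qr.solve(X, z), error = function(e) NULL)
        if (is.null(b)) next
        pred <- (drop(X %*% b) + d * st$P * st$T) / den
        val <- mean(abs(pred - y2) / y2)
        if (is.finite(val) && (is.null(best) || val < best$val))
          best <- list(val = val, par = c(b[1:3], d, b[4:5]))
      }
      if (is.null(best)) stop("yu: profile initializer failed")
      best$par
    }))

  ## ---- Association (solid-liquid equilibrium) models --------------------
  kb <- function(k) {                 # kappa bounded, remaining free
    rbind(lower = c(-10, rep(-1e6, k - 1)), upper = c(10, rep(1e6, k - 1)))
  }
  shift_kappa <- function(p) c(p[1] - 1, p[-1])
  unshift_kappa <- function(b) c(b[1] + 1, b[-1])
  add(new_model("rajasekhar_madras", "Rajasekhar-Madras", "association",
    "association", "lny", c("kappa", "D1", "D2", "D3"), 3,
    "y2 = (P / P*)^(kappa - 1) exp(D1 / T + D2 rho[mol/mL] + D3),  P* = 0.1 MPa",
    design = function(st) cbind(log(st$P / 0.1), 1 / st$T, st$rho_mm, 1),
    to_beta = shift_kappa, from_beta = unshift_kappa, bounds = kb(4)))
  add(new_model("assoc_reduced", "Modified association (reduced variables)",
    "association", "association", "lny", c("kappa", "A1", "A2", "A3"), 3,
    "y2 = (P / P*)^(kappa - 1) exp(A1 / Tr + A2 rho_r + A3),  P* = 0.1 MPa",
    design = function(st) cbind(log(st$P / 0.1), 1 / st$Tr, st$rho_r, 1),
    to_beta = shift_kappa, from_beta = unshift_kappa, bounds = kb(4)))
  add(new_model("assoc_pressure", "Modified association (pressure term)",
    "association", "association", "lny", c("kappa", "C1", "C2", "C3", "C4"), 3,
    "y2 = (P / P*)^(kappa - 1) exp(C1 / T + C2 rho[mol/mL] + C3 P + C4),  P* = 0.1 MPa",
    design = function(st) cbind(log(st$P / 0.1), 1 / st$T, st$rho_mm, st$P, 1),
    to_beta = shift_kappa, from_beta = unshift_kappa, bounds = kb(5)))

  m
}

THE_REGISTRY <- build_registry()

#' The model registry
#'
#' All registered solubility correlation models: 25 density-based models
#' in three groups (I: functions of T, P and density; II: T and density;
#' III: T and P) plus three association-theory solid-liquid-equilibrium
#' models.
#'
#' @param family One of `"all"`, `"density"`, `"association"`.
#' @return Named list of `scf_model` specs.
#' @export
#' @examples
#' length(model_registry("density"))  # 25
model_registry <- function(family = c("all", "density", "association")) {
  family <- match.arg(family)
  if (family == "all") return(THE_REGISTRY)
  Filter(function(m) m$family == family, THE_REGISTRY)
}

#' Look up one model by name
#'
#' @param name Registry name, e.g. `"chrastil"`.
#' @return An `scf_model` spec.
#' @export
get_model <- function(name) {
  if (inherits(name, "scf_model")) return(name)
  spec <- THE_REGISTRY[[name]]
  if (is.null(spec))
    stop(sprintf("unknown model '%s'; see model_catalogue()", name))
  spec
}

#' Machine-readable model catalogue
#'
#' @return Data frame with one row per registered model: name, label,
#'   group, family, parameter count, prediction space, linearity flag
#'   and formula.
#' @export
model_catalogue <- function() {
  do.call(rbind, lapply(unname(THE_REGISTRY), function(m)
    data.frame(name = m$name, label = m$label, group = m$group,
               family = m$family, n_params = m$n_params, space = m$space,
               linear = m$linear, formula = m$formula,
               stringsAsFactors = FALSE)))
}
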