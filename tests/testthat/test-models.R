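test_that("registry carries the full model battery", {
  cat25 <- model_catalogue()
  density <- cat25[cat25$family == "density", ]
  expect_equal(nrow(density), 25L)
  expect_equal(as.vector(table(density$group)[c("I", "II", "III")]),
               c(8L, 12L, 5L))
  expect_equal(nrow(cat25[cat25$family == "association", ]), 3L)

  ch <- get_model("chrastil")
  expect_equal(ch$space, "lnS")
  expect_equal(ch$n_params, 3L)
  expect_true(ch$linear)

  go <- get_model("gordillo")
  expect_equal(go$n_params, 6L)
  expect_equal(go$group, "III")

  expect_error(get_model("nope"), "unknown model")
})

test_that("predictions honour each model's native-space expression", {
  # round trip: predict y2, push it back through the space transform,
  # and compare with the parameterized right-hand side
  d <- reg_dataset()
  st <- scfsolub:::as_state(d)
  for (nm in names(model_registry())) {
    spec <- get_model(nm)
    params <- if (spec$linear) unname(linear_fit(spec, d)) else
      unname(fit_model(spec, d, fit_config(n_starts = 1))$params)
    y <- predict_y2(spec, params, d)
    lhs_native <- scfsolub:::native_from_y2(spec$space, y, st)
    rhs_native <- scfsolub:::native_value(spec, params, st)
    expect_lt(max(abs(lhs_native - rhs_native) /
                    pmax(abs(rhs_native), 1e-10)), 1e-10,
              label = sprintf("%s native-space mismatch", nm))
  }
})

test_that("algebraic reductions of individual models hold", {
  d <- reg_dataset()
  r <- d$records
  # Chrastil with b = c = 0 is the constant S = exp(a)
  y_const <- predict_y2("chrastil", c(2, 0, 0), d)
  expect_equal(solubility_from_y2(r$rho_kg_m3, y_const, 44.01, 500.83),
               rep(exp(2), 24), tolerance = 1e-10)
  # Mendez-Santiago-Teja with a = b = c = 0 reduces to y2 = 1/P
  y_mst <- predict_y2("mendez_teja", c(0, 0, 0), d)
  expect_equal(y_mst, 1 / (r$P_bar / 10), tolerance = 1e-12)
  # deterministic and pure
  expect_identical(predict_y2("gordillo", c(1, -1, 0.01, 1e-4, -0.02, 1e-5), d),
                   predict_y2("gordillo", c(1, -1, 0.01, 1e-4, -0.02, 1e-5), d))
})

test_that("log-space models always predict positive mole fractions", {
  d <- reg_dataset()
  set.seed(11)
  for (nm in c("kumar_johnston", "gordillo", "rajasekhar_madras")) {
    spec <- get_model(nm)
    base <- unname(linear_fit(spec, d))
    for (i in 1:5) {
      p <- base * (1 + runif(spec$n_params, -0.05, 0.05))
      expect_true(all(predict_y2(spec, p, d) > 0))
    }
  }
})

test_that("Chrastil ln S is affine in ln rho at fixed T with slope b", {
  params <- c(-27.2, 5.47, -4190)
  rec <- data.frame(T_K = 318, P_bar = c(150, 151), rho_kg_m3 = c(744, 744.7),
                    y2 = c(1e-6, 1e-6))
  d <- scf_dataset(rec, reg_solute(), co2_solvent())
  y <- predict_y2("chrastil", params, d)
  lnS <- log(solubility_from_y2(rec$rho_kg_m3, y, 44.01, 500.83))
  slope <- diff(lnS) / diff(log(rec$rho_kg_m3))
  expect_equal(slope, params[2], tolerance = 1e-4)
})

test_that("exact linear solver recovers generating parameters and is OLS", {
  truth <- c(-27.2, 5.47, -4190)
  d <- generated_dataset("chrastil", truth)
  expect_rel_equal(unname(linear_fit("chrastil", d)), truth, 1e-8)

  # normal equations: residuals orthogonal to the design columns
  reg <- reg_dataset()
  st <- scfsolub:::as_state(reg)
  spec <- get_model("chrastil")
  X <- spec$design(st)
  z <- scfsolub:::native_from_y2("lnS", reg$records$y2, st)
  res <- z - drop(X %*% unname(linear_fit(spec, reg)))
  expect_lt(max(abs(crossprod(X, res))) / max(abs(crossprod(X, z))), 1e-10)

  # degenerate design: single isotherm makes 1/T collinear with 1
  one_iso <- scf_dataset(reg$records[reg$records$T_K == 308, ],
                         reg_solute(), co2_solvent())
  expect_error(linear_fit("del_valle_aguilera", one_iso), "rank-deficient")
  expect_error(linear_fit("yu", reg), "not linear")
})

test_that("OLS solution matches a brute-force grid-refine oracle", {
  # independent oracle: iteratively refined lattice search of the
  # native-space SSE for a 3-parameter model
  d <- reg_dataset()
  st <- scfsolub:::as_state(d)
  spec <- get_model("kumar_johnston")
  X <- spec$design(st)
  z <- log(d$records$y2)
  sse <- function(p) sum((z - drop(X %*% p))^2)
  # the intercept solves exactly given (b, c); brute-force the rest
  sse_bc <- function(bc) {
    r <- z - X[, 2] * bc[1] - X[, 3] * bc[2]
    sum((r - mean(r))^2)
  }
  ols <- unname(linear_fit(spec, d))
  centre <- ols[2:3] * c(1.4, 0.8)      # start deliberately off the optimum
  width <- abs(ols[2:3])
  for (round in 1:40) {
    grid <- expand.grid(b = centre[1] + width[1] * seq(-1, 1, length.out = 7),
                        c = centre[2] + width[2] * seq(-1, 1, length.out = 7))
    vals <- apply(grid, 1, sse_bc)
    centre <- as.numeric(grid[which.min(vals), ])
    width <- width * 0.6
  }
  expect_rel_equal(centre, ols[2:3], 1e-6)
  expect_lte(sse(ols), min(vals) * (1 + 1e-12))
})
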