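test_that("bundled dataset loads with the published structure", {
  d <- reg_dataset()
  expect_s3_class(d, "scf_dataset")
  expect_equal(n_records(d), 24L)
  expect_length(isotherms(d), 4L)
  expect_equal(sort(unique(d$records$T_K)), c(308, 318, 328, 338))
  row <- d$records[d$records$T_K == 338 & d$records$P_bar == 270, ]
  expect_equal(row$rho_kg_m3, 783)
  expect_equal(row$y2, 6.44e-6)
  expect_true(all(d$records$y2 >= 3.1e-7 & d$records$y2 <= 6.44e-6))
})

test_that("bundled dataset satisfies the expected monotonicity structure", {
  d <- reg_dataset()
  for (iso in isotherms(d)) {
    o <- order(iso$P_bar)
    expect_true(all(diff(iso$y2[o]) > 0))
    expect_true(all(diff(iso$rho_kg_m3[o]) > 0))
  }
  # at fixed pressure, density falls with temperature
  for (p in unique(d$records$P_bar)) {
    sl <- d$records[d$records$P_bar == p, ]
    expect_true(all(diff(sl$rho_kg_m3[order(sl$T_K)]) < 0))
  }
})

test_that("record validation rejects invariant violations with a named field", {
  base <- data.frame(T_K = 310, P_bar = 100, rho_kg_m3 = 700, y2 = 1e-6)
  sol <- reg_solute(); co2 <- co2_solvent()
  bad <- base; bad$y2 <- 1.5
  expect_error(scf_dataset(bad, sol, co2), "y2")
  bad <- base; bad$T_K <- -1
  expect_error(scf_dataset(bad, sol, co2), "T_K")
  expect_error(scf_dataset(base[, -3], sol, co2), "rho_kg_m3")
  dup <- rbind(base, base)
  expect_error(scf_dataset(dup, sol, co2), "duplicated")
  expect_error(scf_dataset(base[0, ], sol, co2), "at least one record")
})

test_that("reader reports malformed rows and the writer round-trips", {
  d <- reg_dataset()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_solubility(d, tmp)
  d2 <- read_solubility(tmp, reg_solute(), co2_solvent())
  expect_equal(d2$records, d$records, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("T_K,P_bar,rho_kg_m3,y2", "310,100,700,1e-6",
               "320,oops,700,1e-6"), bad)
  expect_error(read_solubility(bad, reg_solute(), co2_solvent()),
               "line 3")
})

test_that("sampling-loop conversion matches direct mole arithmetic", {
  su <- sampling_setup(V1 = 0.0006, V_col = 0.006, C = 0.05)
  got <- mole_fraction_from_sampling(su, rho1 = 783, M1 = 44.01, M2 = 500.83)
  n2 <- 0.05 * 0.006 / 500.83      # mol solute in vial
  n1 <- 0.0006 * 783 / 44.01       # mol CO2 in the loop
  expect_equal(got, n2 / (n1 + n2), tolerance = 1e-14)

  # no solute, no mole fraction
  su0 <- sampling_setup(0.0006, 0.006, 0)
  expect_equal(mole_fraction_from_sampling(su0, 783, 44.01, 500.83), 0)

  # doubling the collected mass and the loop volume together cancels
  su2 <- sampling_setup(0.0012, 0.012, 0.05)
  expect_equal(mole_fraction_from_sampling(su2, 783, 44.01, 500.83), got)

  expect_error(sampling_setup(0, 0.006, 0.05), "positive")
  expect_error(mole_fraction_from_sampling(su, -1, 44.01, 500.83), "positive")
})

test_that("gravimetric solubility conversion is exact and involutive", {
  # hand arithmetic: S = rho (M2/M1) y/(1-y)
  S <- solubility_from_y2(783, 6.44e-6, 44.01, 500.83)
  expect_equal(S, 783 * (500.83 / 44.01) * 6.44e-6 / (1 - 6.44e-6),
               tolerance = 1e-14)
  expect_equal(S, 5.74e-2, tolerance = 2e-3)
  expect_equal(solubility_from_y2(783, 0, 44.01, 500.83), 0)
  expect_error(solubility_from_y2(783, 1, 44.01, 500.83), "y2")

  d <- reg_dataset()$records
  S_all <- solubility_from_y2(d$rho_kg_m3, d$y2, 44.01, 500.83)
  back <- y2_from_solubility(d$rho_kg_m3, S_all, 44.01, 500.83)
  expect_rel_equal(back, d$y2, 1e-12)
})

test_that("expanded uncertainty combines relative terms in quadrature", {
  expect_equal(expanded_uncertainty(data.frame(P = 1, u_rel = 0.01),
                                    y = 100, k = 2), 2)
  expect_equal(expanded_uncertainty(data.frame(P = c(1, 1),
                                               u_rel = c(0.03, 0.03)),
                                    y = 1, k = 2), 2 * 0.03 * sqrt(2))
  expect_equal(expanded_uncertainty(data.frame(P = c(1, 2),
                                               u_rel = c(0, 0)), y = 5), 0)
  expect_error(expanded_uncertainty(data.frame(P = numeric(),
                                               u_rel = numeric()), y = 1),
               "empty")
  expect_error(expanded_uncertainty(data.frame(P = 1, u_rel = -0.1), y = 1),
               ">= 0")
})
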