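# Shared fixtures built in code.

# A small two-isotherm dataset with physically shaped values, handy for
# validation and diagnostics tests that don't need the bundled data.
toy_dataset <- function() {
  rec <- data.frame(
    T_K = rep(c(310, 330), each = 4),
    P_bar = rep(c(100, 150, 200, 250), 2),
    rho_kg_m3 = c(720, 790, 840, 880, 500, 640, 720, 780),
    y2 = c(1.0e-6, 1.6e-6, 2.1e-6, 2.5e-6,
           4.0e-7, 1.1e-6, 2.4e-6, 3.9e-6))
  scf_dataset(rec, reg_solute(), co2_solvent())
}

# Dataset whose ln y2 is exactly linear in P on each isotherm, with the
# two isotherms crossing at a known pressure (analytic crossover case).
crossing_dataset <- function(p_cross = 150, slope = 0.004) {
  P <- c(100, 150, 200)
  rec <- data.frame(
    T_K = rep(c(308, 318), each = 3),
    P_bar = rep(P, 2),
    rho_kg_m3 = rep(c(800, 850, 900), 2),
    y2 = c(exp(-13 + slope * (P - p_cross)),
           exp(-13 - slope * (P - p_cross))))
  scf_dataset(rec, reg_solute(), co2_solvent())
}

# Noise-free dataset generated from a named registry model.
generated_dataset <- function(model, params, sigma = 0, seed = 1L) {
  simulate_dataset(simulation_config(model, params, sigma = sigma,
                                     seed = seed))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
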