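# Internal: per-record state variables handed to every model.
#
# Canonical storage units are K, bar and kg/m3; models see pressure in
# MPa (so the Bartle/association reference pressure 0.1 MPa and the
# critical pressure in MPa line up), reduced variables formed from the
# solvent's critical constants, and density additionally as mol/mL for
# the association models (kg/m3 divided by 1000 * M1).
dataset_state <- function(records, solute, solvent) {
  M1 <- solvent$molar_mass
  M2 <- solute$molar_mass
  T <- records$T_K
  P <- records$P_bar / 10       # MPa
  rho <- records$rho_kg_m3
  list(
    T = T, P = P, P_bar = records$P_bar, rho = rho,
    Tr = T / solvent$T_c, Pr = P / solvent$P_c, rho_r = rho / solvent$rho_c,
    rho_mm = rho / (1000 * M1), # mol/mL
    lr = log(rho),
    M1 = M1, M2 = M2, n = nrow(records)
  )
}

as_state <- function(data, solute = NULL, solvent = NULL) {
  if (inherits(data, "scf_dataset"))
    return(dataset_state(data$records, data$solute, data$solvent))
  if (is.null(solute) || is.null(solvent))
    stop("solute and solvent must be supplied when data is a plain data frame")
  dataset_state(as.data.frame(data), solute, solvent)
}

# Native-space observations z for a model space, given observed y2.
native_from_y2 <- function(space, y2, st) {
  switch(space,
    lny = log(y2),
    y = y2,
    lnS = log(solubility_from_y2(st$rho, y2, st$M1, st$M2)),
    mst = st$T * log(y2 * st$P),
    bartle = log(y2 * st$P / 0.1),
    stop(sprintf("unknown prediction space '%s'", space))
  )
}

# Mole fraction from a native-space prediction f.
y2_from_native <- function(space, f, st) {
  switch(space,
    lny = exp(f),
    y = f,
    lnS = y2_from_solubility(st$rho, exp(f), st$M1, st$M2),
    mst = exp(f / st$T) / st$P,
    bartle = 0.1 * exp(f) / st$P,
    stop(sprintf("unknown prediction space '%s'", space))
  )
}
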