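---
title: "Correlating drug solubility in supercritical CO2: models, fitting and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating drug solubility in supercritical CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Solubility of a crystalline solid in supercritical CO₂ is measured on a
small isothermal grid: a handful of temperatures, a handful of pressures,
one equilibrium mole fraction y₂ per state, with the solvent density ρ₁
taken from a reference equation of state. The bundled dataset —
Regorafenib monohydrate (REG, M = 500.83 g/mol) in CO₂ — is typical:
4 isotherms (308–338 K) × 6 pressures (120–270 bar), y₂ between 3.1×10⁻⁷
and 6.44×10⁻⁶. Such tables are summarized by semi-empirical correlations
whose fitted constants carry thermodynamic meaning, and the field's
standard practice is to fit a whole battery of candidate equations and
compare them by AARD. This package implements that practice end to end.

Densities are *inputs*: the package deliberately contains no equation of
state. Mole-fraction records are validated on ingestion (positivity,
y₂ ∈ (0,1), unique (T, P) pairs, isotherms grouped by exact temperature
equality).

# Units and conversions

Storage units are K, bar and kg/m³ (the units the tables are printed in).
Internally every model receives pressure in MPa, so the 0.1 MPa reference
pressure of the Bartle and association models and the critical pressure
P_c = 7.39 MPa line up without per-model conversions. Density reaches the
association models as mol/mL (ρ₁/44 010) and the reduced-variable models
as ρ_r = ρ₁/467.6; T_r = T/304.12. For purely multiplicative unit choices
(e.g. bar vs MPa inside Gordillo's polynomial) the fitted AARD is
invariant — only the parameter values rescale.

The gravimetric solubility S (g/L) and the mole fraction are linked
exactly by S = ρ₁ (M₂/M₁) y₂/(1−y₂), and the package always recomputes S
from y₂ through this identity. The S column printed alongside the bundled
table is retained for reference but is *not* used in fitting: it is not
consistent with the monohydrate molar mass to printing precision, and
recomputing from y₂ avoids guessing how it was rounded.

Measurement-chain helpers mirror how such data are produced: moles of
solute from the collection-vial concentration (n₂ = C·V_col/M₂), moles of
CO₂ from the sampling loop (n₁ = V₁ρ₁/M₁), y₂ = n₂/(n₁+n₂), and expanded
uncertainty U = k·y·sqrt(Σ(Pᵢ·uᵢ)²) with coverage factor k = 2. The
sensitivity coefficients Pᵢ are user-supplied rather than derived
symbolically; published tables rarely list them, so no default set would
be defensible.

# The model registry

Twenty-five density-based correlations (Groups I–III by functional
dependence) plus three association-theory SLE models are registered; see
`model_catalogue()` for names, groups and formulas. Several published
renderings of these equations circulate with typographic damage (lost
fraction bars, merged exponents), so each registry entry documents the
canonical form this package implements. Three readings deserve explicit
justification:

- **Reddy et al.** is implemented in log space,
  ln y₂ = (a + b·P_r)·T_r² + (c + d·P_r)·T_r + e. The mole-fraction-space
  reading is sometimes printed, but parameter magnitudes reported for this
  model only make sense applied to ln y₂, and the descriptive text around
  it speaks of the *logarithm* of the solubility. On the bundled data the
  log-space form fits at ≈13% AARD versus ≈22% for the y₂-space form.
- **Mitra–Wilson** is implemented as
  ln S = a·ln P + b·T + c·P·T + d·P + e. A d^P reading of the fourth term
  also circulates; it requires d > 0, contradicts reported negative d
  values, and fits the bundled data at roughly twice the AARD of the d·P
  form, so the linear term is taken as the intended one.
- **Sparks et al.** uses the reduced-density form
  ln S = (a + b·ρ_r + c·ln T_r)·ln ρ_r + d + e/T_r + f/T_r².

The association models all share the prefactor (P/P*)^(κ−1), P* = 0.1 MPa,
with κ the association number, fitted as a continuous parameter in
[−10, 10] (reported values are non-integer and occasionally negative, in
which case κ is a free shape parameter without a stoichiometric reading).
The fugacity-based derivation behind them lumps sublimation pressure,
molar volume and fugacity-coefficient terms into the fitted constants;
those quantities are therefore not separately identifiable, and the
package exposes only the lumped working equations. Note that the
reduced-variable variant is an exact reparameterization of the
Rajasekhar–Madras form (1/T_r = T_c/T and ρ_r ∝ ρ₁), so the two
necessarily reach the same optimal AARD while reporting different
parameter values; both are kept because both parameterizations are used
in the literature. The pressure-term variant nests Rajasekhar–Madras at
C₃ = 0, which the test suite asserts as an identity.

The Yu et al. equation is implicit in y₂; since the implicit term is
linear, the package solves the closed-form rearrangement
y₂ = (a + bP + cP² + dPT + eT + fT²)/(1 + dPT) rather than iterating.
Its coupling parameter d is weakly identified at y₂ ~ 10⁻⁶ (the
(1 − y₂) factor is within 10⁻⁵ of 1), which is why the noiseless-recovery
test tolerates a looser parameter error for this one model while still
requiring essentially exact prediction recovery.

# Fitting

The objective is formed in mole-fraction space — AARD(%) by default,
matching how the models are ranked in practice, with SSE available for
sensitivity analysis. Fitting in y₂-space rather than each model's native
log space matters: the two weight residuals very differently when y₂
spans an order of magnitude.

The search is best-of-N multistart:

1. Start 1 is deterministic: every model except Yu is linear in its
   parameters in its native space (after the fixed offset and, where
   needed, an invertible reparameterization such as κ → κ−1 or
   a → ln a), so exact ordinary least squares provides it. For Yu, a
   profile initializer grids the nonlinear coupling d (signed,
   log-spaced) and solves the remaining five parameters exactly.
2. The other `n_starts − 1` (default 63) points are a Latin-hypercube
   sample, seed-controlled, drawn in a box centred on start 1 with
   half-width `2|p| + 0.1·mean|p|` per coordinate and clipped to the
   parameter bounds. Bounds default to |p| ≤ 10⁶ with per-model
   overrides (the Del Valle–Aguilera 1/T² coefficient is legitimately
   O(10⁶–10⁷); association κ ∈ [−10, 10]). Sampling around the exact
   linear solution, rather than uniformly over the full bounds, is what
   makes 64 starts informative in 3–8 dimensions.
3. Each start runs Nelder–Mead (relative tolerance 10⁻¹², per-parameter
   scaling, default 2000 iterations); AARD's absolute values make
   gradient-based solvers unattractive here. Out-of-bounds or
   non-finite proposals score a large penalty. The incumbent is then
   polished by up to 8 restarts until the objective stops improving.

The contract is "best local optimum found", not global optimality. The
result is bit-reproducible for a fixed seed; ties between starts break to
the lexicographically smallest parameter vector; and the returned
objective never exceeds the objective at the deterministic initializer.
A brute-force lattice-refinement oracle in the test suite confirms that
for 3-parameter models the multistart optimum agrees with an exhaustive
search to 10⁻³ in the objective.

## Scorecard conventions

AARD, R², R_adj, SSE, RMSE are computed in mole-fraction space. Two
deliberate conventions: RMSE is reported as √SSE *without* dividing by N,
so the SSE and RMSE columns of a report are definitionally consistent
(the conventional per-point quantity is exposed as `rmse_mean`); and
R_adj uses the absolute-value form |R² − Q(1−R²)/(N−Q−1)| with Q the
number of *independent variables* of the model (3 for Group I and the
association models, 2 for Groups II–III), not its parameter count. A
nonstandard R² variant whose denominator compares predictions to the
observed mean is occasionally printed in this literature; it is exposed
as `r2_printed` but never used for ranking.

# Enthalpies

With ln S (Chrastil) or ln y₂ (Kumar–Johnston) affine in 1/T, the
coefficient c estimates −ΔH_tot/R; Bartle's c estimates −ΔH_vap/R; and
ΔH_sol = mean(ΔH_tot) − ΔH_vap. `enthalpies()` fits the three models
deterministically — exact OLS followed by the Nelder–Mead AARD polish,
no random starts. The polish step is not cosmetic: on the bundled data
pure log-space OLS under-weights the high-solubility points and yields a
total enthalpy several percent lower than the AARD-consistent value that
this literature reports; polishing in mole-fraction space aligns the
extraction with how the correlations themselves are fitted, while
remaining fully deterministic. ΔH_sol comes out negative (solvation is
exothermic); the report stores the signed value and prints the magnitude,
which is the common reporting convention.

# Diagnostics

**Self-consistency.** Each of Chrastil, Kumar–Johnston, Bartle and
Méndez-Santiago–Teja linearizes into coordinates in which all isotherms
should collapse onto a single straight line once the fitted temperature
term is removed (e.g. Bartle: x = ρ₁ − 700, y = ln(y₂P/P_ref) − c/T).
The diagnostic pools all records, fits one line, and reports the pooled
R² plus per-point residuals. The temperature coefficient is taken from
the exact OLS fit, which is sufficient for a collapse diagnostic and
keeps it solver-free. Exactly generated data give R² = 1; shuffling y₂
across records destroys the collapse, which the tests use as a negative
control.

**Crossover.** For every isotherm pair, ln y₂ is interpolated against P
piecewise-linearly (a spline on 6-point isotherms invites spurious
crossings), the sign changes of the difference are located on the common
pressure range, and each bracketing segment is solved linearly for the
intersection pressure. Pairs with identical curves are reported as
degenerate rather than as a continuum of crossings; non-overlapping
pressure ranges are skipped with a note. The envelope of all intersection
pressures is the crossover band — for the bundled data it sits around
190–200 bar, inside the 180–210 bar window expected from the isotherm
plots.

# Synthetic data

`simulate_dataset()` emulates the structure of the measured tables: a
T × P grid (default the bundled 4 × 6 design), densities from a bilinear
interpolant of the bundled ρ(T, P) table (exact at the grid nodes,
extrapolation refused — again, no equation of state), truth from any
registered model, and multiplicative lognormal noise
y₂ = truth · exp(ε), ε ~ N(0, σ²). Multiplicative noise is the right
default because replicate solubility measurements show roughly constant
*relative* scatter; the bundled table's standard deviations are 2–30% of
y₂ with no trend in the mean. σ = 0.05 is the reference noise level used
in the recovery tests, consistent with that scatter.

What the generator does *not* emulate: the UV-calibration measurement
chain (the conversion helpers are exercised directly instead),
temperature/pressure setpoint error, correlated errors within an
isotherm, and any model-misspecification structure — simulated data are
drawn from a registry model, real data are not. Passing recovery tests
therefore demonstrate that the estimator is consistent and identifiable
under the stated noise model, not that any model is "true" for real
measurements.

`recovery_study()` loops simulate → fit over replicates (replicate r
uses seed + r − 1), reporting per-parameter relative bias and RMSE and
the AARD distribution. The test suite runs it at σ = 0.05 with 20
replicates for five representative, well-conditioned models (Chrastil,
Kumar–Johnston, Bartle, Méndez-Santiago–Teja, Rajasekhar–Madras) and
requires every median parameter error under 15%. Heavily parameterized
registry members (e.g. the 8-parameter Belghait equation) are *not*
expected to be identifiable from 24 points under noise; they are covered
by the noiseless-recovery property instead.

# Problem sizes and determinism

The shipped configuration fits 24-point datasets with 64 starts per
model; a full 28-model report takes on the order of a minute on one core,
and the property suite uses reduced start counts (1–8) where the exact
initializer already solves the problem. All randomness (multistart draws,
simulated noise) flows from explicit integer seeds; `reproduce_study()`
fixes its seed by default and writes a manifest (package version, seed,
start count, dataset checksum) sufficient to re-run bit-identically.

# Known limitations

- Densities must be supplied (or interpolated within the bundled grid);
  states outside 308–338 K × 120–270 bar need a user density table.
- The multistart search documents no global-optimality guarantee, and no
  parameter uncertainties are attached to fits.
- Typographically ambiguous published forms (Sparks, Mitra–Wilson, some
  Group I renderings) are resolved to the canonical readings documented
  above; alternative readings would change those models' AARDs by a few
  points.
- Binary systems only: the association models assume the solvent mole
  fraction is ≈ 1, which is excellent at y₂ ~ 10⁻⁶ but rules out
  cosolvent work.
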