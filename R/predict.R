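#' Predict mole-fraction solubility from a model
#'
#' Evaluates a registered model in its native prediction space (log
#' mole fraction, mole fraction, log gravimetric solubility, or one of
#' the Mendez-Santiago-Teja / Bartle transformed spaces) and converts
#' the result to mole fraction `y2`.
#'
#' @param model An `scf_model` spec or registry name.
#' @param params Numeric parameter vector in the model's canonical
#'   order (see `model_catalogue()$formula`).
#' @param data An `scf_dataset`, or a data frame of records with
#'   columns `T_K`, `P_bar`, `rho_kg_m3` (then `solute` and `solvent`
#'   must be given).
#' @param solute,solvent Required when `data` is a plain data frame.
#' @return Numeric vector of predicted mole fractions, one per record.
#' @export
#' @examples
#' d <- reg_dataset()
#' p <- linear_fit(get_model("chrastil"), d)
#' predict_y2("chrastil", p, d)
predict_y2 <- function(model, params, data, solute = NULL, solvent = NULL) {
  spec <- get_model(model)
  params <- as.numeric(params)
  if (length(params) != spec$n_params)
    stop(sprintf("%s: expected %d parameters, got %d", spec$name,
                 spec$n_params, length(params)))
  st <- as_state(data, solute, solvent)
  f <- native_value(spec, params, st)
  if (any(!is.finite(f)))
    stop(sprintf("%s: non-finite native-space value at record %d (check parameter signs and magnitudes)",
                 spec$name, which(!is.finite(f))[1L]))
  y2_from_native(spec$space, f, st)
}

# Quiet variant for optimizer internals: returns NULL instead of
# raising on non-finite intermediates.
predict_y2_quiet <- function(spec, params, st) {
  f <- native_value(spec, params, st)
  if (any(!is.finite(f))) return(NULL)
  y <- y2_from_native(spec$space, f, st)
  if (any(!is.finite(y))) return(NULL)
  y
}
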