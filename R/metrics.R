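#' Average absolute relative deviation, in percent
#'
#' `AARD = 100 / N * sum(|pred - obs| / obs)`, the headline
#' goodness-of-fit statistic for solubility correlations.  It is
#' invariant under common rescaling of both vectors.
#'
#' @param observed Observed values, strictly nonzero.
#' @param predicted Predicted values, same length.
#' @return AARD in percent.
#' @export
#' @examples
#' aard(c(1, 2), c(1.1, 1.8))  # 10
aard <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    stop("aard: observed and predicted must be equal-length, nonempty vectors")
  if (any(observed == 0))
    stop("aard: observed values must be nonzero")
  100 * mean(abs(predicted - observed) / abs(observed))
}

#' Five-statistic goodness-of-fit scorecard
#'
#' Computes, in mole-fraction space: AARD percent, the coefficient of
#' determination `R2 = 1 - SSE / SStot` (total sum of squares about the
#' observed mean), the adjusted coefficient
#' `R_adj = |R2 - Q (1 - R2) / (N - Q - 1)|` where `Q` is the number of
#' independent variables in the model, `SSE = sum((obs - pred)^2)`, and
#' `RMSE = sqrt(SSE)` (the square root of SSE without division by N, so
#' that the SSE and RMSE columns of a report are internally consistent;
#' the conventional per-point variant is reported as `rmse_mean`).  A
#' nonstandard published variant of R2 whose denominator is
#' `sum((mean(obs) - pred)^2)` is exposed as `r2_printed`.
#'
#' @inheritParams aard
#' @param Q Number of independent variables of the model (not its
#'   parameter count).
#' @return Named list with `aard`, `r2`, `r_adj`, `sse`, `rmse`, plus
#'   `rmse_mean` and `r2_printed`.
#' @export
scorecard <- function(observed, predicted, Q) {
  n <- length(observed)
  if (n <= Q + 1)
    stop("scorecard: need N > Q + 1 observations for the adjusted R2")
  sse <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  r2 <- 1 - sse / sstot
  denom_printed <- sum((mean(observed) - predicted)^2)
  list(
    aard = aard(observed, predicted),
    r2 = r2,
    r_adj = abs(r2 - Q * (1 - r2) / (n - Q - 1)),
    sse = sse,
    rmse = sqrt(sse),
    rmse_mean = sqrt(sse / n),
    r2_printed = if (denom_printed > 0) 1 - sse / denom_printed else NA_real_
  )
}
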