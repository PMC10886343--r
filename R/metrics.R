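#' Prediction-quality metrics for a model against observations
#'
#' The four statistics customarily tabulated when comparing response-surface
#' and neural-network predictions: the coefficient of determination
#' R2 = 1 - SSE/SStot, the root mean squared error, the absolute average
#' deviation AAD% = 100/n * sum(|pred - obs| / pred) (deviations relative
#' to the predicted value), and the standard error of prediction
#' SEP% = 100 * RMSE / mean(obs).
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return List of class `comparison_report` with `r2`, `rmse`, `aad_pct`,
#'   `sep_pct`, `n` and `mean_obs`.
#' @examples
#' compare_predictions(c(1, 2, 3), c(1, 2, 4))
#' @export
compare_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ym <- mean(observed)
  if (ym == 0) stop("mean observed response is zero", call. = FALSE)
  sst <- sum((observed - ym)^2)
  if (sst == 0) {
    stop("observed responses have zero variance: R2 undefined", call. = FALSE)
  }
  rmse <- sqrt(mean((observed - predicted)^2))
  structure(
    list(r2 = 1 - sum((observed - predicted)^2) / sst,
         rmse = rmse,
         aad_pct = 100 * mean(abs(predicted - observed) / predicted),
         sep_pct = 100 * rmse / ym,
         n = length(observed), mean_obs = ym),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("n = %d | R2 %.4f | RMSE %.4f | AAD%% %.4f | SEP%% %.4f\n",
              x$n, x$r2, x$rmse, x$aad_pct, x$sep_pct))
  invisible(x)
}

#' Side-by-side comparison table for several prediction sets
#'
#' @param observed Numeric vector of observations.
#' @param predictions Named list of predicted vectors (e.g. RSM and ANN).
#' @return Data frame, one row per metric and one column per model.
#' @export
comparison_table <- function(observed, predictions) {
  reports <- lapply(predictions, compare_predictions, observed = observed)
  out <- data.frame(metric = c("r2", "rmse", "aad_pct", "sep_pct"))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    out[[nm]] <- c(r$r2, r$rmse, r$aad_pct, r$sep_pct)
  }
  out
}

#' Validate a model prediction against a confirmatory measurement
#'
#' The relative standard error RSE% = 100 * (actual - predicted)/predicted
#' keeps the sign of the discrepancy; the relative standard deviation
#' RSD% = 100 * sd(actual, predicted) / mean(actual, predicted) uses the
#' two-value sample standard deviation |a - b|/sqrt(2). Agreement is
#' conventionally declared when RSD < 10% and |RSE| < 5%.
#'
#' @param actual Measured value at the validated optimum.
#' @param predicted Model-predicted value (> 0).
#' @param rsd_limit,rse_limit Pass thresholds in percent.
#' @return List of class `validation_report` with `actual`, `predicted`,
#'   `rsd_pct`, `rse_pct`, `rsd_pass`, `rse_pass`.
#' @examples
#' validate_optimum(77.52, 75.56)  # RSD 1.81, RSE 2.59
#' @export
validate_optimum <- function(actual, predicted, rsd_limit = 10, rse_limit = 5) {
  if (predicted <= 0) {
    stop("predicted value must be positive", call. = FALSE)
  }
  rsd <- 100 * stats::sd(c(actual, predicted)) / mean(c(actual, predicted))
  rse <- 100 * (actual - predicted) / predicted
  structure(
    list(actual = actual, predicted = predicted,
         rsd_pct = rsd, rse_pct = rse,
         rsd_pass = rsd < rsd_limit, rse_pass = abs(rse) < rse_limit),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("actual %.4g vs predicted %.4g: RSD%% = %.2f (%s), RSE%% = %.2f (%s)\n",
              x$actual, x$predicted,
              x$rsd_pct, if (x$rsd_pass) "pass" else "FAIL",
              x$rse_pct, if (x$rse_pass) "pass" else "FAIL"))
  invisible(x)
}
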