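#' Root-mean-squared error
#'
#' @param y Observed yields (Mg/ha).
#' @param yhat Predicted yields (Mg/ha).
#' @return RMSE in Mg/ha.
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Relative root-mean-squared error
#'
#' RMSE divided by the mean of the observed values; a dimensionless fraction
#' (multiply by 100 to report percent).
#'
#' @inheritParams rmse
#' @return RRMSE as a fraction.
#' @export
rrmse <- function(y, yhat) {
  check_metric_input(y, yhat)
  m <- mean(y)
  if (m == 0) stop("rrmse undefined: mean of observed values is zero")
  rmse(y, yhat) / m
}

#' Mean absolute percentage error (mean-normalized)
#'
#' Mean absolute error divided by the mean of the observed values, so the
#' statistic does not grow with sample size. `literal = TRUE` instead returns
#' the raw sum of absolute errors over the observed mean (no 1/n), for
#' comparison against formulations that omit the averaging.
#'
#' @inheritParams rmse
#' @param literal If TRUE, skip the 1/n averaging of absolute errors.
#' @return MAPE as a fraction.
#' @export
mape <- function(y, yhat, literal = FALSE) {
  check_metric_input(y, yhat)
  m <- mean(y)
  if (m == 0) stop("mape undefined: mean of observed values is zero")
  ae <- abs(y - yhat)
  if (literal) sum(ae) / m else mean(ae) / m
}

#' Pearson correlation between observed and predicted values
#'
#' @inheritParams rmse
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (length(y) < 2) stop("pearson requires at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("pearson undefined: zero variance in one of the vectors")
  stats::cor(y, yhat)
}

check_metric_input <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) == 0) stop("empty input")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("metric input must be finite")
  invisible(TRUE)
}

#' Evaluate predictions overall and per treatment
#'
#' Computes RMSE, RRMSE, MAPE and Pearson correlation on the full vector and
#' within every treatment class. Pearson is NA (flagged, not an error) for
#' treatments with fewer than 2 rows or zero variance.
#'
#' @inheritParams rmse
#' @param treatments Treatment label per observation.
#' @return A `metrics_report`: list with `overall` (one-row data.frame) and
#'   `by_treatment` (one row per treatment, with its n).
#' @export
evaluate_by_treatment <- function(y, yhat, treatments) {
  check_metric_input(y, yhat)
  if (length(treatments) != length(y))
    stop("treatments must have one label per observation")
  one <- function(yy, pp) {
    p <- tryCatch(pearson(yy, pp), error = function(e) NA_real_)
    data.frame(
      n = length(yy), rmse = rmse(yy, pp), rrmse = rrmse(yy, pp),
      mape = mape(yy, pp), pearson = p
    )
  }
  overall <- one(y, yhat)
  split_idx <- split(seq_along(y), treatments)
  by_treat <- do.call(rbind, lapply(names(split_idx), function(tr) {
    i <- split_idx[[tr]]
    cbind(treatment = tr, one(y[i], yhat[i]))
  }))
  rownames(by_treat) <- NULL
  structure(list(overall = overall, by_treatment = by_treat),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Overall:\n")
  print(format_metrics(x$overall), row.names = FALSE)
  cat("\nBy treatment:\n")
  print(cbind(treatment = x$by_treatment$treatment,
              format_metrics(x$by_treatment)), row.names = FALSE)
  invisible(x)
}

format_metrics <- function(df) {
  data.frame(
    n = df$n,
    `RMSE (Mg/ha)` = round(df$rmse, 3),
    `RRMSE (%)` = round(100 * df$rrmse, 1),
    `MAPE (%)` = round(100 * df$mape, 1),
    `Pearson r` = round(df$pearson, 3),
    check.names = FALSE
  )
}
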