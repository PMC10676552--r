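#' Validation statistic battery
#'
#' For a (observed, predicted) pairing this computes the residual sum of
#' squares RSS, the total sum of squares SS about the observed mean, the
#' coefficient of determination \eqn{R^2 = 1 - RSS/SS}, the adjusted
#' \eqn{R^2}, the Pearson correlation R of predictions against
#' observations, the predictive squared correlation
#' \eqn{Q^2 = 1 - PRESS/SS} (PRESS being the squared prediction error, so
#' on a single pairing PRESS equals RSS; the distinction matters when the
#' pairing is a held-out set), and the error magnitudes MSE = RSS/n,
#' RMSE and MAE.
#'
#' @param y_obs observed responses (length >= 3, not constant).
#' @param y_pred predicted responses, same length.
#' @param n_predictors predictor count for the adjusted \eqn{R^2}
#'   (default 0 reduces it to plain \eqn{R^2} up to the n-1 factor).
#' @return object of class `metrics_report`: list with `n`, `ss`, `rss`,
#'   `press`, `r`, `r2`, `r2_adjusted`, `q2`, `mse`, `rmse`, `mae`.
#' @export
fit_metrics <- function(y_obs, y_pred, n_predictors = 0L) {
  if (length(y_obs) != length(y_pred))
    stop("observed and predicted lengths differ", call. = FALSE)
  n <- length(y_obs)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  ss <- sum((y_obs - mean(y_obs))^2)
  if (ss == 0) stop("observed responses are constant (SS = 0)", call. = FALSE)
  rss <- sum((y_pred - y_obs)^2)
  r2 <- 1 - rss / ss
  r2_adj <- if (n - n_predictors - 1L > 0)
    1 - (1 - r2) * (n - 1) / (n - n_predictors - 1) else NA_real_
  out <- list(n = n, ss = ss, rss = rss, press = rss,
              r = if (stats::sd(y_pred) == 0) NA_real_
                  else stats::cor(y_pred, y_obs),
              r2 = r2, r2_adjusted = r2_adj, q2 = 1 - rss / ss,
              mse = rss / n, rmse = sqrt(rss / n),
              mae = mean(abs(y_pred - y_obs)))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  R = %.4f  R2 = %.4f  adjR2 = %.4f  Q2 = %.4f\n",
              x$n, x$r, x$r2, x$r2_adjusted, x$q2))
  cat(sprintf("MSE = %.6f  RMSE = %.6f  MAE = %.6f\n", x$mse, x$rmse, x$mae))
  invisible(x)
}

#' Predictive squared correlation on a held-out set
#'
#' \eqn{Q^2 = 1 - PRESS/SS} where PRESS is the sum of squared prediction
#' errors on the held-out compounds. By default SS is taken about the
#' held-out set's own observed mean (each set self-referenced); pass a
#' precomputed `ss_reference` (e.g. about the training mean) to use the
#' alternative convention. \eqn{Q^2} can be negative — a model worse than
#' predicting the mean — and is never clipped.
#'
#' @param y_obs,y_pred held-out observations and predictions (non-empty).
#' @param ss_reference optional positive total sum of squares to reference
#'   PRESS against; `NULL` computes SS about `mean(y_obs)`.
#' @return scalar \eqn{Q^2}.
#' @export
external_q2 <- function(y_obs, y_pred, ss_reference = NULL) {
  if (length(y_obs) == 0L) stop("held-out set is empty", call. = FALSE)
  if (length(y_obs) != length(y_pred))
    stop("observed and predicted lengths differ", call. = FALSE)
  press <- sum((y_pred - y_obs)^2)
  ss <- if (is.null(ss_reference)) sum((y_obs - mean(y_obs))^2) else ss_reference
  if (!is.finite(ss) || ss <= 0)
    stop("reference sum of squares must be positive", call. = FALSE)
  1 - press / ss
}

#' Robustness gap between training fit and predictive power
#'
#' The gap \eqn{R^2_{train} - Q^2} measures how much apparent fit is lost
#' out of sample; a gap not exceeding 0.3 is the conventional robustness
#' screen for QSAR models.
#'
#' @param r2_train training \eqn{R^2} (at most 1).
#' @param q2 predictive \eqn{Q^2} (at most 1).
#' @param threshold pass threshold on the gap, default 0.3.
#' @return list with `gap` and logical `pass`.
#' @export
robustness_gap <- function(r2_train, q2, threshold = 0.3) {
  stopifnot(r2_train <= 1, q2 <= 1)
  gap <- r2_train - q2
  list(gap = gap, pass = gap <= threshold)
}
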