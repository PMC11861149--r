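# Regression metrics for predicted vGRF curves: R^2, MAPE (%), rMSE.

curve_pair <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat))) {
    stop("y and y_hat must have identical shapes", call. = FALSE)
  }
  list(y = y, y_hat = y_hat)
}

#' Coefficient of determination R^2
#'
#' `R^2 = 1 - SSE/SST` with SST taken around the mean of the true values.
#' For curve matrices (one curve per row) the default computes R^2 per
#' curve and averages across curves; `pooled = TRUE` instead pools all
#' points into one R^2. Curves with constant true values have an undefined
#' R^2 and are dropped with a warning (`NA` if all are constant).
#'
#' @param y true values (vector, or matrix of curves in rows).
#' @param y_hat predicted values, same shape.
#' @param pooled pool all points instead of averaging per-curve values.
#' @return scalar R^2 (<= 1).
#' @export
r_squared <- function(y, y_hat, pooled = FALSE) {
  p <- curve_pair(y, y_hat)
  if (pooled || is.null(dim(y))) {
    yv <- as.numeric(p$y); pv <- as.numeric(p$y_hat)
    sst <- sum((yv - mean(yv))^2)
    if (sst == 0) {
      warning("constant true values: R^2 undefined")
      return(NA_real_)
    }
    return(1 - sum((pv - yv)^2) / sst)
  }
  sse <- rowSums((p$y_hat - p$y)^2)
  sst <- rowSums((p$y - rowMeans(p$y))^2)
  const <- sst == 0
  if (any(const)) {
    warning(sum(const), " curve(s) with constant true values dropped from R^2")
    if (all(const)) return(NA_real_)
  }
  mean(1 - sse[!const] / sst[!const])
}

#' Mean absolute percentage error (percent)
#'
#' `100/n * sum(|y_hat - y| / |y|)` over the points whose true magnitude is
#' at least `floor`. The floor (default 0.05 on the min-max-normalized
#' scale) keeps the near-zero force samples at touch-down and toe-off from
#' blowing the percentage up; set `floor = 0` to disable.
#'
#' @param y true values.
#' @param y_hat predicted values, same shape.
#' @param floor smallest `|y|` included in the average.
#' @return MAPE in percent (`NA` with a warning if every point is masked).
#' @export
mape <- function(y, y_hat, floor = 0.05) {
  p <- curve_pair(y, y_hat)
  keep <- abs(p$y) >= floor
  if (!any(keep)) {
    warning("all points below the MAPE floor: MAPE undefined")
    return(NA_real_)
  }
  100 * mean(abs((p$y_hat[keep] - p$y[keep]) / p$y[keep]))
}

#' Root mean squared error
#'
#' The square root of the mean squared residual over all points.
#'
#' @param y true values.
#' @param y_hat predicted values, same shape.
#' @return scalar rMSE on the scale of `y`.
#' @export
rmse <- function(y, y_hat) {
  p <- curve_pair(y, y_hat)
  sqrt(mean((p$y_hat - p$y)^2))
}
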