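#' Validation metrics: RMSE and coefficient of determination
#'
#' `rmse(y, y_pred)` is `sqrt(SS_res / n)` with
#' `SS_res = sum((y - y_pred)^2)`. `r_squared(y, y_pred)` is
#' `1 - SS_res / SS_tot` with `SS_tot = sum((y - mean(y))^2)`. Both operate
#' on the 0--100 percent-open scale throughout the package, so RMSE values
#' are in percentage points. A constant reference vector makes R^2
#' undefined and raises an error rather than returning a silent value.
#'
#' @param y observed values.
#' @param y_pred predicted values, same length.
#' @return a single number.
#' @examples
#' rmse(c(0, 1, 2), c(1, 1, 1))       # sqrt(2/3)
#' r_squared(c(0, 1, 2), c(1, 1, 1))  # 0
#' @export
rmse <- function(y, y_pred) {
  stopifnot(length(y) == length(y_pred), length(y) >= 1)
  sqrt(mean((y - y_pred)^2))
}

#' @rdname rmse
#' @export
r_squared <- function(y, y_pred) {
  stopifnot(length(y) == length(y_pred), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: reference values are constant", call. = FALSE)
  1 - sum((y - y_pred)^2) / ss_tot
}
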