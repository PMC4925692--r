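#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that refuses degenerate input instead
#' of returning `NA`: zero variance in either variable is an error, because
#' a silently undefined correlation would be indistinguishable from a real
#' value in a sweep table.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return The correlation coefficient, in \eqn{[-1, 1]}.
#' @examples
#' pearson_r(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  stats::cor(x, y)
}

#' Ordinary least-squares line
#'
#' Slope and intercept of the least-squares regression of `y` on `x`, the
#' convention of a spreadsheet trend line: slope
#' \eqn{= \mathrm{cov}(x,y)/\mathrm{var}(x)}, intercept fitted.
#'
#' @inheritParams pearson_r
#' @return Named numeric vector `c(slope = ..., intercept = ...)`.
#' @examples
#' ols_fit(1:4, c(1, 3, 2, 4))  # slope 0.8, intercept 0.5
#' @export
ols_fit <- function(x, y) {
  check_xy(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length.", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("need at least 2 paired observations.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values in `x` or `y`; drop pairs before fitting.", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation/slope undefined for constant input.",
         call. = FALSE)
  }
  invisible(NULL)
}
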