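#' Forward Lassen count-flow transform
#'
#' Maps a relative flow value \eqn{F/F_r} to the expected SPECT count ratio
#' \eqn{C/C_r} under the (extended) Lassen equation
#' \deqn{C/C_r = \frac{F/F_r \, (1 + \alpha)}{F/F_r + \alpha}.}
#' The transform models the flow-dependent back-diffusion of Tc-99m HMPAO:
#' counts saturate towards \eqn{1 + \alpha} at high flow, compressing image
#' contrast above the reference level. All quantities are dimensionless
#' ratios to a reference region (conventionally the cerebellum).
#'
#' @param flow_ratio numeric vector of relative flow values \eqn{F/F_r};
#'   must be non-negative.
#' @param alpha Lassen's parameter (scalar, strictly positive). Smaller
#'   values correspond to stronger count-flow nonlinearity.
#'
#' @return Numeric vector of expected count ratios, in \eqn{[0, 1+\alpha)}.
#'   The reference value maps to itself: `lassen_forward(1, alpha) == 1`.
#'
#' @examples
#' lassen_forward(c(0.5, 1, 2), alpha = 0.5)  # 0.75, 1, 1.2
#' @seealso [lassen_inverse()] for the correction (the exact inverse).
#' @export
lassen_forward <- function(flow_ratio, alpha) {
  check_alpha(alpha)
  if (!is.numeric(flow_ratio)) {
    stop("`flow_ratio` must be numeric.", call. = FALSE)
  }
  if (any(flow_ratio < 0, na.rm = TRUE)) {
    stop("`flow_ratio` must be non-negative: flows are ratios to a reference region.",
         call. = FALSE)
  }
  flow_ratio * (1 + alpha) / (flow_ratio + alpha)
}

#' Inverse Lassen transform (the linearization correction)
#'
#' Applies Lassen's linearization correction, mapping a measured count ratio
#' \eqn{C/C_r} to the corrected tracer accumulation ratio
#' \deqn{A/A_r = \frac{\alpha \, C/C_r}{1 + \alpha - C/C_r},}
#' the exact functional inverse of [lassen_forward()] at the same `alpha`.
#' The correction is singular at \eqn{C/C_r = 1 + \alpha} and is only a
#' faithful inverse on the open interval \eqn{(0, 1 + \alpha)}; statistical
#' noise can push measured ratios outside it, which `guard` controls.
#'
#' @param count_ratio numeric vector of measured count ratios \eqn{C/C_r}.
#' @param alpha correction parameter (scalar, strictly positive). Smaller
#'   `alpha` gives stronger compensation; the classical value is 1.5, the
#'   value matching integrated first-pass extraction plus back-diffusion
#'   for HMPAO is 0.5.
#' @param guard policy for count ratios outside \eqn{(0, 1+\alpha)}:
#'   \describe{
#'     \item{`"raw"`}{compute the formula as-is (the spreadsheet behaviour);
#'       values beyond the singularity come back negative. An input exactly
#'       at the singularity \eqn{1+\alpha} is an error, never an infinity.}
#'     \item{`"exclude"`}{return `NA` for out-of-domain inputs so paired
#'       statistics can drop them.}
#'     \item{`"clip"`}{clamp inputs into
#'       \eqn{[\epsilon, 1+\alpha-\epsilon]}, \eqn{\epsilon = 10^{-9}},
#'       before inverting.}
#'   }
#'   Out-of-domain inputs are never silently altered: use [lassen_correct()]
#'   to obtain the flags alongside the corrected values.
#'
#' @return Numeric vector of corrected accumulation ratios \eqn{A/A_r}.
#'
#' @examples
#' lassen_inverse(1.2, alpha = 0.5)   # 2: undoes lassen_forward(2, 0.5)
#' lassen_inverse(1.2, alpha = 1.5)   # ~1.385: weaker correction
#' @export
lassen_inverse <- function(count_ratio, alpha,
                           guard = c("raw", "exclude", "clip")) {
  guard <- match.arg(guard)
  check_alpha(alpha)
  if (!is.numeric(count_ratio)) {
    stop("`count_ratio` must be numeric.", call. = FALSE)
  }
  upper <- 1 + alpha
  x <- as.numeric(count_ratio)
  if (guard == "raw" && any(x == upper, na.rm = TRUE)) {
    stop("count ratio equal to 1 + alpha = ", format(upper),
         ": Lassen's correction is singular there (guard = \"raw\").",
         call. = FALSE)
  }
  if (guard == "clip") {
    eps <- 1e-9
    x <- pmin(pmax(x, eps), upper - eps)
  }
  corrected <- alpha * x / (upper - x)
  if (guard == "exclude") {
    corrected[!is_invertible(count_ratio, alpha)] <- NA_real_
  }
  corrected
}

#' Correct a series of count ratios, with diagnostics
#'
#' Vectorised correction of a simulated (or measured) count-ratio series,
#' recording which observations fell outside the invertible domain
#' \eqn{(0, 1 + \alpha)}. Pairing with the flow values is preserved through
#' the `flagged` logical vector, so downstream statistics under
#' `guard = "exclude"` can drop matched pairs rather than single values.
#'
#' @inheritParams lassen_inverse
#' @param count_ratios non-empty numeric vector of count ratios.
#'
#' @return A list of class `"lassen_correction"`:
#'   \describe{
#'     \item{`corrected`}{numeric vector, same length as the input
#'       (`NA` where excluded).}
#'     \item{`flagged`}{logical vector marking inputs outside
#'       \eqn{(0, 1+\alpha)} under every policy.}
#'     \item{`n_flagged`}{number of flagged inputs.}
#'     \item{`alpha`, `guard`}{the settings used.}
#'   }
#'
#' @examples
#' lassen_correct(c(0.75, 1, 1.2), alpha = 0.5)$corrected  # 0.5, 1, 2
#' @export
lassen_correct <- function(count_ratios, alpha,
                           guard = c("raw", "exclude", "clip")) {
  guard <- match.arg(guard)
  if (length(count_ratios) == 0L) {
    stop("`count_ratios` must be non-empty.", call. = FALSE)
  }
  flagged <- !is_invertible(count_ratios, alpha)
  corrected <- lassen_inverse(count_ratios, alpha, guard = guard)
  if (guard == "exclude" && all(flagged)) {
    stop("all ", length(count_ratios),
         " count ratios fall outside (0, 1 + alpha); no data left.",
         call. = FALSE)
  }
  structure(
    list(corrected = corrected, flagged = flagged,
         n_flagged = sum(flagged), alpha = alpha, guard = guard),
    class = "lassen_correction"
  )
}

# domain of the exact inverse: the open interval (0, 1 + alpha)
is_invertible <- function(count_ratio, alpha) {
  count_ratio > 0 & count_ratio < 1 + alpha
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single positive number (the correction is degenerate at alpha = 0).",
         call. = FALSE)
  }
  invisible(alpha)
}

#' @export
print.lassen_correction <- function(x, ...) {
  cat("Lassen correction: alpha =", format(x$alpha),
      "| guard =", x$guard,
      "| n =", length(x$corrected),
      "| flagged =", x$n_flagged, "\n")
  invisible(x)
}
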