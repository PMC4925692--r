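#' Generate relative flow values
#'
#' Draws `n` independent relative flow values \eqn{F/F_r} from
#' \eqn{Normal(mean, sd)}. The defaults reproduce the simulated cohort of
#' the study conditions: 1000 points, mean 1 (the reference level),
#' SD 0.18, which places essentially all mass between roughly 0.5 and 1.5.
#' Non-positive draws (probability ~1.5e-8 per draw at the defaults) are
#' redrawn from the same seeded stream so every flow is strictly positive
#' while the output remains a pure function of `seed`.
#'
#' @param n number of flow values (>= 2).
#' @param mean,sd parameters of the generating normal distribution
#'   (dimensionless; `sd > 0`).
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible. `NULL` uses the current RNG state.
#'
#' @return Numeric vector of `n` strictly positive flow ratios.
#' @examples
#' f <- generate_flow_ratios(1000, seed = 1)
#' c(mean(f), sd(f))  # ~1, ~0.18
#' @export
generate_flow_ratios <- function(n, mean = 1, sd = 0.18, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0) {
    stop("`sd` must be a single positive number.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  flows <- stats::rnorm(n, mean = mean, sd = sd)
  while (any(flows <= 0)) {
    bad <- flows <= 0
    flows[bad] <- stats::rnorm(sum(bad), mean = mean, sd = sd)
  }
  flows
}

#' Add square-root count-statistics noise to an expected count ratio
#'
#' Implements the stochastic term of the extended Lassen count model:
#' \deqn{C/C_r = E + NL \sqrt{E} \, z, \qquad E = \mathrm{forward}(F/F_r),}
#' where `z` is a standard-normal deviate and `nl` scales the noise.
#' The square-root dependence mimics Poisson counting statistics after
#' ratio normalisation; `nl = 0` returns the expectation exactly. The noisy
#' result may be negative or exceed \eqn{1+\alpha} -- that is deliberate
#' and is handled downstream by the guard policies, never clipped here.
#'
#' @param expected_ratio non-negative expected count ratio(s)
#'   (first term of the count model).
#' @param nl noise level, a non-negative scalar. Canonical grid:
#'   0 (none), 0.0125 (extremely low), 0.025 (low), 0.05 (medium; typical
#'   of routine clinical acquisitions).
#' @param z standard-normal draw(s), recycled against `expected_ratio`.
#'
#' @return Numeric vector of noisy count ratios.
#' @examples
#' add_count_noise(1, nl = 0.05, z = 1)       # 1.05
#' add_count_noise(0.75, nl = 0.05, z = -2)   # ~0.6634
#' @export
add_count_noise <- function(expected_ratio, nl, z) {
  if (any(expected_ratio < 0, na.rm = TRUE)) {
    stop("`expected_ratio` must be non-negative.", call. = FALSE)
  }
  if (!is.numeric(nl) || length(nl) != 1L || nl < 0) {
    stop("`nl` must be a single non-negative number.", call. = FALSE)
  }
  expected_ratio + nl * sqrt(expected_ratio) * z
}

#' Simulate one paired flow/count dataset
#'
#' Composes the full generative model: flows from
#' [generate_flow_ratios()], expected count ratios through
#' [lassen_forward()] at the true parameter `alpha_true`, then one
#' independent noise deviate per point via [add_count_noise()]. The
#' noiseless expectations are kept alongside the noisy counts so tests and
#' plots can separate model curvature from noise. With `nl = 0` the count
#' column equals the expected column exactly.
#'
#' @param n number of paired observations (default 1000).
#' @param flow_mean,flow_sd flow-distribution parameters (defaults 1, 0.18).
#' @param alpha_true generative Lassen parameter \eqn{\alpha_t}
#'   (default 0.5, the value integrating back-diffusion and flow-dependent
#'   first-pass extraction for HMPAO).
#' @param nl noise level (see [add_count_noise()]).
#' @param seed optional integer seed for full reproducibility.
#' @param flows optional numeric vector of flow ratios to use verbatim
#'   instead of drawing them (for controlled experiments); its length
#'   overrides `n`.
#'
#' @return A `data.frame` of class `"lassen_dataset"` with columns
#'   `flow_ratio`, `expected_count_ratio`, `count_ratio`, and attributes
#'   `alpha_true`, `nl`, `seed`, `flow_mean`, `flow_sd`.
#' @examples
#' d <- simulate_dataset(nl = 0.05, seed = 42)
#' head(d)
#' @export
simulate_dataset <- function(n = 1000, flow_mean = 1, flow_sd = 0.18,
                             alpha_true = 0.5, nl = 0, seed = NULL,
                             flows = NULL) {
  check_alpha(alpha_true)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(flows)) {
    flows <- generate_flow_ratios(n, mean = flow_mean, sd = flow_sd)
  } else {
    if (any(flows < 0)) stop("supplied `flows` must be non-negative.", call. = FALSE)
    n <- length(flows)
  }
  expected <- lassen_forward(flows, alpha_true)
  z <- stats::rnorm(n)
  counts <- add_count_noise(expected, nl, z)
  out <- data.frame(
    flow_ratio = flows,
    expected_count_ratio = expected,
    count_ratio = counts
  )
  attr(out, "alpha_true") <- alpha_true
  attr(out, "nl") <- nl
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "flow_mean") <- flow_mean
  attr(out, "flow_sd") <- flow_sd
  class(out) <- c("lassen_dataset", "data.frame")
  out
}

#' @export
print.lassen_dataset <- function(x, ...) {
  cat("Simulated HMPAO count-ratio dataset: n =", nrow(x),
      "| alpha_t =", format(attr(x, "alpha_true")),
      "| NL =", format(attr(x, "nl")),
      "| seed =", attr(x, "seed"), "\n")
  NextMethod()
}
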