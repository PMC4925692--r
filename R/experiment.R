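#' Configure a correction-parameter sweep
#'
#' Builds and validates the configuration for the full experiment: for each
#' noise level and each replicate, one dataset is simulated and then
#' corrected at every `alpha` in the grid, so all correction settings see
#' the identical noise realisation (an alpha sweep must not re-randomise).
#' Defaults reproduce the study conditions: n = 1000 flows ~ Normal(1,
#' 0.18), generative alpha 0.5, noise levels {0, 0.0125, 0.025, 0.05},
#' alpha grid 0.1 to 3.0 in steps of 0.05 (covering both the classical 1.5
#' and the proposed 0.5, and the 1.0-3.0 window over which the correlation
#' coefficient was historically reported as stable), 100 replicates.
#'
#' @param alpha_grid strictly increasing vector of positive correction
#'   parameters.
#' @param nl_list noise levels to simulate.
#' @param replicates number of independent datasets per noise level.
#' @param n,flow_mean,flow_sd flow generator settings
#'   (see [generate_flow_ratios()]).
#' @param alpha_true generative Lassen parameter.
#' @param guard singularity policy passed to [lassen_correct()].
#' @param seed master seed; per-(replicate, noise-level) child seeds are
#'   derived from it deterministically, so the whole sweep replays
#'   bit-identically.
#'
#' @return A validated list of class `"sweep_config"`.
#' @examples
#' cfg <- sweep_config(replicates = 2, nl_list = 0, alpha_grid = c(0.5, 1.5))
#' @export
sweep_config <- function(alpha_grid = seq(2L, 60L) / 20,
                         nl_list = c(0, 0.0125, 0.025, 0.05),
                         replicates = 100,
                         n = 1000, flow_mean = 1, flow_sd = 0.18,
                         alpha_true = 0.5,
                         guard = c("raw", "exclude", "clip"),
                         seed = 1L) {
  guard <- match.arg(guard)
  if (length(alpha_grid) < 1L || any(alpha_grid <= 0)) {
    stop("`alpha_grid` must contain positive values only.", call. = FALSE)
  }
  if (is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("`alpha_grid` must be strictly increasing.", call. = FALSE)
  }
  if (any(nl_list < 0)) {
    stop("`nl_list` must be non-negative.", call. = FALSE)
  }
  if (length(replicates) != 1L || replicates < 1 ||
      replicates != round(replicates)) {
    stop("`replicates` must be a single integer >= 1.", call. = FALSE)
  }
  if (!is.numeric(flow_sd) || flow_sd <= 0) {
    stop("`flow_sd` must be positive.", call. = FALSE)
  }
  if (n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2.", call. = FALSE)
  }
  check_alpha(alpha_true)
  if (length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  structure(
    list(alpha_grid = as.numeric(alpha_grid),
         nl_list = as.numeric(nl_list),
         replicates = as.integer(replicates),
         n = as.integer(n),
         flow_mean = flow_mean, flow_sd = flow_sd,
         alpha_true = alpha_true, guard = guard,
         seed = as.integer(seed)),
    class = "sweep_config"
  )
}

# deterministic child seed per (replicate, noise-level index); stays < 2^31
child_seed <- function(master, replicate, nl_index) {
  as.integer((abs(as.numeric(master)) + 100003 * replicate +
                10007 * nl_index) %% 2147483629)
}

#' Correct one dataset at one alpha and fit the flow relationship
#'
#' Applies Lassen's correction at a single `alpha` to a simulated dataset,
#' then regresses corrected accumulation \eqn{A/A_r} against true flow
#' \eqn{F/F_r}: Pearson correlation plus OLS slope and intercept. Under
#' `guard = "exclude"` the flagged pairs are removed pairwise before both
#' statistics; under `"raw"` and `"clip"` all pairs are used and the flag
#' count is purely diagnostic.
#'
#' @param dataset a `lassen_dataset` from [simulate_dataset()] (or any
#'   data frame with `flow_ratio` and `count_ratio` columns).
#' @param alpha correction parameter.
#' @param guard singularity policy (see [lassen_inverse()]).
#'
#' @return One-row `data.frame`: `alpha`, `nl`, `replicate` (`NA` outside a
#'   sweep), `pearson_r`, `slope`, `intercept`, `n_used`, `n_flagged`.
#' @examples
#' d <- simulate_dataset(nl = 0, seed = 1)
#' run_condition(d, alpha = 0.5)  # r = 1, slope = 1: exact recovery
#' @export
run_condition <- function(dataset, alpha,
                          guard = c("raw", "exclude", "clip")) {
  guard <- match.arg(guard)
  stopifnot(is.data.frame(dataset),
            all(c("flow_ratio", "count_ratio") %in% names(dataset)))
  corr <- lassen_correct(dataset$count_ratio, alpha, guard = guard)
  keep <- if (guard == "exclude") !corr$flagged else
    rep(TRUE, nrow(dataset))
  if (sum(keep) < 2L) {
    stop("fewer than 2 pairs survive the guard; no statistics possible.",
         call. = FALSE)
  }
  x <- dataset$flow_ratio[keep]
  y <- corr$corrected[keep]
  fit <- ols_fit(x, y)
  nl <- attr(dataset, "nl")
  data.frame(
    alpha = alpha,
    nl = if (is.null(nl)) NA_real_ else nl,
    replicate = NA_integer_,
    pearson_r = pearson_r(x, y),
    slope = unname(fit["slope"]),
    intercept = unname(fit["intercept"]),
    n_used = sum(keep),
    n_flagged = corr$n_flagged
  )
}

#' Run the full noise-level by alpha sweep
#'
#' The experiment driver: for every (replicate, noise level), simulate one
#' dataset from a child seed of `config$seed`, then evaluate
#' [run_condition()] at every grid alpha on that same dataset. A condition
#' that fails (e.g. every point excluded) is recorded as a row of `NA`
#' statistics, never dropped silently.
#'
#' @param config a [sweep_config()].
#' @return A `data.frame` of class `"lassen_sweep"` with one row per
#'   (replicate, nl, alpha), columns as in [run_condition()], and the
#'   config stored in attribute `"config"`.
#' @examples
#' res <- run_sweep(sweep_config(alpha_grid = c(0.5, 1.5), nl_list = 0,
#'                               replicates = 1, n = 100))
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  n_cond <- length(config$alpha_grid) * length(config$nl_list) *
    config$replicates
  rows <- vector("list", n_cond)
  i <- 0L
  for (k in seq_along(config$nl_list)) {
    for (rep_i in seq_len(config$replicates)) {
      d <- simulate_dataset(
        n = config$n, flow_mean = config$flow_mean,
        flow_sd = config$flow_sd, alpha_true = config$alpha_true,
        nl = config$nl_list[k],
        seed = child_seed(config$seed, rep_i, k)
      )
      for (a in config$alpha_grid) {
        i <- i + 1L
        row <- tryCatch(
          run_condition(d, a, guard = config$guard),
          error = function(e) data.frame(
            alpha = a, nl = config$nl_list[k], replicate = NA_integer_,
            pearson_r = NA_real_, slope = NA_real_, intercept = NA_real_,
            n_used = 0L, n_flagged = NA_integer_
          )
        )
        row$replicate <- rep_i
        rows[[i]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("lassen_sweep", "data.frame")
  out
}

#' Aggregate a sweep over replicates
#'
#' Means and SDs of the correlation coefficient and slope for each
#' (alpha, nl) cell, plus the mean flag count. With a single replicate the
#' means equal the raw values and the SDs are `NA`.
#'
#' @param results a results table from [run_sweep()].
#' @return `data.frame` with one row per (alpha, nl): `alpha`, `nl`,
#'   `mean_r`, `sd_r`, `mean_slope`, `sd_slope`, `mean_flagged`,
#'   `n_replicates`.
#' @seealso [peak_alpha()] for the argmax-alpha of the mean-r curve.
#' @export
summarize_sweep <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("alpha", "nl", "pearson_r", "slope") %in% names(results)))
  if (nrow(results) == 0L) stop("empty results table.", call. = FALSE)
  key <- list(alpha = results$alpha, nl = results$nl)
  agg <- function(v, f) stats::aggregate(v, by = key, FUN = f,
                                         na.rm = TRUE)$x
  out <- stats::aggregate(results$pearson_r, by = key,
                          FUN = mean, na.rm = TRUE)
  names(out)[3] <- "mean_r"
  sd_na <- function(v, ...) if (sum(!is.na(v)) < 2) NA_real_ else
    stats::sd(v, na.rm = TRUE)
  out$sd_r <- agg(results$pearson_r, sd_na)
  out$mean_slope <- agg(results$slope, mean)
  out$sd_slope <- agg(results$slope, sd_na)
  out$mean_flagged <- agg(results$n_flagged, mean)
  out$n_replicates <- agg(results$pearson_r,
                          function(v, ...) sum(!is.na(v)))
  out <- out[order(out$nl, out$alpha), ]
  rownames(out) <- NULL
  out
}

#' Alpha maximizing the mean correlation coefficient, per noise level
#'
#' Locates, for each noise level, the grid alpha with the largest mean
#' Pearson r. Ties are broken towards the smaller alpha (the stronger
#' correction), which matters when the r-versus-alpha curve is flat.
#'
#' @param summary output of [summarize_sweep()].
#' @return `data.frame` with columns `nl`, `peak_alpha`, `peak_mean_r`.
#' @export
peak_alpha <- function(summary) {
  stopifnot(all(c("alpha", "nl", "mean_r") %in% names(summary)))
  do.call(rbind, lapply(split(summary, summary$nl), function(s) {
    s <- s[order(s$alpha), ]
    best <- which.max(s$mean_r)  # first max = smallest alpha on ties
    data.frame(nl = s$nl[1], peak_alpha = s$alpha[best],
               peak_mean_r = s$mean_r[best], row.names = NULL)
  }))
}
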