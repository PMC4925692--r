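#' Scatter plot of a simulated dataset
#'
#' Flow ratio against (optionally corrected) count ratio with the identity
#' line, the qualitative counterpart of the study's raw and corrected
#' scatter panels. With `alpha` supplied the counts are corrected first.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param alpha optional correction parameter; `NULL` plots raw counts.
#' @param guard singularity policy when correcting.
#' @return A ggplot object.
#' @export
plot_dataset <- function(dataset, alpha = NULL,
                         guard = c("raw", "exclude", "clip")) {
  guard <- match.arg(guard)
  stopifnot(is.data.frame(dataset))
  y <- if (is.null(alpha)) dataset$count_ratio else
    lassen_correct(dataset$count_ratio, alpha, guard = guard)$corrected
  df <- data.frame(flow = dataset$flow_ratio, y = y)
  ylab <- if (is.null(alpha)) "count ratio C/Cr" else
    sprintf("corrected accumulation A/Ar (alpha = %s)", format(alpha))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flow, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, na.rm = TRUE) +
    ggplot2::labs(
      x = "flow ratio F/Fr", y = ylab,
      title = sprintf("NL = %s, alpha_t = %s",
                      format(attr(dataset, "nl")),
                      format(attr(dataset, "alpha_true")))
    ) +
    ggplot2::theme_minimal()
}

#' Correlation-coefficient and slope curves over alpha
#'
#' Mean Pearson r (or mean slope) against the correction alpha, one curve
#' per noise level -- the qualitative counterpart of the study's summary
#' curves. Ribbons show +/- 1 SD across replicates where available.
#'
#' @param summary a [summarize_sweep()] table.
#' @param metric `"r"` or `"slope"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(summary, metric = c("r", "slope")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(summary))
  df <- summary
  df$value <- if (metric == "r") df$mean_r else df$mean_slope
  df$sdv <- if (metric == "r") df$sd_r else df$sd_slope
  df$nl_f <- factor(format(df$nl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$value,
                                        colour = .data$nl_f,
                                        group = .data$nl_f))
  if (any(!is.na(df$sdv))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sdv,
                   ymax = .data$value + .data$sdv, fill = .data$nl_f),
      alpha = 0.15, colour = NA, na.rm = TRUE)
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "correction parameter alpha",
      y = if (metric == "r") "mean Pearson r" else "mean OLS slope",
      colour = "NL", fill = "NL"
    ) +
    ggplot2::theme_minimal()
}
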