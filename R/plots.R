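# Scatter diagnostics: per-SNP outcome effects against exposure effects with
# estimator fit lines, the standard visual check of a summary-data MR fit.

#' Scatter plot of a harmonized instrument set with estimator lines
#'
#' Plots beta_out against beta_exp (records oriented so beta_exp >= 0) with
#' per-SNP error bars and, for each supplied estimate, its fitted line
#' through the origin (or the Egger intercept where present).
#'
#' @param hset a [harmonized_set()].
#' @param estimates MR-estimate rows to draw lines for (e.g. the output of
#'   [mr_ivw()] / [mr_egger()] stacked).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_mr_scatter <- function(hset, estimates = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    analysis_error("plot_mr_scatter requires the ggplot2 package")
  }
  d <- as_mr_data(hset)
  flip <- sign(d$beta_exp); flip[flip == 0] <- 1
  d$beta_exp <- d$beta_exp * flip
  d$beta_out <- d$beta_out * flip
  p <- ggplot2::ggplot(d, ggplot2::aes(x = beta_exp, y = beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = beta_out - 1.96 * se_out,
                                        ymax = beta_out + 1.96 * se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = beta_exp - 1.96 * se_exp,
                                         xmax = beta_exp + 1.96 * se_exp),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "SNP effect on exposure (SD)",
                  y = "SNP effect on outcome (log-odds)",
                  title = sprintf("%s -> %s", hset$exposure_id, hset$outcome_id))
  if (!is.null(estimates)) {
    lines <- data.frame(
      method = estimates$method,
      slope = estimates$beta,
      intercept = ifelse(is.na(estimates$intercept), 0, estimates$intercept)
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = slope, intercept = intercept, colour = method)
    )
  }
  p + ggplot2::theme_minimal()
}
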