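# Pooling the per-source MR estimates across outcome sources: fixed-effect
# and DerSimonian-Laird random-effects meta-analysis, heterogeneity
# statistics, and the effect-scale conversions used for reporting.

#' Pool estimates across sources
#'
#' Fixed effect uses inverse-variance weights 1/se^2. Random effects is
#' DerSimonian-Laird: tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2/sum w))
#' with the fixed-effect weights, then weights 1/(se^2 + tau2). `"auto"`
#' selects random effects iff the fixed-effect Cochran Q p-value is below
#' 0.05, mirroring the convention of pooling with fixed effects unless
#' heterogeneity is detected. With only two sources I2 is reported but
#' unstable; the result carries a note saying so.
#'
#' @param estimates data.frame (or list coercible to one) with columns
#'   `beta` and `se`, one row per source (k >= 2).
#' @param model `"fixed"`, `"random_dl"` or `"auto"` (default `"auto"`).
#' @return An object of class `meta_result`: one-row data.frame with
#'   `pooled_beta`, `pooled_se`, `ci_low`, `ci_high`, `pval`, `model`, `Q`,
#'   `Q_df`, `Q_pval`, `I2`, `tau2`, `k_sources`, `note`.
#' @export
meta_combine <- function(estimates, model = c("auto", "fixed", "random_dl")) {
  model <- match.arg(model)
  est <- as.data.frame(estimates)
  b <- est$beta; se <- est$se
  k <- length(b)
  if (k < 2L) analysis_error("meta_combine: need at least 2 estimates")
  if (any(se <= 0)) analysis_error("meta_combine: nonpositive SE")
  w <- 1 / se^2
  pooled_f <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled_f)^2)
  df <- k - 1L
  Q_pval <- stats::pchisq(Q, df, lower.tail = FALSE)
  use_random <- switch(model, fixed = FALSE, random_dl = TRUE, auto = Q_pval < 0.05)
  if (use_random) {
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (se^2 + tau2)
    pooled <- sum(wr * b) / sum(wr)
    pooled_se <- 1 / sqrt(sum(wr))
    model_used <- "random_dl"
  } else {
    tau2 <- 0
    pooled <- pooled_f
    pooled_se <- 1 / sqrt(sum(w))
    model_used <- "fixed"
  }
  res <- data.frame(
    pooled_beta = pooled, pooled_se = pooled_se,
    ci_low = pooled - stats::qnorm(0.975) * pooled_se,
    ci_high = pooled + stats::qnorm(0.975) * pooled_se,
    pval = z_pval(pooled, pooled_se),
    model = model_used,
    Q = Q, Q_df = df, Q_pval = Q_pval, I2 = het_i2(Q, df),
    tau2 = tau2, k_sources = k,
    note = if (k == 2L) "I2 unstable at k=2" else "",
    stringsAsFactors = FALSE
  )
  class(res) <- c("meta_result", "data.frame")
  res
}

#' Odds ratio with 95% CI from a log-odds estimate
#'
#' @param beta log-odds effect.
#' @param se its standard error (> 0).
#' @return `c(or=, ci_low=, ci_high=)` = exp(beta), exp(beta -+ 1.96 se).
#' @export
or_with_ci <- function(beta, se) {
  if (se <= 0) analysis_error("or_with_ci: se must be positive")
  z <- stats::qnorm(0.975)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Percent risk increase implied by an odds ratio
#'
#' (OR - 1) x 100, rounded to one decimal — display form for statements like
#' "OR 1.118 = 11.8% higher risk".
#'
#' @param or_value odds ratio (> 0).
#' @param digits display rounding (default 1 decimal).
#' @return Percentage (single number).
#' @export
percent_increase_from_or <- function(or_value, digits = 1) {
  if (any(or_value <= 0)) analysis_error("percent_increase_from_or: OR must be positive")
  round((or_value - 1) * 100, digits)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is_count(n_tests)) config_error("n_tests must be a positive integer")
  alpha / n_tests
}
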