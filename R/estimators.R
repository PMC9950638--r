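# Two-sample MR estimators and their diagnostics: Wald ratio, IVW (fixed and
# multiplicative random effects), MR-Egger, weighted median, Cochran Q / I2.
# MR-PRESSO lives in presso.R.
#
# All estimators accept either a harmonized_set or a plain data.frame with
# columns beta_exp, se_exp, beta_out, se_out (the fast path used by the
# simulation studies). Two-sided p-values come from the normal distribution,
# the summary-data MR convention; MR-Egger can use t with k-2 df via a flag.

as_mr_data <- function(x) {
  if (inherits(x, "harmonized_set")) x$records else x
}

#' Construct an MR estimate record
#'
#' One method's causal estimate with its 95% normal CI and heterogeneity
#' diagnostics, as a one-row data.frame so results stack into tables.
#' @noRd
mr_estimate <- function(method, beta, se, n_snp,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_pval = NA_real_,
                        Q = NA_real_, Q_df = NA_integer_, Q_pval = NA_real_,
                        I2 = NA_real_, pval = NULL) {
  data.frame(
    method = method, beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pval = pval %||% z_pval(beta, se),
    n_snp = n_snp,
    intercept = intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval,
    Q = Q, Q_df = Q_df, Q_pval = Q_pval, I2 = I2,
    stringsAsFactors = FALSE
  )
}

het_i2 <- function(Q, df) if (is.na(Q) || Q <= 0) 0 else max(0, (Q - df) / Q)

#' Wald ratio estimate for a single instrument
#'
#' beta = beta_out / beta_exp. The default SE is the first-order delta
#' approximation se_out / |beta_exp| (the common two-sample practice, which
#' ignores exposure-side noise); `second_order = TRUE` adds the
#' beta_out^2 se_exp^2 / beta_exp^4 term.
#'
#' @param rec one harmonized record (one-row data.frame or list with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param second_order use the second-order delta SE (default FALSE).
#' @return A one-row MR-estimate data.frame (`method = "wald"`).
#' @export
wald_ratio <- function(rec, second_order = FALSE) {
  if (rec$beta_exp == 0) analysis_error("null instrument: beta_exp = 0")
  beta <- rec$beta_out / rec$beta_exp
  se <- if (second_order) {
    sqrt(rec$se_out^2 / rec$beta_exp^2 +
           rec$beta_out^2 * rec$se_exp^2 / rec$beta_exp^4)
  } else {
    rec$se_out / abs(rec$beta_exp)
  }
  mr_estimate("wald", beta, se, n_snp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Combines per-SNP Wald ratios r_j = beta_out_j/beta_exp_j with weights
#' w_j = beta_exp_j^2/se_out_j^2 — equivalently the zero-intercept weighted
#' regression of beta_out on beta_exp with weights 1/se_out^2. Fixed-effect
#' SE is 1/sqrt(sum w); the multiplicative random-effects ("mre") SE scales
#' it by max(1, sqrt(Q/(k-1))) — heterogeneity inflates, never deflates.
#' `model = "auto"` uses mre iff the Cochran Q p-value is below 0.05. A
#' single SNP degenerates to its Wald ratio.
#'
#' @param hset a [harmonized_set()] or data.frame of harmonized records.
#' @param model `"auto"` (default), `"fixed"` or `"mre"`.
#' @return A one-row MR-estimate data.frame (`method = "ivw_fe"` or
#'   `"ivw_mre"`), with Q, Q_df, Q_pval and I2 filled in.
#' @export
mr_ivw <- function(hset, model = c("auto", "fixed", "mre")) {
  model <- match.arg(model)
  d <- as_mr_data(hset)
  k <- nrow(d)
  if (k == 0L) analysis_error("mr_ivw: no instruments")
  if (k == 1L) {
    est <- wald_ratio(d[1, ])
    est$method <- "ivw_fe"
    est$Q <- 0; est$Q_df <- 0L; est$Q_pval <- NA_real_; est$I2 <- 0
    return(est)
  }
  r <- d$beta_out / d$beta_exp
  w <- d$beta_exp^2 / d$se_out^2
  beta <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (r - beta)^2)
  df <- k - 1L
  Q_pval <- stats::pchisq(Q, df, lower.tail = FALSE)
  use_mre <- switch(model, fixed = FALSE, mre = TRUE, auto = Q_pval < 0.05)
  scale <- if (use_mre) max(1, sqrt(Q / df)) else 1
  mr_estimate(if (use_mre) "ivw_mre" else "ivw_fe",
              beta, scale * se_fixed, n_snp = k,
              Q = Q, Q_df = df, Q_pval = Q_pval, I2 = het_i2(Q, df))
}

#' MR-Egger regression
#'
#' Weighted linear regression of beta_out on beta_exp with an intercept,
#' weights 1/se_out^2, after orienting every record so beta_exp >= 0 (Egger
#' is not invariant to instrument coding without this). The slope is the
#' causal estimate; the intercept estimates average directional pleiotropy,
#' and its test is the pleiotropy diagnostic. SEs carry the multiplicative
#' scaling max(1, sqrt(RSS_w/(k-2))).
#'
#' @param hset a [harmonized_set()] or data.frame of harmonized records
#'   (k >= 3).
#' @param t_dist use t with k-2 df for the p-values instead of the normal
#'   (default FALSE).
#' @return A one-row MR-estimate data.frame (`method = "egger"`) with
#'   intercept fields and residual heterogeneity (Q with k-2 df).
#' @export
mr_egger <- function(hset, t_dist = FALSE) {
  d <- as_mr_data(hset)
  k <- nrow(d)
  if (k < 3L) analysis_error("insufficient instruments for Egger (need >= 3)")
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  bx <- d$beta_exp * flip
  by <- d$beta_out * flip
  w <- 1 / d$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sigma <- summary(fit)$sigma        # sqrt(weighted RSS / (k-2))
  X <- cbind(1, bx)
  xtwx_inv <- solve(crossprod(X * sqrt(w)))  # unscaled (sigma = 1) covariance
  se_un <- sqrt(diag(xtwx_inv))
  scale <- max(1, sigma)             # floor the multiplicative dispersion at 1
  slope <- unname(stats::coef(fit)["bx"]); slope_se <- se_un[2] * scale
  int <- unname(stats::coef(fit)["(Intercept)"]); int_se <- se_un[1] * scale
  pfun <- if (t_dist) {
    function(b, s) 2 * stats::pt(-abs(b / s), df = k - 2L)
  } else {
    z_pval
  }
  Q <- sigma^2 * (k - 2L)            # weighted residual sum of squares
  mr_estimate("egger", slope, slope_se, n_snp = k,
              intercept = int, intercept_se = int_se,
              intercept_pval = pfun(int, int_se),
              Q = Q, Q_df = k - 2L,
              Q_pval = stats::pchisq(Q, k - 2L, lower.tail = FALSE),
              I2 = het_i2(Q, k - 2L),
              pval = pfun(slope, slope_se))
}

#' Weighted median of the per-SNP Wald ratios (point estimate only)
#' @noRd
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Sorts the Wald ratios and takes the inverse-variance-weighted median:
#' with normalized weights w_j (w_j = beta_exp_j^2/se_out_j^2), cumulative
#' midpoints p_j = cum_j - w_j/2, the estimate interpolates the ratios at
#' p = 0.5. Consistent when valid instruments carry a majority of the
#' weight, i.e. robust to up to half the SNPs being pleiotropic. The SE is a
#' seeded parametric bootstrap: beta_exp_j and beta_out_j are resampled from
#' normals at their SEs, the weighted median recomputed, and the SD taken.
#'
#' @param hset a [harmonized_set()] or data.frame of harmonized records
#'   (k >= 3).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required: the SE is
#'   stochastic and must be reproducible).
#' @return A one-row MR-estimate data.frame (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed) {
  if (missing(seed)) config_error("mr_weighted_median: a seed is required")
  d <- as_mr_data(hset)
  k <- nrow(d)
  if (k < 3L) analysis_error("insufficient instruments for weighted median (need >= 3)")
  ratios <- d$beta_out / d$beta_exp
  weights <- d$beta_exp^2 / d$se_out^2
  est <- weighted_median_point(ratios, weights)
  boot <- local({
    set.seed(seed)
    bx <- matrix(stats::rnorm(k * n_boot, d$beta_exp, d$se_exp), nrow = k)
    by <- matrix(stats::rnorm(k * n_boot, d$beta_out, d$se_out), nrow = k)
    vapply(seq_len(n_boot), function(s) {
      weighted_median_point(by[, s] / bx[, s], bx[, s]^2 / d$se_out^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boot), n_snp = k)
}

#' Cochran Q heterogeneity test and I-squared
#'
#' Q = sum w_j (b_j - b_pooled)^2 with w_j = 1/se_j^2 and b_pooled the
#' inverse-variance-weighted mean, referred to chi-square with k-1 df;
#' I2 = max(0, (Q - df)/Q). For a harmonized set the per-SNP estimates are
#' the Wald ratios with first-order SEs.
#'
#' @param x a [harmonized_set()], harmonized records, or a data.frame with
#'   columns `beta` and `se` (k >= 2).
#' @return `list(Q=, df=, pval=, I2=)`.
#' @export
cochran_q <- function(x) {
  d <- as_mr_data(x)
  if (all(c("beta_exp", "beta_out") %in% names(d))) {
    b <- d$beta_out / d$beta_exp
    se <- d$se_out / abs(d$beta_exp)
  } else {
    b <- d$beta
    se <- d$se
  }
  k <- length(b)
  if (k < 2L) analysis_error("cochran_q: need at least 2 estimates")
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled)^2)
  df <- k - 1L
  list(Q = Q, df = df,
       pval = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = het_i2(Q, df))
}
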