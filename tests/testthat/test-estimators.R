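test_that("Wald ratio follows the first-order delta definition", {
  r <- hrecs(bx = 0.1, bxse = 0.01, by = 0.02, byse = 0.01)
  w <- wald_ratio(r[1, ])
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(w$ci_low, 0.2 - qnorm(0.975) * 0.1)

  expect_equal(wald_ratio(hrecs(0.1, 0.01, 0, 0.01)[1, ])$beta, 0)
  expect_equal(wald_ratio(hrecs(-0.1, 0.01, 0.02, 0.01)[1, ])$beta, -0.2)
  expect_gt(wald_ratio(hrecs(-0.1, 0.01, 0.02, 0.01)[1, ])$se, 0)

  # second-order SE adds the exposure-noise term
  w2 <- wald_ratio(hrecs(0.1, 0.05, 0.02, 0.01)[1, ], second_order = TRUE)
  expect_equal(w2$se, sqrt(0.01^2 / 0.1^2 + 0.02^2 * 0.05^2 / 0.1^4))

  null_inst <- hrecs(0, 0.01, 0.02, 0.01)
  expect_error(wald_ratio(null_inst[1, ]), "null instrument",
               class = "bidirmr_analysis_error")
})

test_that("IVW matches the worked 2-SNP example and degenerates sensibly", {
  d <- hrecs(bx = c(0.1, 0.2), bxse = 0.01, by = c(0.02, 0.02), byse = 0.01)
  e <- mr_ivw(d, model = "fixed")
  expect_equal(e$beta, 0.12)
  expect_equal(e$se, 1 / sqrt(500))

  # identical ratios: no heterogeneity, fixed == mre
  same <- hrecs(bx = c(0.1, 0.2, 0.3), bxse = 0.01,
                by = c(0.01, 0.02, 0.03), byse = 0.01)
  ef <- mr_ivw(same, model = "fixed")
  em <- mr_ivw(same, model = "mre")
  expect_equal(ef$beta, 0.1)
  expect_equal(ef$Q, 0)
  expect_equal(ef$I2, 0)
  expect_equal(em$se, ef$se)

  # single SNP: equals the Wald ratio
  one <- hrecs(0.1, 0.01, 0.02, 0.01)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one[1, ])$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(one[1, ])$se)

  expect_error(mr_ivw(hrecs(0.1, 0.01, 0.02, 0.01)[0, ]),
               class = "bidirmr_analysis_error")
})

test_that("IVW equals the zero-intercept WLS closed form on random instances", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    d <- hrecs(bx = rnorm(k, 0.2, 0.1), bxse = runif(k, 0.005, 0.05),
               by = rnorm(k, 0.02, 0.02), byse = runif(k, 0.005, 0.05))
    e <- mr_ivw(d, model = "fixed")
    oracle <- wls_oracle(d$beta_exp, d$beta_out, 1 / d$se_out^2, intercept = FALSE)
    expect_equal(e$beta, unname(oracle), tolerance = 1e-10)
  }
})

test_that("IVW is invariant to joint sign flips and mre never shrinks the SE", {
  set.seed(12)
  for (i in 1:30) {
    k <- sample(3:10, 1)
    d <- hrecs(bx = rnorm(k, 0.2, 0.1), bxse = 0.02,
               by = rnorm(k, 0.02, 0.05), byse = runif(k, 0.01, 0.05))
    flip <- sample(c(-1, 1), k, replace = TRUE)
    d2 <- d
    d2$beta_exp <- d$beta_exp * flip
    d2$beta_out <- d$beta_out * flip
    expect_equal(mr_ivw(d2, "fixed")$beta, mr_ivw(d, "fixed")$beta)
    expect_gte(mr_ivw(d, "mre")$se, mr_ivw(d, "fixed")$se)
  }
})

test_that("auto IVW switches to multiplicative random effects under heterogeneity", {
  calm <- hrecs(bx = c(0.1, 0.2, 0.3), bxse = 0.01,
                by = c(0.01, 0.02, 0.03), byse = 0.01)
  expect_equal(mr_ivw(calm, "auto")$method, "ivw_fe")
  wild <- hrecs(bx = c(0.1, 0.2, 0.3), bxse = 0.01,
                by = c(0.05, -0.06, 0.09), byse = 0.005)
  e <- mr_ivw(wild, "auto")
  expect_equal(e$method, "ivw_mre")
  expect_lt(e$Q_pval, 0.05)
  expect_equal(e$se, sqrt(e$Q / e$Q_df) / sqrt(sum(wild$beta_exp^2 / wild$se_out^2)))
})

test_that("MR-Egger recovers exact linear pleiotropy and matches the WLS oracle", {
  # data generated exactly as by = 0.05 + 0.3 bx, equal weights
  bx <- c(0.1, 0.2, 0.3, 0.4)
  d <- hrecs(bx = bx, bxse = 0.01, by = 0.05 + 0.3 * bx, byse = 0.01)
  e <- mr_egger(d)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$Q, 0, tolerance = 1e-12)

  # no pleiotropy: intercept 0
  d0 <- hrecs(bx = bx, bxse = 0.01, by = 0.25 * bx, byse = 0.01)
  expect_equal(mr_egger(d0)$intercept, 0, tolerance = 1e-12)

  # 4-point unequal-weight instance vs lm oracle
  d4 <- hrecs(bx = c(0.12, 0.2, 0.31, 0.4), bxse = 0.01,
              by = c(0.02, 0.07, 0.06, 0.11), byse = c(0.01, 0.02, 0.015, 0.03))
  e4 <- mr_egger(d4)
  oracle <- wls_oracle(d4$beta_exp, d4$beta_out, 1 / d4$se_out^2)
  expect_equal(e4$intercept, unname(oracle[1]), tolerance = 1e-10)
  expect_equal(e4$beta, unname(oracle[2]), tolerance = 1e-10)

  # orientation invariance: joint sign flips leave the fit unchanged
  flip <- c(-1, 1, -1, 1)
  d4f <- d4
  d4f$beta_exp <- d4$beta_exp * flip
  d4f$beta_out <- d4$beta_out * flip
  expect_equal(mr_egger(d4f)$beta, e4$beta)
  expect_equal(mr_egger(d4f)$intercept, e4$intercept)

  expect_error(mr_egger(d4[1:2, ]), "insufficient",
               class = "bidirmr_analysis_error")
})

test_that("Egger constrained through the origin reproduces IVW", {
  set.seed(13)
  d <- hrecs(bx = rnorm(8, 0.25, 0.05), bxse = 0.02,
             by = rnorm(8, 0.03, 0.02), byse = runif(8, 0.01, 0.03))
  constrained <- wls_oracle(d$beta_exp, d$beta_out, 1 / d$se_out^2, intercept = FALSE)
  expect_equal(mr_ivw(d, "fixed")$beta, unname(constrained), tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted ratio CDF", {
  # equal weights, odd k: the plain median
  d <- hrecs(bx = c(1, 1, 1), bxse = 0.01, by = c(0.1, 0.2, 0.9), byse = 1)
  wm <- mr_weighted_median(d, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2)

  # hand-executable interpolation: ratios (1,2,3), weights (4,1,1)
  # midpoints (1/3, 3/4, 11/12); interpolate at 1/2 -> 1.4
  d2 <- hrecs(bx = c(2, 1, 1), bxse = 0.01, by = c(2, 2, 3), byse = 1)
  wm2 <- mr_weighted_median(d2, n_boot = 100, seed = 1)
  expect_equal(wm2$beta, 1.4)

  # all ratios identical: estimate exactly that constant, bootstrap SE small
  d3 <- hrecs(bx = c(0.1, 0.2, 0.4), bxse = 1e-6, by = c(0.05, 0.1, 0.2), byse = 1e-6)
  wm3 <- mr_weighted_median(d3, n_boot = 200, seed = 2)
  expect_equal(wm3$beta, 0.5)
  expect_lt(wm3$se, 1e-3)

  # equal weights, random odd k: equals sample median (oracle)
  set.seed(14)
  for (i in 1:20) {
    k <- sample(c(3, 5, 7, 9), 1)
    ratios <- rnorm(k)
    di <- hrecs(bx = rep(1, k), bxse = 0.01, by = ratios, byse = 1)
    wmi <- mr_weighted_median(di, n_boot = 10, seed = i)
    expect_equal(wmi$beta, median(ratios))
    expect_equal(wmi$beta, wm_oracle(ratios, rep(1, k)))
  }

  # seeded: same seed, same SE; different seed, (almost surely) different
  a <- mr_weighted_median(d, n_boot = 50, seed = 99)
  b <- mr_weighted_median(d, n_boot = 50, seed = 99)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(d[1:2, ], n_boot = 10, seed = 1),
               class = "bidirmr_analysis_error")
  expect_error(mr_weighted_median(d, n_boot = 10), class = "bidirmr_config_error")
})

test_that("MR-PRESSO flags a planted outlier and respects its preconditions", {
  set.seed(21)
  k <- 12
  bx <- rnorm(k, 0.2, 0.05)
  by <- 0.1 * bx + rnorm(k, 0, 0.01)
  by[5] <- by[5] + 10 * 0.01           # residual inflated by 10 outcome-SEs
  d <- hrecs(bx = bx, bxse = 0.01, by = by, byse = 0.01)
  p <- mr_presso(d, n_sim = 1000, seed = 5)
  expect_lt(p$global_pval, 0.01)
  expect_true("rs005" %in% p$outlier_snps$snp_id)
  expect_equal(p$corrected$method, "presso_outlier_corrected")
  # removing the outlier moves the estimate back toward the truth
  expect_lt(abs(p$corrected$beta - 0.1), abs(p$raw$beta - 0.1))
  expect_false(is.na(p$distortion_pval))

  expect_error(mr_presso(d[1:3, ], n_sim = 100, seed = 1), "insufficient",
               class = "bidirmr_analysis_error")
  expect_error(mr_presso(d, n_sim = 100), class = "bidirmr_config_error")

  # determinism under the seed
  p2 <- mr_presso(d, n_sim = 200, seed = 7)
  p3 <- mr_presso(d, n_sim = 200, seed = 7)
  expect_identical(p2$global_pval, p3$global_pval)
})

test_that("PRESSO add-one p-values never reach zero and outliers need a global signal", {
  set.seed(22)
  bx <- rnorm(8, 0.2, 0.05)
  d <- hrecs(bx = bx, bxse = 0.01, by = 0.1 * bx + rnorm(8, 0, 0.01), byse = 0.01)
  p <- mr_presso(d, n_sim = 300, seed = 3)
  expect_gte(p$global_pval, 1 / 301)
  if (p$global_pval >= 0.05) expect_equal(nrow(p$outlier_snps), 0L)
})

test_that("Cochran Q matches hand arithmetic and the I2 identity", {
  same <- data.frame(beta = c(0.1, 0.1, 0.1), se = 1)
  q0 <- cochran_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$I2, 0)
  expect_equal(q0$pval, 1)

  two <- data.frame(beta = c(0, 2), se = 1)
  q2 <- cochran_q(two)
  expect_equal(q2$Q, 2)        # pooled 1; 1^2 + 1^2
  expect_equal(q2$df, 1L)
  expect_equal(q2$I2, (2 - 1) / 2)
  expect_equal(q2$pval, pchisq(2, 1, lower.tail = FALSE))

  expect_error(cochran_q(data.frame(beta = 1, se = 1)),
               class = "bidirmr_analysis_error")

  # heterogeneity recovery: I2 approaches its generating value
  set.seed(23)
  i2_hat <- replicate(200, {
    k <- 30
    tau <- 0.2; se <- 0.1
    b <- rnorm(k, 0, sqrt(tau^2 + se^2))
    cochran_q(data.frame(beta = b, se = se))$I2
  })
  expect_equal(mean(i2_hat), 0.2^2 / (0.2^2 + 0.1^2), tolerance = 0.05)
})
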