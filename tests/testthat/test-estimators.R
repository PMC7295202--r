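# causal-effect estimators against hand values and independent oracles

test_that("the Wald ratio divides and propagates error by the delta method", {
  e <- wald_ratio(beta_x = 0.2, se_x = 0.01, beta_y = 0.4, se_y = 0.1)
  expect_equal(e$beta, 2.0)
  expect_equal(e$se, 0.5)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.1)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.4, 0.1), "beta_x = 0")
  # second-order SE adds the exposure-side term
  e2 <- wald_ratio(0.2, 0.01, 0.4, 0.1, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.1^2 / 0.04 + 0.16 * 1e-4 / 0.2^4))
  expect_gt(e2$se, e$se)
})

test_that("IVW matches its closed form, the single-SNP Wald ratio, and lm through the origin", {
  # hand case: equal beta_x and se_y, ratios 1 and 3 average to 2
  h <- harmonized_set(beta_x = c(0.1, 0.1), se_x = c(0.01, 0.01),
                      beta_y = c(0.1, 0.3), se_y = c(0.1, 0.1))
  expect_equal(mr_ivw(h, model = "fixed")$beta, 2.0)
  # single SNP: identical to the Wald ratio
  h1 <- harmonized_set(0.2, 0.01, 0.4, 0.1)
  expect_equal(mr_ivw(h1, model = "fixed")$beta, wald_ratio(0.2, 0.01, 0.4, 0.1)$beta)
  expect_equal(mr_ivw(h1, model = "fixed")$se, wald_ratio(0.2, 0.01, 0.4, 0.1)$se)
  expect_error(mr_ivw(h1, model = "random"), "L >= 2")
  # oracle equivalence on random instances
  for (s in 1:20) {
    hh <- mk_h(L = sample(3:30, 1), beta = runif(1, -1, 1), seed = s)
    expect_equal(mr_ivw(hh, model = "fixed")$beta, ivw_oracle(hh),
                 tolerance = 1e-12)
  }
  # degenerate input
  h0 <- harmonized_set(c(0, 0), c(1, 1), c(0.1, 0.2), c(0.1, 0.1),
                       orient_beta_x_positive = FALSE)
  expect_error(mr_ivw(h0), "all beta_x are zero")
})

test_that("random-effects IVW widens but never narrows the fixed-effect interval", {
  for (s in 1:10) {
    hh <- mk_h(L = 20, beta = 0.3, seed = s)
    expect_gte(mr_ivw(hh, "random")$se, mr_ivw(hh, "fixed")$se)
    expect_equal(mr_ivw(hh, "random")$beta, mr_ivw(hh, "fixed")$beta)
  }
})

test_that("IVW recovers a simulated causal effect from 50 valid instruments", {
  h <- mk_h(L = 50, beta = 0.3, seed = 101)
  e <- mr_ivw(h, "random")
  expect_lt(abs(e$beta - 0.3), 3 * e$se)
})

test_that("Egger regression fits an exact line exactly and matches weighted lm", {
  h <- harmonized_set(beta_x = c(0.1, 0.2, 0.3), se_x = rep(0.01, 3),
                      beta_y = c(0.3, 0.5, 0.7), se_y = rep(0.1, 3))
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 2)
  expect_equal(e$intercept$beta, 0.1)
  # residuals are exactly zero, so the estimated-dispersion SE degenerates;
  # the floored variant keeps it positive
  expect_equal(e$slope$se, 0)
  expect_gt(mr_egger(h, floor_dispersion = TRUE)$slope$se, 0)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
  for (s in 1:10) {
    hh <- mk_h(L = 15, beta = 0.2, seed = s)
    o <- egger_oracle(hh)
    f <- mr_egger(hh)
    expect_equal(f$intercept$beta, unname(o[1]), tolerance = 1e-12)
    expect_equal(f$slope$beta, unname(o[2]), tolerance = 1e-12)
    ou <- egger_oracle(hh, weighted = FALSE)
    fu <- mr_egger(hh, weighted = FALSE)
    expect_equal(fu$slope$beta, unname(ou[2]), tolerance = 1e-12)
  }
})

test_that("the Egger intercept recovers directional pleiotropy under InSIDE", {
  set.seed(7)
  alpha <- rnorm(40, mean = 0.02, sd = 0.005)  # independent of strength
  h <- mk_h(L = 40, beta = 0.3, seed = 7, alpha = alpha)
  e <- mr_egger(h)
  expect_lt(abs(e$intercept$beta - 0.02), 3 * e$intercept$se)
  expect_lt(abs(e$slope$beta - 0.3), 3 * e$slope$se)
})

test_that("SIMEX at a zero-only grid reproduces the unweighted Egger fit bit-exactly", {
  h <- mk_h(L = 12, beta = 0.25, seed = 3)
  s <- simex_egger(h, lambdas = 0, b_reps = 50, seed = 1)
  u <- mr_egger(h, weighted = FALSE)
  expect_identical(s$slope$beta, u$slope$beta)
  expect_identical(s$slope$se, u$slope$se)
  expect_identical(s$intercept$beta, u$intercept$beta)
  expect_identical(s$intercept$se, u$intercept$se)
})

test_that("SIMEX is deterministic under a seed and requires a zero lambda", {
  h <- mk_h(L = 12, beta = 0.25, seed = 4, se_x = 0.02)
  a <- simex_egger(h, b_reps = 30, seed = 99)
  b <- simex_egger(h, b_reps = 30, seed = 99)
  expect_identical(a$slope$beta, b$slope$beta)
  expect_identical(a$intercept$se, b$intercept$se)
  expect_error(simex_egger(h, lambdas = c(0.5, 1), b_reps = 10), "include 0")
  expect_error(simex_egger(h[1:2, ]), "at least 3")
})

test_that("the weighted median matches enumeration and hand cases", {
  # equal weights, ratios (1, 2, 10): the middle value
  h <- harmonized_set(beta_x = c(1, 1, 1), se_x = rep(0.01, 3),
                      beta_y = c(1, 2, 10), se_y = rep(0.5, 3))
  expect_equal(mr_weighted_median(h, b_boot = 0)$beta, 2)
  # identical ratios: that value, with a positive bootstrap SE
  hi <- harmonized_set(beta_x = c(0.1, 0.2, 0.4), se_x = rep(0.001, 3),
                       beta_y = c(0.05, 0.10, 0.20), se_y = rep(0.01, 3))
  e <- mr_weighted_median(hi, b_boot = 200, seed = 2)
  expect_equal(e$beta, 0.5)
  expect_gt(e$se, 0)
  expect_error(mr_weighted_median(h[1, ]), "at least 2")
  # property: equals the brute-force weighted-quantile oracle
  set.seed(2024)
  for (i in 1:200) {
    L <- 5L
    bx <- runif(L, 0.05, 0.5)
    by <- rnorm(L, 0.3 * bx, 0.05)
    sy <- runif(L, 0.02, 0.2)
    hh <- harmonized_set(bx, rep(0.01, L), by, sy)
    r <- hh$beta_y / hh$beta_x
    w <- hh$beta_x^2 / hh$se_y^2
    expect_equal(mr_weighted_median(hh, b_boot = 0)$beta, wm_oracle(r, w),
                 tolerance = 1e-12)
  }
})

test_that("the weighted median is deterministic under a seed", {
  h <- mk_h(L = 15, beta = 0.3, seed = 8)
  a <- mr_weighted_median(h, b_boot = 100, seed = 5)
  b <- mr_weighted_median(h, b_boot = 100, seed = 5)
  expect_identical(a$se, b$se)
})

test_that("the weighted median resists a minority of invalid instruments", {
  # 14 valid + 6 strongly pleiotropic instruments, invalid weight < 50%
  alpha <- c(rep(0, 14), rep(0.05, 6))
  h <- mk_h(L = 20, beta = 0.3, seed = 31, alpha = alpha)
  e <- mr_weighted_median(h, b_boot = 500, seed = 6)
  expect_lt(abs(e$beta - 0.3), 3 * e$se)
})

test_that("the mode-based estimate finds the largest ratio cluster", {
  # point mass: all ratios identical
  hi <- harmonized_set(beta_x = c(0.1, 0.2, 0.4), se_x = rep(0.001, 3),
                       beta_y = c(0.05, 0.10, 0.20), se_y = rep(0.01, 3))
  expect_equal(mr_mbe(hi, b_boot = 0)$beta, 0.5)
  # 7 ratios near 0.5, 3 near 2.0, equal weights
  set.seed(12)
  ratios <- c(0.5 + runif(7, -0.02, 0.02), 2 + runif(3, -0.02, 0.02))
  h <- harmonized_set(beta_x = rep(1, 10), se_x = rep(0.01, 10),
                      beta_y = ratios, se_y = rep(0.1, 10))
  e <- mr_mbe(h, phi = 0.5, b_boot = 0)
  expect_lt(abs(e$beta - 0.5), 0.05)
  # and the package grid agrees with a much finer independent grid
  r <- h$beta_y / h$beta_x
  s <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  w <- (h$beta_x / h$se_y)^2
  expect_lt(abs(e$beta - mbe_oracle(r, w, 0.5 * s)), 0.003)
  expect_error(mr_mbe(h[1:2, ]), "at least 3")
})

test_that("the mode-based estimate is deterministic under a seed", {
  h <- mk_h(L = 15, beta = 0.3, seed = 9)
  a <- mr_mbe(h, b_boot = 100, seed = 7)
  b <- mr_mbe(h, b_boot = 100, seed = 7)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
})

test_that("the allele-score meta-analysis pools outcome effects by inverse variance", {
  h <- harmonized_set(beta_x = c(0.1, 0.1), se_x = c(0.01, 0.01),
                      beta_y = c(0.1, 0.3), se_y = c(0.1, 0.1))
  expect_equal(allele_score_meta(h)$beta, 0.2)
  h2 <- harmonized_set(beta_x = c(0.1, 0.1), se_x = c(0.01, 0.01),
                       beta_y = c(0, 0.2), se_y = c(0.1, 0.2))
  e2 <- allele_score_meta(h2)
  expect_equal(e2$beta, 0.04)
  expect_equal(e2$se, 1 / sqrt(125))
  # single record: passed through unchanged
  h1 <- harmonized_set(0.1, 0.01, 0.07, 0.02)
  e1 <- allele_score_meta(h1)
  expect_equal(e1$beta, 0.07)
  expect_equal(e1$se, 0.02)
})

test_that("the allele-score meta-analysis agrees with metafor's fixed-effect model", {
  skip_if_not_installed("metafor")
  h <- mk_h(L = 12, beta = 0.3, seed = 13)
  fit <- metafor::rma(yi = h$beta_y, sei = h$se_y, method = "FE")
  e <- allele_score_meta(h)
  expect_equal(e$beta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(e$se, as.numeric(fit$se), tolerance = 1e-10)
})

test_that("odds-ratio transformation exponentiates monotonically and only once", {
  e0 <- mr_estimate("ivw_random", 0, 0.1, 5L)
  expect_equal(to_odds_ratio(e0)$beta, 1.0)
  e <- mr_estimate("ivw_random", log(1.06), 0.05, 5L,
                   ci_lower = -0.1, ci_upper = 0.2)
  or <- to_odds_ratio(e)
  expect_equal(or$beta, 1.06)
  expect_equal(or$ci_lower, exp(-0.1))
  expect_equal(or$ci_upper, exp(0.2))
  expect_lt(or$ci_lower, or$ci_upper)
  expect_equal(or$pvalue, e$pvalue)
  expect_error(to_odds_ratio(or), "already")
})

test_that("estimates scale correctly under rescaling of either axis", {
  h <- mk_h(L = 15, beta = 0.3, seed = 21)
  c_ <- 2.5
  hx <- harmonized_set(h$beta_x * c_, h$se_x * c_, h$beta_y, h$se_y)
  hy <- harmonized_set(h$beta_x, h$se_x, h$beta_y * c_, h$se_y * c_)
  for (f in list(function(z) mr_ivw(z, "fixed")$beta,
                 function(z) mr_weighted_median(z, b_boot = 0)$beta,
                 function(z) mr_mbe(z, b_boot = 0)$beta,
                 function(z) mr_egger(z)$slope$beta)) {
    expect_equal(f(hx), f(h) / c_, tolerance = 1e-9)
    expect_equal(f(hy), f(h) * c_, tolerance = 1e-9)
  }
})
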