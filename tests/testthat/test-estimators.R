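test_that("wald ratio arithmetic, null case and zero-denominator error", {
  h <- make_harmonized(0.5, 0.1, se_exp = 0.01, se_out = 0.05)
  est <- mr_wald_ratio(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$or, exp(0.2), tolerance = 1e-15)
  expect_lt(est$ci_low, est$or); expect_gt(est$ci_high, est$or)

  null <- mr_wald_ratio(make_harmonized(0.5, 0))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  expect_error(mr_wald_ratio(make_harmonized(0, 0.1)), "zero")
})

test_that("first-order wald se matches the Monte-Carlo ratio sd for strong instruments", {
  bx <- 0.5; sx <- 0.02; by <- 0.1; sy <- 0.05  # |bx/sx| = 25
  est <- mr_wald_ratio(make_harmonized(bx, by, sx, sy))
  mc_sd <- withr::with_seed(91, sd(rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)))
  expect_equal(est$se, mc_sd, tolerance = 0.05)
  # and the second-order correction stays within 5% when bx/sx > 10
  se2 <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  expect_equal(est$se, se2, tolerance = 0.05)
})

test_that("IVW reduces to the Wald ratio and to the consensus of equal ratios", {
  h1 <- make_harmonized(0.5, 0.1)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(h1)$beta)
  expect_equal(mr_ivw(h1)$method, "wald_ratio")

  h3 <- make_harmonized(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8) * 0.3,
                        se_out = c(0.01, 0.07, 0.02))
  expect_equal(mr_ivw(h3)$beta, 0.3, tolerance = 1e-12)

  # a SNP with zero exposure effect is excluded with a warning
  h0 <- make_harmonized(c(0.2, 0, 0.8), c(0.06, 0.1, 0.24))
  expect_warning(est <- mr_ivw(h0), "zero exposure effect")
  expect_equal(est$n_snp, 2L)
})

test_that("IVW and Egger match a generic weighted-least-squares oracle to 1e-10 relative", {
  h <- fixture_20snp()
  w <- 1 / h$se_out^2

  ivw <- mr_ivw(h, model = "fixed")
  fit0 <- lm(beta_out ~ 0 + beta_exp, data = h, weights = w)
  expect_equal(ivw$beta, unname(coef(fit0)[1]), tolerance = 1e-10)
  expect_equal(ivw$se, sqrt(1 / sum(w * h$beta_exp^2)), tolerance = 1e-10)
  # random-effects model shares the point estimate
  expect_equal(mr_ivw(h)$beta, ivw$beta, tolerance = 1e-15)

  egger <- mr_egger(h)
  fit1 <- lm(beta_out ~ beta_exp, data = h, weights = w)  # beta_exp > 0 here
  expect_equal(egger$beta, unname(coef(fit1)[2]), tolerance = 1e-10)
  expect_equal(egger$egger_intercept, unname(coef(fit1)[1]), tolerance = 1e-10)
  # lm's coefficient SEs scale with sigma-hat; reconciling the two error
  # models recovers the spec'd truncated multiplicative random-effects SE
  sm <- summary(fit1)
  expect_equal(egger$se,
               unname(sm$coefficients[2, 2]) / min(1, sm$sigma),
               tolerance = 1e-10)
})

test_that("Egger recovers injected directional pleiotropy with an unbiased slope", {
  res <- t(vapply(1:50, function(s) {
    st <- simulate_gwas(simulation_config(
      seed = 6000 + s, n_snp_mediator = 0, n_snp_null = 0,
      pleiotropy = list(mode = "directional", offset = 0.01, sd = 0)))
    h <- harmonized_from_study(st)
    e <- mr_egger(h)
    c(e$egger_intercept, e$beta)
  }, numeric(2)))
  expect_gt(mean(res[, 1]), 0.005)
  expect_lt(mean(res[, 1]), 0.015)
  # slope unbiased despite the pleiotropy: within 2 MC SEs of the truth
  truth <- 0.06 * log(1.25) + 0.22
  expect_lt(abs(mean(res[, 2]) - truth), 2 * sd(res[, 2]) / sqrt(nrow(res)))
})

test_that("Egger intercept p-values are calibrated under the zero-pleiotropy null", {
  p <- vapply(1:200, function(s) {
    st <- simulate_gwas(simulation_config(seed = 7000 + s,
                                          n_snp_mediator = 0, n_snp_null = 0))
    mr_egger(harmonized_from_study(st))$egger_intercept_p
  }, numeric(1))
  # truncated random-effects scaling makes the test mildly conservative,
  # never anti-conservative; calibration holds at KS level 0.01
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_gt(mean(p), 0.45)
})

test_that("weighted median reduces to the simple median and obeys dominance", {
  h <- make_harmonized(c(1, 1, 1), c(1, 2, 9), se_out = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 2)

  # dominant SNP (90% of the weight) sits at its own ratio
  w_target <- c(0.05, 0.9, 0.05)
  bx <- sqrt(w_target)  # se_out = 1 -> weights bx^2
  h2 <- make_harmonized(bx, bx * c(1, 2, 9), se_out = c(1, 1, 1))
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$beta, 2)
})

test_that("weighted median lies within the per-SNP ratio range", {
  withr::with_seed(92, {
    for (i in 1:20) {
      k <- sample(3:15, 1)
      h <- make_harmonized(runif(k, 0.1, 1), rnorm(k),
                           se_out = runif(k, 0.1, 1))
      est <- mr_weighted_median(h, n_boot = 100, seed = i)
      ratios <- h$beta_out / h$beta_exp
      expect_gte(est$beta, min(ratios))
      expect_lte(est$beta, max(ratios))
    }
  })
})

test_that("weighted-median bootstrap se stabilizes with resample count", {
  h <- fixture_20snp()
  se5 <- mr_weighted_median(h, n_boot = 5000, seed = 13)$se
  se10 <- mr_weighted_median(h, n_boot = 10000, seed = 14)$se
  expect_lt(abs(se5 - se10) / se10, 0.03)
})

test_that("all estimators are invariant to rescaling the exposure", {
  h <- fixture_20snp()
  for (k in c(0.1, 10)) {
    hk <- h
    hk$beta_exp <- k * h$beta_exp
    hk$se_exp <- k * h$se_exp
    hk <- as_harmonized_set(as.data.frame(hk))
    expect_equal(mr_ivw(hk)$beta, mr_ivw(h)$beta / k, tolerance = 1e-12)
    expect_equal(mr_egger(hk)$beta, mr_egger(h)$beta / k, tolerance = 1e-12)
    expect_equal(mr_egger(hk)$egger_intercept, mr_egger(h)$egger_intercept,
                 tolerance = 1e-12)
    h1 <- as_harmonized_set(as.data.frame(h)[1, , drop = FALSE])
    hk1 <- as_harmonized_set(as.data.frame(hk)[1, , drop = FALSE])
    expect_equal(mr_wald_ratio(hk1)$beta, mr_wald_ratio(h1)$beta / k,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_median(hk, n_boot = 500, seed = 3)$beta,
                 mr_weighted_median(h, n_boot = 500, seed = 3)$beta / k,
                 tolerance = 1e-12)
  }
})

test_that("IVW recovers a log(1.25) effect at biobank scale across seeds", {
  est <- vapply(1:100, function(s) {
    st <- simulate_gwas(simulation_config(
      seed = 7500 + s, n_snp_causal = 50, n_snp_mediator = 0, n_snp_null = 0,
      beta_xm = 0, beta_my = 0, beta_xy_direct = log(1.25)))
    mr_ivw(harmonized_from_study(st))$beta
  }, numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(1.25)), 2 * mcse)
})

test_that("mr_all dispatches on instrument count", {
  expect_named(mr_all(make_harmonized(0.5, 0.1)), "wald_ratio")
  expect_named(mr_all(make_harmonized(c(0.4, 0.5), c(0.1, 0.12)),
                      seed = 1), "ivw")
  expect_setequal(names(mr_all(fixture_20snp(), seed = 1)),
                  c("ivw", "egger", "weighted_median"))
})
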