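test_that("exact within fit on a noiseless two-entity panel", {
  d <- data.frame(province = rep(c("Beijing", "Tianjin"), each = 2),
                  year = rep(c(2005L, 2010L), 2),
                  x = c(1, 2, 3, 5))
  d$y <- ifelse(d$province == "Beijing", 0.2, 0.6) + 1.0 * d$x
  fit <- panel_fe(y ~ x, d)
  expect_equal(unname(coef(fit)), 1.0, tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), rep(0, 4), tolerance = 1e-12)
  # estimated entity effects recover the intercepts
  expect_equal(unname(fit$effects[c("Beijing", "Tianjin")]), c(0.2, 0.6),
               tolerance = 1e-12)
})

test_that("within estimator reproduces LSDV coefficients and SEs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 12L; Tn <- 4L
    provs <- province_roster()[seq_len(n)]
    d <- data.frame(province = rep(provs, each = Tn),
                    year = rep(seq_len(Tn), n),
                    x1 = rnorm(n * Tn), x2 = rnorm(n * Tn),
                    x3 = rnorm(n * Tn))
    alpha <- rnorm(n, sd = 2)
    d$y <- rep(alpha, each = Tn) + 0.5 * d$x1 - 1.2 * d$x2 + 0.1 * d$x3 +
      rnorm(n * Tn, sd = 0.7)
    fit <- panel_fe(y ~ x1 + x2 + x3, d)
    lsdv <- oracle_lsdv(y ~ x1 + x2 + x3, d)
    expect_equal(unname(coef(fit)[rownames(lsdv)]),
                 unname(lsdv[, "Estimate"]), tolerance = 1e-8)
    expect_equal(unname(sqrt(diag(vcov(fit)))[rownames(lsdv)]),
                 unname(lsdv[, "Std. Error"]), tolerance = 1e-8)
  }
})

test_that("FE slopes ignore entity-constant shifts of the response", {
  d <- generate_covariate_panel(sim_config(seed = 77))
  fml <- A ~ POO + ODR + AHS + lnGDP + PST + UL + UR + AYE + SAE
  f1 <- panel_fe(fml, d)
  shift <- stats::setNames(rnorm(31, sd = 5), province_roster())
  d2 <- d
  d2$A <- d2$A + shift[d2$province]
  f2 <- panel_fe(fml, d2)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-10)
})

test_that("fit statistics are internally consistent", {
  d <- generate_covariate_panel(sim_config(seed = 55))
  fit <- panel_fe(A ~ POO + ODR + lnGDP + AYE, d)
  expect_equal(nobs(fit), 93L)
  expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
  expect_equal(fit$F,
               (fit$r2 / fit$K) / ((1 - fit$r2) / fit$dof))
  sm <- summary(fit)
  expect_equal(sm$coefficients$t_value,
               sm$coefficients$estimate / sm$coefficients$std_error)
  tcrit <- qt(0.975, fit$dof)
  expect_equal(sm$coefficients$ci_upper,
               sm$coefficients$estimate +
                 tcrit * sm$coefficients$std_error)
  expect_equal(sm$aic, AIC(fit))
  expect_equal(sm$bic, BIC(fit))
  # stars follow the 1/5/10 percent thresholds
  p <- sm$coefficients$p_value
  expect_equal(sm$coefficients$stars,
               ifelse(p < 0.01, "***",
                      ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", ""))))
})

test_that("regressors without within variation are dropped with warning", {
  d <- generate_covariate_panel(sim_config(seed = 20))
  d$flat <- stats::setNames(rnorm(31), province_roster())[d$province]
  expect_warning(fit <- panel_fe(A ~ POO + flat, d), "flat")
  expect_false("flat" %in% names(coef(fit)))
})

test_that("random effects hit the pooled and within limits", {
  # no entity effects, no noise: RE equals pooled OLS and the truth
  cfg0 <- sim_config(seed = 9, entity_sd = 0, y_noise_sd = 0, rho = 0)
  d0 <- generate_covariate_panel(cfg0)
  fml <- A ~ POO + ODR + AHS + lnGDP + PST + UL + UR + AYE + SAE
  re0 <- suppressWarnings(panel_re(fml, d0))
  beta <- attr(d0, "beta")
  expect_equal(coef(re0)[names(beta)], beta, tolerance = 1e-6)
  pooled <- lm(fml, data = d0)
  expect_equal(coef(re0)[names(beta)], coef(pooled)[names(beta)],
               tolerance = 1e-6)

  # dominant entity variance: RE approaches FE
  cfg1 <- sim_config(seed = 10, entity_sd = 25, y_noise_sd = 0.01)
  d1 <- generate_covariate_panel(cfg1)
  fe1 <- panel_fe(fml, d1)
  re1 <- panel_re(fml, d1)
  expect_equal(coef(re1)[names(coef(fe1))], coef(fe1), tolerance = 0.02)
  expect_gt(min(re1$theta), 0.9)
})

test_that("RE is more efficient than FE when effects are uncorrelated", {
  fml <- A ~ POO + ODR + AHS + lnGDP + PST + UL + UR + AYE + SAE
  wins <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    d <- generate_covariate_panel(sim_config(seed = 5000 + r, rho = 0))
    fe <- panel_fe(fml, d)
    re <- panel_re(fml, d)
    common <- names(coef(fe))
    if (mean(sqrt(diag(vcov(re)))[common]) <
          mean(sqrt(diag(vcov(fe)))[common])) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.90)
})

test_that("Hausman test is zero on identical fits and behaves under truth", {
  d <- generate_covariate_panel(sim_config(seed = 64))
  fe <- panel_fe(A ~ POO + ODR + lnGDP, d)
  h0 <- suppressWarnings(hausman_test(fe, fe))
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)
  expect_equal(h0$recommendation, "random")
})

test_that("FE bias is smaller than RE bias under correlated effects", {
  fml <- A ~ POO + ODR + AHS + lnGDP + PST + UL + UR + AYE + SAE
  fe_err <- re_err <- numeric(200L)
  for (r in 1:200) {
    cfg <- sim_config(seed = 9000 + r, rho = 0.8)
    d <- generate_covariate_panel(cfg)
    truth <- attr(d, "beta")["lnGDP"]
    fe_err[r] <- coef(panel_fe(fml, d))["lnGDP"] - truth
    re_err[r] <- coef(panel_re(fml, d))["lnGDP"] - truth
  }
  expect_lt(abs(mean(fe_err)), abs(mean(re_err)))
})
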