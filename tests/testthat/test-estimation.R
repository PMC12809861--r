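# Fitting tests use modest sample sizes so the default run stays fast;
# the heavier calibration checks live in test-acceptance.R.

sim_fit_data <- function(seed, n = 400, K = 0.05, h2 = 0.70, c2 = 0.10,
                         rg = -0.30, re = -0.05) {
  cfg <- quick_cfg(n_mz = n, n_dz = n, seed = seed, h2 = h2, c2 = c2,
                   rg = rg, re = re,
                   disease = disease_model(0.84, 0, 0.16, K))
  simulate_population(cfg)
}

test_that("degenerate inputs error clearly", {
  ds <- tiny_dataset()
  empty <- twin_data(ds$data[0, , drop = FALSE], measures = "iq",
                     phenotypes = "dx")
  expect_error(fit_bivariate_ace(empty, "iq", "dx", "maudsley_sz"),
               "empty dataset")
  expect_error(fit_bivariate_ace(ds, "nope", "dx", "maudsley_sz"),
               "unknown measure")
})

test_that("the fit recovers generating parameters on population data", {
  pop <- sim_fit_data(seed = 21, n = 800)
  fit <- fit_bivariate_ace(pop, "score", "dx",
                           disease_model(0.84, 0, 0.16, 0.05),
                           covariates = FALSE, seed = 1)
  expect_true(fit$convergence$converged)
  expect_lt(fit$convergence$grad_norm, 1e-3)
  e <- fit$estimates
  expect_equal(e$h2 + e$c2 + e$e2, 1, tolerance = 1e-8)
  expect_lt(abs(e$h2 - 0.70), 0.12)
  expect_lt(abs(e$rg - (-0.30)), 0.15)
  expect_equal(e$v, 1, tolerance = 0.12)
  # rc is auto-fixed at 0 when the disease profile has no shared environment
  expect_identical(e$rc, 0)
})

test_that("estimates are invariant to affine rescaling of the measure", {
  pop <- sim_fit_data(seed = 31, n = 300)
  fit1 <- fit_bivariate_ace(pop, "score", "dx",
                            disease_model(0.84, 0, 0.16, 0.05),
                            covariates = FALSE, seed = 1)
  pop2 <- pop
  pop2$data$score <- 15 * pop2$data$score + 100
  fit2 <- fit_bivariate_ace(pop2, "score", "dx",
                            disease_model(0.84, 0, 0.16, 0.05),
                            covariates = FALSE, seed = 1)
  for (nm in c("h2", "c2", "e2", "rg", "re"))
    expect_equal(fit1$estimates[[nm]], fit2$estimates[[nm]],
                 tolerance = 1e-4, label = nm)
  expect_equal(fit2$estimates$v, 225 * fit1$estimates$v, tolerance = 0.02)
  expect_equal(fit2$estimates$mu, 100 + 15 * fit1$estimates$mu,
               tolerance = 0.5)
})

test_that("covariate effects on the mean are recovered", {
  cfg <- sim_config(n_mz = 400, n_dz = 400, n_sib = 0,
                    params = ace_params(a = sqrt(0.7), c = sqrt(0.1),
                                        e = sqrt(0.2), rg = -0.3, rc = 0,
                                        re = 0, mu = 0),
                    disease = disease_model(0.84, 0, 0.16, 0.05),
                    covariate_effects = list(age = -0.02, sex = 0.3,
                                             education = 0.05,
                                             centre = c(0, 0.4)),
                    centre_probs = c(0.6, 0.4), seed = 8)
  pop <- simulate_population(cfg)
  fit <- fit_bivariate_ace(pop, "score", "dx",
                           disease_model(0.84, 0, 0.16, 0.05),
                           covariates = TRUE, seed = 1)
  b <- fit$estimates$beta
  names(b) <- colnames(fit$X)
  expect_lt(abs(b["age"] - (-0.02)), 0.01)
  expect_lt(abs(b["sex"] - 0.3), 0.15)
  expect_lt(abs(b["centre_centre2"] - 0.4), 0.2)
})

test_that("freeing a parameter never lowers the maximized likelihood and
           the LRT follows the chi-square identity", {
  pop <- sim_fit_data(seed = 41, n = 300)
  dz <- disease_model(0.84, 0, 0.16, 0.05)
  full <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                            seed = 1)
  norg <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                            fix = list(rg = 0), seed = 1)
  expect_gte(full$loglik, norg$loglik - 1e-6)
  lrt <- likelihood_ratio_test(full, norg, df = 1)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  # identity: a deviance drop of 1.92073 at 1 df sits at p = 0.05
  self <- likelihood_ratio_test(full, full, df = 1)
  expect_identical(self$statistic, 0)
  expect_identical(self$p, 1)
  fake <- list(loglik = full$loglik - 1.92073)
  expect_equal(likelihood_ratio_test(full, fake, df = 1)$statistic,
               3.84146, tolerance = 1e-4)
  expect_equal(likelihood_ratio_test(full, fake, df = 1)$p, 0.05,
               tolerance = 1e-4)
  expect_error(likelihood_ratio_test(full, norg, df = 0), "df")
})

test_that("the rg likelihood-ratio test is calibrated under the null", {
  # data generated with rg = 0: the 1-df LRT p-values should be uniform;
  # 40 scaled-down replicates, so the checks are coarse by design
  dz <- disease_model(0.84, 0, 0.16, 0.05)
  ps <- vapply(1:40, function(r) {
    pop <- sim_fit_data(seed = 500 + r, n = 250, rg = 0, re = 0)
    full <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                              n_starts = 1, seed = r)
    nested <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                                fix = list(rg = 0), n_starts = 1, seed = r)
    likelihood_ratio_test(full, nested, df = 1)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.15)   # type-I error near alpha
  expect_gt(mean(ps), 0.35)           # uniform null: mean p about 0.5
  expect_lt(mean(ps), 0.68)
})

test_that("profile intervals contain the MLE and flag boundary endpoints", {
  pop <- sim_fit_data(seed = 51, n = 400)
  dz <- disease_model(0.84, 0, 0.16, 0.05)
  fit <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                           seed = 1)
  ci_h2 <- profile_ci(fit, "h2")
  expect_lte(ci_h2[1], fit$estimates$h2)
  expect_gte(ci_h2[2], fit$estimates$h2)
  ci_rg <- profile_ci(fit, "rg")
  expect_lte(ci_rg[1], fit$estimates$rg)
  expect_gte(ci_rg[2], fit$estimates$rg)
  # c2 typically sits near its lower bound here: boundary flag mechanics
  ci_c2 <- profile_ci(fit, "c2")
  expect_gte(ci_c2[1], 0)
  # a parameter fixed in the fit reports a degenerate, flagged interval
  fx <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                          fix = list(rg = 0), seed = 1)
  ci_fx <- profile_ci(fx, "rg")
  expect_identical(as.numeric(ci_fx), c(0, 0))
  expect_true(all(attr(ci_fx, "boundary")))
})

test_that("the sub-model battery reports one LRT per restriction", {
  pop <- sim_fit_data(seed = 61, n = 300)
  dz <- disease_model(0.84, 0, 0.16, 0.05)
  fit <- fit_bivariate_ace(pop, "score", "dx", dz, covariates = FALSE,
                           seed = 1)
  tab <- ace_submodel_tests(fit)
  expect_identical(tab$restriction, c("rg=0", "rph_a=0", "h2=0"))
  expect_true(all(tab$statistic >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
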