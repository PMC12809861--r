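test_that("prevalence threshold inverts the normal upper tail", {
  expect_identical(threshold_from_prevalence(0.5), 0)
  # frozen values from the quadrature-inversion oracle
  expect_equal(threshold_from_prevalence(0.0075), 2.432379, tolerance = 1e-6)
  expect_equal(threshold_from_prevalence(0.017), 2.120072, tolerance = 1e-6)
  for (K in c(0.0032, 0.0075, 0.01, 0.017, 0.5))
    expect_lt(abs(pnorm(threshold_from_prevalence(K),
                        lower.tail = FALSE) - K), 1e-12)
  expect_error(threshold_from_prevalence(0), "strictly")
  expect_error(threshold_from_prevalence(1.2), "strictly")
})

test_that("disease profiles carry the fixed published parameters", {
  sz <- disease_profile("maudsley_sz")
  expect_equal(c(sz$h2, sz$c2, sz$e2, sz$prevalence),
               c(0.84, 0, 0.16, 0.0075))
  expect_equal(disease_profile("maudsley_bd1")$prevalence, 0.0032)
  br <- disease_profile("maudsley_broad")
  expect_equal(c(br$h2, br$prevalence), c(0.90, 0.017))
  expect_equal(disease_profile("polderman_sz")$h2, 0.77)
  expect_error(disease_model(0.8, 0.1, 0.2, 0.01), "equal 1")
  expect_error(disease_profile("nope"), "unknown")
})

test_that("kinship coefficients are the biometrical constants", {
  expect_identical(kinship_coefficient("MZ"), 1.0)
  expect_identical(kinship_coefficient("DZ"), 0.5)
  expect_identical(kinship_coefficient("SIB"), 0.5)
  expect_error(kinship_coefficient("HZ"), "unknown")
})

test_that("expected pair covariance matches the path-rule entries", {
  sz <- disease_profile("maudsley_sz")
  pr <- ace_params(a = sqrt(0.3), c = sqrt(0.2), e = sqrt(0.5),
                   rg = 0.42, rc = 0, re = 0)
  S_mz <- expected_pair_covariance(pr, sz, 1.0)
  S_dz <- expected_pair_covariance(pr, sz, 0.5)
  expect_equal(S_mz["l1", "l2"], 0.84)
  expect_equal(S_dz["l1", "l2"], 0.42)
  expect_equal(S_mz["y1", "y1"], 1)
  expect_equal(S_mz["y1", "y2"], 0.3 + 0.2)
  expect_equal(S_dz["y1", "y2"], 0.15 + 0.2)
  # product rule for the within-member cross-trait entry, h2_d = 0.90
  br <- disease_profile("maudsley_broad")
  S <- expected_pair_covariance(ace_params(a = sqrt(0.3), c = sqrt(0.22),
                                           e = sqrt(0.48), rg = 0.42),
                                br, 1.0)
  expect_equal(S["y1", "l1"], 0.42 * sqrt(0.3 * 0.90), tolerance = 1e-12)
  expect_equal(round(S["y1", "l1"], 2), 0.22)
  # independence when all cross-trait correlations vanish
  S0 <- expected_pair_covariance(ace_params(1, 1, 1), sz, 0.5)
  expect_true(all(S0[1:2, 3:4] == 0))
  # symmetry under member exchange
  sw <- c(2, 1, 4, 3)
  S1 <- expected_pair_covariance(ace_params(0.8, 0.4, 0.6, rg = -0.5,
                                            re = 0.2), sz, 0.5)
  expect_equal(unname(S1[sw, sw]), unname(S1), ignore_attr = TRUE)
})

test_that("bivariate normal CDF agrees with the integration oracle", {
  set.seed(42)
  for (rho in c(-0.99, -0.9, -0.6, -0.2, 0.3, 0.7, 0.924, 0.926, 0.99)) {
    h <- runif(5, -3.5, 3.5); k <- runif(5, -3.5, 3.5)
    expect_equal(pbvn(h, k, rho),
                 mapply(oracle_pbvn, h, k, MoreArgs = list(rho = rho)),
                 tolerance = 1e-10)
  }
  expect_equal(pbvn(0, 0, 0.5), 1 / 4 + asin(0.5) / (2 * pi),
               tolerance = 1e-14)
})

test_that("pair log-likelihood reproduces closed-form special cases", {
  half <- disease_model(0.84, 0, 0.16, 0.5)
  pr <- ace_params(1, 0.5, 1)
  # singleton, affection only, K = 0.5
  expect_equal(pair_loglik(c(NA, NA), c(0, NA), "MZ", pr, half), log(0.5))
  # MZ pair, both affected, no cognition: upper orthant at tau with rho 0.84
  sz <- disease_profile("maudsley_sz")
  got <- pair_loglik(c(NA, NA), c(1, 1), "MZ", pr, sz)
  orth <- twinace:::bvnu(sz$tau, sz$tau, 0.84)
  expect_equal(got, log(orth), tolerance = 1e-12)
  expect_equal(got, oracle_pair_loglik(c(NA, NA), c(1, 1), "MZ", pr, sz),
               tolerance = 1e-8)
})

test_that("affection-pattern probabilities sum to one given any cognition", {
  sz <- disease_profile("maudsley_sz")
  set.seed(7)
  for (i in 1:20) {
    pr <- ace_params(a = runif(1, 0.3, 1), c = runif(1, 0.1, 0.8),
                     e = runif(1, 0.3, 1), rg = runif(1, -0.9, 0.9),
                     rc = 0, re = runif(1, -0.7, 0.7), mu = rnorm(1))
    y <- rnorm(2, pr$mu, 1)
    zyg <- sample(c("MZ", "DZ", "SIB"), 1)
    dens <- pair_loglik(y, c(NA, NA), zyg, pr, sz)
    tot <- sum(vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(d)
      exp(pair_loglik(y, d, zyg, pr, sz) - dens), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("marginal affection probability equals the prevalence", {
  for (nm in disease_profiles()) {
    dz <- disease_profile(nm)
    pr <- ace_params(0.7, 0.4, 0.6, rg = -0.4, rc = 0, re = 0.2)
    p_aff <- exp(pair_loglik(c(NA, NA), c(1, NA), "DZ", pr, dz))
    expect_equal(p_aff, dz$prevalence, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to swapping pair members", {
  sz <- disease_profile("maudsley_sz")
  set.seed(3)
  for (i in 1:10) {
    pr <- ace_params(a = runif(1, 0.3, 1), c = runif(1, 0.1, 0.8),
                     e = runif(1, 0.3, 1), rg = runif(1, -0.9, 0.9),
                     rc = 0, re = runif(1, -0.7, 0.7))
    y <- rnorm(2); d <- sample(0:1, 2, replace = TRUE)
    zyg <- sample(c("MZ", "DZ"), 1)
    expect_equal(pair_loglik(y, d, zyg, pr, sz),
                 pair_loglik(rev(y), rev(d), zyg, pr, sz),
                 tolerance = 1e-12)
  }
})

test_that("implied cross-twin cognitive correlation is monotone in kinship", {
  sz <- disease_profile("maudsley_sz")
  pr <- ace_params(a = sqrt(0.6), c = sqrt(0.15), e = sqrt(0.25))
  r_at <- function(RA) {
    S <- expected_pair_covariance(pr, sz, RA)
    S["y1", "y2"] / S["y1", "y1"]
  }
  rs <- vapply(c(0, 0.25, 0.5, 0.75, 1), r_at, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_equal(r_at(0.5), 0.6 * 0.5 + 0.15)
})
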