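# Independent oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own computational path:
# probabilities come from stats::integrate, not from pbvn()/.fiml_ll().

# upper-tail threshold by inverting a numerically integrated normal density
oracle_threshold <- function(K) {
  f <- function(t)
    stats::integrate(stats::dnorm, t, Inf, rel.tol = 1e-13,
                     abs.tol = 1e-15)$value - K
  stats::uniroot(f, c(-9, 9), tol = 1e-13)$root
}

# brute-force pair log-likelihood: observed-cognition density times the
# affection-pattern probability obtained by nested 1-D quadrature over the
# conditional liabilities
oracle_pair_loglik <- function(y, d, zyg, pr, dz) {
  S <- expected_pair_covariance(pr, dz, kinship_coefficient(zyg))
  obs <- c(!is.na(y), !is.na(d))
  idx <- (1:4)[obs]
  iy <- idx[idx <= 2]; il <- idx[idx > 2]
  m <- rep(pr$mu, 2)
  ll <- 0
  if (length(iy)) {
    Syy <- S[iy, iy, drop = FALSE]
    r <- y[iy] - m[iy]
    ll <- ll - 0.5 * (t(r) %*% solve(Syy) %*% r +
                        determinant(Syy)$modulus +
                        length(iy) * log(2 * pi))
  }
  if (length(il)) {
    if (length(iy)) {
      W <- S[il, iy, drop = FALSE] %*% solve(S[iy, iy, drop = FALSE])
      cm <- as.vector(W %*% (y[iy] - m[iy]))
      Sc <- S[il, il, drop = FALSE] - W %*% S[iy, il, drop = FALSE]
    } else {
      cm <- rep(0, length(il)); Sc <- S[il, il, drop = FALSE]
    }
    dd <- d[il - 2]
    tau <- dz$tau
    if (length(il) == 1) {
      sdc <- sqrt(Sc[1, 1])
      p <- if (dd == 1)
        stats::integrate(function(l) dnorm(l, cm, sdc), tau, Inf,
                         rel.tol = 1e-10)$value
      else
        stats::integrate(function(l) dnorm(l, cm, sdc), -Inf, tau,
                         rel.tol = 1e-10)$value
    } else {
      rho <- Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
      l2 <- if (dd[2] == 1) c(tau, 40) else c(-40, tau)
      inner <- function(x1) vapply(x1, function(a) {
        cmu <- cm[2] + rho * sqrt(Sc[2, 2] / Sc[1, 1]) * (a - cm[1])
        csd <- sqrt(Sc[2, 2] * (1 - rho^2))
        dnorm(a, cm[1], sqrt(Sc[1, 1])) *
          (pnorm(l2[2], cmu, csd) - pnorm(l2[1], cmu, csd))
      }, numeric(1))
      l1 <- if (dd[1] == 1) c(tau, 40) else c(-40, tau)
      p <- stats::integrate(inner, l1[1], l1[2], rel.tol = 1e-9,
                            abs.tol = 1e-13)$value
    }
    ll <- ll + log(p)
  }
  as.numeric(ll)
}

# 2-D CDF oracle for pbvn
oracle_pbvn <- function(h, k, rho) {
  f <- function(x) pnorm((k - rho * x) / sqrt(1 - rho^2)) * dnorm(x)
  stats::integrate(f, -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# small hand-built dataset: 2 MZ pairs, 1 DZ pair, 1 SIB singleton
tiny_dataset <- function() {
  twin_data(data.frame(
    pair_id = c(1, 1, 2, 2, 3, 3, 4),
    member_index = c(1, 2, 1, 2, 1, 2, 1),
    zygosity = c("MZ", "MZ", "MZ", "MZ", "DZ", "DZ", "SIB"),
    affected_dx = c(0, 0, 1, 0, 0, NA, 1),
    iq = c(100, 104, 92, NA, 110, 98, 85),
    age = c(30, 30, 45, 45, 22, 25, 50),
    sex = c(0, 0, 1, 1, 0, 1, 1),
    education = c(12, 13, 10, 11, 16, 15, 9),
    centre = c("A", "A", "B", "B", "A", "A", "B"),
    stringsAsFactors = FALSE))
}

# default quick simulation: standardized trait, no covariate effects
quick_cfg <- function(n_mz = 400, n_dz = 400, n_sib = 0, seed = 1,
                      h2 = 0.70, c2 = 0.10, rg = -0.30, re = -0.05,
                      disease = disease_profile("maudsley_sz")) {
  e2 <- 1 - h2 - c2
  sim_config(n_mz = n_mz, n_dz = n_dz, n_sib = n_sib,
             params = ace_params(a = sqrt(h2), c = sqrt(c2), e = sqrt(e2),
                                 rg = rg, rc = 0, re = re, mu = 0),
             disease = disease,
             covariate_effects = list(age = 0, sex = 0, education = 0,
                                      centre = c(0, 0, 0)),
             seed = seed)
}
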