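#' Bivariate ACE parameters for the cognitive trait
#'
#' The "correlated factors" parameterization: path coefficients `a`, `c`, `e`
#' for the cognitive measure (variances a^2, c^2, e^2), cross-trait factor
#' correlations `rg`, `rc`, `re` with the disease liability, an intercept
#' `mu` and covariate coefficients `beta`. The disease side is carried by a
#' fixed [disease_model] and is never part of this object.
#'
#' @param a,c,e path coefficients (`e` must be positive).
#' @param rg,rc,re A-, C- and E-factor cross-trait correlations in `[-1, 1]`.
#' @param mu intercept of the cognitive mean.
#' @param beta covariate coefficient vector (may be empty).
#' @return an `ace_params` object.
#' @export
ace_params <- function(a, c, e, rg = 0, rc = 0, re = 0, mu = 0,
                       beta = numeric(0)) {
  if (e <= 0) stop("e must be > 0")
  for (r in list(rg = rg, rc = rc, re = re))
    if (abs(r) > 1) stop("factor correlations must lie in [-1, 1]")
  structure(list(a = a, c = c, e = e, rg = rg, rc = rc, re = re,
                 mu = mu, beta = beta),
            class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  v <- x$a^2 + x$c^2 + x$e^2
  cat(sprintf(
    "<ace_params> h2=%.3f c2=%.3f e2=%.3f (var=%.3f)  rg=%.3f rc=%.3f re=%.3f\n",
    x$a^2 / v, x$c^2 / v, x$e^2 / v, v, x$rg, x$rc, x$re))
  invisible(x)
}

#' Additive-genetic kinship coefficient for a pair class
#'
#' MZ twins share all segregating genes (1.0); DZ twins and full siblings
#' share half on average (0.5). Shared environment C correlates 1 in every
#' pair class and E correlates 0.
#'
#' @param zygosity `"MZ"`, `"DZ"` or `"SIB"`.
#' @return scalar kinship coefficient.
#' @export
kinship_coefficient <- function(zygosity) {
  switch(toupper(as.character(zygosity)),
         MZ = 1.0, DZ = 0.5, SIB = 0.5,
         stop("unknown zygosity code: ", zygosity))
}

#' Expected pair covariance of (cognition, liability)
#'
#' The model-implied 4x4 covariance of `(y1, y2, l1, l2)`: both members'
#' cognitive scores and disease liabilities. Liabilities are on the unit
#' variance scale with cross-member covariance `R_A * h2_d + c2_d`; the
#' cognitive block follows the ACE decomposition, and the cross-trait block
#' combines the factor correlations with the path coefficients.
#'
#' @param params an [ace_params].
#' @param disease a [disease_model].
#' @param R_A kinship coefficient (see [kinship_coefficient()]).
#' @return 4x4 symmetric matrix with dimnames `y1,y2,l1,l2` and attribute
#'   `psd` (FALSE flags an invalid parameter point for the optimizer).
#' @export
expected_pair_covariance <- function(params, disease, R_A) {
  p <- params; dz <- disease
  vy <- p$a^2 + p$c^2 + p$e^2
  cyy <- R_A * p$a^2 + p$c^2
  cll <- R_A * dz$h2 + dz$c2
  within <- p$rg * p$a * sqrt(dz$h2) + p$rc * p$c * sqrt(dz$c2) +
    p$re * p$e * sqrt(dz$e2)
  cross <- R_A * p$rg * p$a * sqrt(dz$h2) + p$rc * p$c * sqrt(dz$c2)
  S <- matrix(c(vy,    cyy,   within, cross,
                cyy,   vy,    cross,  within,
                within, cross, 1,     cll,
                cross, within, cll,   1), 4, 4,
              dimnames = list(c("y1", "y2", "l1", "l2"),
                              c("y1", "y2", "l1", "l2")))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  attr(S, "psd") <- min(ev) > -1e-10
  S
}

# ---------------------------------------------------------------------------
# FIML engine
#
# Joint likelihood of observed cognition and affection pattern for one pair:
#   log N(y_obs; m_obs, S_yy) + log P(affection pattern | y_obs)
# where the conditional liability distribution given y_obs is normal with a
# covariance that depends only on (zygosity, missingness pattern), so pairs
# are grouped by pattern and the orthant probabilities vectorize with a
# scalar conditional correlation per group.
# ---------------------------------------------------------------------------

# Precompute missingness-pattern groups for a pair table: the conditional
# liability covariance is constant within (zygosity kind, pattern), so the
# per-evaluation work is a handful of vectorized blocks.
.fiml_groups <- function(pt) {
  n <- nrow(pt)
  oy1 <- !is.na(pt$y1); oy2 <- !is.na(pt$y2)
  od1 <- !is.na(pt$d1); od2 <- !is.na(pt$d2)
  mz <- pt$zyg == "MZ"
  key <- mz * 16L + oy1 * 8L + oy2 * 4L + od1 * 2L + od2
  lapply(unique(key), function(g) {
    idx <- which(key == g)
    i <- idx[1]
    iy <- c(1L, 2L)[c(oy1[i], oy2[i])]
    il <- c(3L, 4L)[c(od1[i], od2[i])]
    list(idx = idx, zk = if (mz[i]) "MZ" else "DZ", iy = iy, il = il,
         Y = cbind(pt$y1, pt$y2)[idx, iy - 0L, drop = FALSE],
         D = cbind(pt$d1, pt$d2)[idx, il - 2L, drop = FALSE])
  })
}

.fiml_ll <- function(groups, sigma_by, tau, m1, m2) {
  for (S in sigma_by) if (!isTRUE(attr(S, "psd"))) return(-Inf)
  total <- 0
  M12 <- cbind(m1, m2)
  for (g in groups) {
    S <- sigma_by[[g$zk]]
    iy <- g$iy; il <- g$il
    ny <- length(iy); nl <- length(il)
    ll <- 0
    if (ny > 0L) {
      Syy <- S[iy, iy, drop = FALSE]
      R <- g$Y - M12[g$idx, iy, drop = FALSE]
      if (ny == 1L) {
        if (Syy[1, 1] <= 0) return(-Inf)
        ll <- ll + dnorm(R[, 1], 0, sqrt(Syy[1, 1]), log = TRUE)
      } else {
        dt <- Syy[1, 1] * Syy[2, 2] - Syy[1, 2]^2
        if (dt <= 0 || Syy[1, 1] <= 0) return(-Inf)
        q <- (Syy[2, 2] * R[, 1]^2 - 2 * Syy[1, 2] * R[, 1] * R[, 2] +
                Syy[1, 1] * R[, 2]^2) / dt
        ll <- ll - 0.5 * (q + log(dt) + 2 * log(2 * pi))
      }
    }
    if (nl > 0L) {
      Sll <- S[il, il, drop = FALSE]
      if (ny > 0L) {
        Sly <- S[il, iy, drop = FALSE]
        W <- Sly %*% solve(S[iy, iy, drop = FALSE])
        cm <- R %*% t(W)                  # conditional means, n x nl
        Sc <- Sll - W %*% t(Sly)
      } else {
        cm <- matrix(0, length(g$idx), nl)
        Sc <- Sll
      }
      vdiag <- if (nl == 1L) Sc[1, 1] else c(Sc[1, 1], Sc[2, 2])
      if (any(vdiag <= 0)) return(-Inf)
      if (nl == 1L) {
        z <- (tau - cm[, 1]) / sqrt(vdiag)
        p <- pnorm(z)
        d <- g$D[, 1]
        pr <- (1 - d) * p + d * (1 - p)
      } else {
        rho <- Sc[1, 2] / sqrt(vdiag[1] * vdiag[2])
        if (abs(rho) > 1) return(-Inf)
        z1 <- (tau - cm[, 1]) / sqrt(vdiag[1])
        z2 <- (tau - cm[, 2]) / sqrt(vdiag[2])
        p00 <- pbvn(z1, z2, rho)
        p1 <- pnorm(z1); p2 <- pnorm(z2)
        d1 <- g$D[, 1]; d2 <- g$D[, 2]
        pr <- (1 - d1) * (1 - d2) * p00 +
          d1 * (1 - d2) * (p2 - p00) +
          (1 - d1) * d2 * (p1 - p00) +
          d1 * d2 * (1 - p1 - p2 + p00)
      }
      ll <- ll + log(pmax(pr, 1e-320))
    }
    total <- total + sum(ll)
  }
  total
}

# pt: pair_table rows; sigma_by: list(MZ=4x4, DZ=4x4) (SIB uses DZ);
# m1,m2: mean vectors per pair (NA allowed where member absent); tau: scalar.
# Returns total loglik, or -Inf for an invalid parameter point.
fiml_loglik <- function(pt, sigma_by, tau, m1, m2) {
  if (nrow(pt) == 0L) stop("empty dataset")
  .fiml_ll(.fiml_groups(pt), sigma_by, tau, m1, m2)
}

# helper: member mean vectors for a pair table given mu/beta and design X
pair_means <- function(pt, X, mu, beta) {
  lin <- if (length(beta)) as.numeric(X %*% beta) else rep(0, nrow(X))
  m1 <- ifelse(is.na(pt$i1), NA_real_, mu + lin[pt$i1])
  m2 <- ifelse(is.na(pt$i2), NA_real_, mu + lin[pt$i2])
  list(m1 = m1, m2 = m2)
}

#' Joint log-likelihood of one twin/sibling pair
#'
#' Full-information likelihood of the observed cognitive sub-vector and the
#' observed affection pattern: the continuous part is the (1- or 2-variate)
#' normal density, and the binary part is the orthant probability of the
#' conditional normal distribution of the liabilities given the observed
#' cognition. Missing elements are marginalized by dropping their rows and
#' columns.
#'
#' @param y length-2 numeric of cognitive scores (`NA` = missing/absent).
#' @param d length-2 vector of 0/1 affection flags (`NA` = missing/absent).
#' @param zygosity `"MZ"`, `"DZ"` or `"SIB"`.
#' @param params an [ace_params].
#' @param disease a [disease_model].
#' @param x1,x2 optional covariate rows for members 1 and 2 (vectors matching
#'   `params$beta`).
#' @return scalar log-likelihood (`-Inf` signals an invalid parameter point).
#' @export
pair_loglik <- function(y, d, zygosity, params, disease,
                        x1 = NULL, x2 = NULL) {
  stopifnot(length(y) == 2, length(d) == 2)
  if (all(is.na(y)) && all(is.na(d)))
    stop("pair with no observed data")
  RA <- kinship_coefficient(zygosity)
  S <- expected_pair_covariance(params, disease, RA)
  zk <- if (toupper(zygosity) == "MZ") "MZ" else "DZ"
  pt <- data.frame(pair_id = 1, zyg = zk, y1 = y[1], y2 = y[2],
                   d1 = d[1], d2 = d[2], i1 = 1L, i2 = 2L)
  off1 <- if (length(params$beta) && !is.null(x1))
    sum(params$beta * x1) else 0
  off2 <- if (length(params$beta) && !is.null(x2))
    sum(params$beta * x2) else 0
  fiml_loglik(pt, list(MZ = S, DZ = S), disease$tau,
              params$mu + off1, params$mu + off2)
}
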