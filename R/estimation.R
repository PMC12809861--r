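# Maximum-likelihood machinery for the bivariate ACE liability model.
#
# Internal parameterization (all free parameters unconstrained):
#   lv            log total cognitive variance
#   t_h2, t_c2    stick-breaking logits: h2 = (1-ef)*plogis(t_h2),
#                 c2 = (1-ef-h2)*plogis(t_c2), e2 the remainder (>= ef)
#   z_rg, z_rc, z_re   tanh maps for the factor correlations
#   mu, beta      mean structure
# Any structural quantity (h2, c2, rg, rc, re, rph_a) can be pinned via a
# fix list, which is also how profile likelihoods are computed. Fixing
# rph_a derives rg = rph_a / sqrt(h2 * h2_d) at the current h2, so the
# profile respects the correlation bound automatically.

.e_floor <- 1e-3

# evaluate expr with a local RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.free_names <- function(fix, disease, p) {
  nm <- "lv"
  if (is.null(fix$h2)) nm <- c(nm, "t_h2")
  if (is.null(fix$c2)) nm <- c(nm, "t_c2")
  if (is.null(fix$rg) && is.null(fix$rph_a)) nm <- c(nm, "z_rg")
  if (is.null(fix$rc)) nm <- c(nm, "z_rc")
  if (is.null(fix$re)) nm <- c(nm, "z_re")
  if (isTRUE(fix$free_h2d)) nm <- c(nm, "t_h2d")
  nm <- c(nm, "mu")
  if (p > 0) nm <- c(nm, paste0("beta", seq_len(p)))
  nm
}

.structural <- function(theta, fix, disease, p) {
  ef <- .e_floor
  g <- function(nm) theta[[nm]]
  if (isTRUE(fix$free_h2d)) {
    # "naive" variant: disease-side h2 estimated rather than fixed
    # (used to demonstrate ascertainment bias); prevalence stays fixed
    h2d <- (1 - disease$c2 - 0.01) * stats::plogis(g("t_h2d"))
    disease <- disease_model(h2d, disease$c2, 1 - h2d - disease$c2,
                             disease$prevalence,
                             name = paste0(disease$name, "_free_h2d"))
  }
  v <- exp(g("lv"))
  h2 <- if (!is.null(fix$h2)) fix$h2 else (1 - ef) * stats::plogis(g("t_h2"))
  c2max <- 1 - ef - h2
  if (c2max < 0) return(list(valid = FALSE))
  c2 <- if (!is.null(fix$c2)) fix$c2 else c2max * stats::plogis(g("t_c2"))
  e2 <- 1 - h2 - c2
  if (e2 < ef / 2) return(list(valid = FALSE))
  if (!is.null(fix$rph_a)) {
    den <- sqrt(h2 * disease$h2)
    if (den < 1e-8) return(list(valid = FALSE))
    rg <- fix$rph_a / den
    if (abs(rg) > 1) return(list(valid = FALSE))
  } else rg <- if (!is.null(fix$rg)) fix$rg else tanh(g("z_rg"))
  rc <- if (!is.null(fix$rc)) fix$rc else tanh(g("z_rc"))
  re <- if (!is.null(fix$re)) fix$re else tanh(g("z_re"))
  beta <- if (p > 0) unlist(theta[paste0("beta", seq_len(p))],
                            use.names = FALSE) else numeric(0)
  list(valid = TRUE, v = v, h2 = h2, c2 = c2, e2 = e2,
       rg = rg, rc = rc, re = re, mu = g("mu"), beta = beta,
       disease = disease)
}

.theta_from <- function(est, fix, p) {
  ef <- .e_floor
  clamp <- function(x) pmin(8, pmax(-8, x))
  th <- list(lv = log(max(est$v, 1e-8)))
  if (is.null(fix$h2))
    th$t_h2 <- clamp(stats::qlogis(min(max(est$h2 / (1 - ef), 1e-4), 1 - 1e-4)))
  if (is.null(fix$c2)) {
    c2max <- 1 - ef - est$h2
    frac <- if (c2max > 0) est$c2 / c2max else 0.5
    th$t_c2 <- clamp(stats::qlogis(min(max(frac, 1e-4), 1 - 1e-4)))
  }
  if (is.null(fix$rg) && is.null(fix$rph_a))
    th$z_rg <- atanh(min(max(est$rg, -0.999), 0.999))
  if (is.null(fix$rc)) th$z_rc <- atanh(min(max(est$rc, -0.999), 0.999))
  if (is.null(fix$re)) th$z_re <- atanh(min(max(est$re, -0.999), 0.999))
  th$mu <- est$mu
  if (isTRUE(fix$free_h2d))
    th$t_h2d <- clamp(stats::qlogis(min(max((est$h2_d %||% 0.8) / 0.99,
                                            1e-4), 1 - 1e-4)))
  if (p > 0) for (j in seq_len(p)) th[[paste0("beta", j)]] <- est$beta[j]
  th
}

.ace_objective <- function(pt, X, fix, disease, p) {
  nm <- .free_names(fix, disease, p)
  groups <- .fiml_groups(pt)
  function(par) {
    th <- as.list(par); names(th) <- nm
    s <- .structural(th, fix, disease, p)
    if (!s$valid) return(1e10)
    pr <- ace_params(a = sqrt(s$v * s$h2), c = sqrt(s$v * s$c2),
                     e = sqrt(s$v * s$e2), rg = s$rg, rc = s$rc, re = s$re,
                     mu = s$mu, beta = s$beta)
    sig <- list(MZ = expected_pair_covariance(pr, s$disease, 1.0),
                DZ = expected_pair_covariance(pr, s$disease, 0.5))
    m <- pair_means(pt, X, s$mu, s$beta)
    ll <- .fiml_ll(groups, sig, s$disease$tau, m$m1, m$m2)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

.num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    (f(xp) - f(xm)) / (2 * hj)
  }, numeric(1))
}

# moment-based starting values
.moment_start <- function(pt, X, ds_rows, y_all) {
  v0 <- stats::var(y_all, na.rm = TRUE)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1
  icc <- function(rows) {
    cc <- rows[!is.na(rows$y1) & !is.na(rows$y2), c("y1", "y2")]
    if (nrow(cc) < 3) return(NA_real_)
    stats::cor(c(cc$y1, cc$y2), c(cc$y2, cc$y1))
  }
  rmz <- icc(pt[pt$zyg == "MZ", ]); rdz <- icc(pt[pt$zyg != "MZ", ])
  if (is.na(rmz)) rmz <- 0.5
  if (is.na(rdz)) rdz <- 0.25
  h2 <- min(max(2 * (rmz - rdz), 0.05), 0.9)
  c2 <- min(max(2 * rdz - rmz, 0.01), 0.9 - h2)
  list(v = v0, h2 = h2, c2 = c2, rg = 0, rc = 0, re = 0,
       mu = mean(y_all, na.rm = TRUE), beta = rep(0, ncol(X)))
}

#' Fit the bivariate ACE liability-threshold model
#'
#' Maximizes the summed pair log-likelihood of one cognitive measure jointly
#' with one binary diagnostic phenotype, with the disease side fixed at the
#' supplied [disease_model] (ascertainment correction). Multiple jittered
#' starts guard against local optima; the best converged solution is kept.
#'
#' @param ds a [twin_data] object.
#' @param measure cognitive measure column name.
#' @param phenotype phenotype name (an `affected_<phenotype>` column).
#' @param disease a [disease_model] (or profile name, see [disease_profile()]).
#' @param covariates logical: regress the cognitive mean on the encoded
#'   covariates ([encode_covariates()])?
#' @param fix named list of structural constraints, e.g. `list(rg = 0)`;
#'   recognised names: `h2`, `c2`, `rg`, `rc`, `re`, `rph_a`. When the
#'   disease profile has `c2 = 0`, `rc` is structurally unidentified and is
#'   fixed at 0 automatically.
#' @param n_starts number of optimizer starts (first from data moments, the
#'   rest jittered deterministically from `seed`).
#' @param seed integer seed for the jittered starts.
#' @param start optional structural list overriding the moment start.
#' @param free_disease_h2 estimate the disease-side h2 instead of fixing it
#'   (the "naive" analysis; on proband-selected samples this inflates the
#'   disease h2, which is why the default analysis keeps it fixed).
#' @return an `ace_fit` object: standardized `estimates` (`h2`, `c2`, `e2`,
#'   `rg`, `rc`, `re`, `v`, `mu`, `beta`), `loglik`, `convergence` (status and
#'   gradient norm), `n_pairs_used`, and the ingredients needed to profile.
#' @export
fit_bivariate_ace <- function(ds, measure, phenotype, disease,
                              covariates = TRUE, fix = list(),
                              n_starts = 5, seed = 1, start = NULL,
                              free_disease_h2 = FALSE) {
  stopifnot(inherits(ds, "twin_data"))
  if (is.character(disease)) disease <- disease_profile(disease)
  if (isTRUE(free_disease_h2)) fix$free_h2d <- TRUE
  pt <- pair_table(ds, measure, phenotype)
  if (nrow(pt) == 0L) stop("empty dataset")
  for (z in c("MZ", "DZ")) {
    zr <- if (z == "MZ") pt$zyg == "MZ" else pt$zyg != "MZ"
    if (!any(zr & !is.na(pt$y1) & !is.na(pt$y2)))
      warning("no complete ", z, " pairs with observed '", measure, "'")
  }
  if (disease$c2 == 0 && is.null(fix$rc)) fix$rc <- 0
  X <- if (isTRUE(covariates)) encode_covariates(ds) else
    matrix(numeric(0), nrow = nrow(ds$data), ncol = 0)
  p <- ncol(X)
  y_all <- ds$data[[measure]]
  if (p > 0 && is.null(start)) {
    # initialize beta by OLS on observed rows
    ok <- !is.na(y_all) & stats::complete.cases(X)
    b0 <- tryCatch(stats::coef(stats::lm(y_all[ok] ~ X[ok, , drop = FALSE])),
                   error = function(e) rep(0, p + 1))
    beta0 <- unname(b0[-1]); beta0[is.na(beta0)] <- 0
  } else beta0 <- rep(0, p)
  s0 <- start %||% .moment_start(pt, X, ds$data, y_all)
  if (is.null(start)) s0$beta <- beta0
  obj <- .ace_objective(pt, X, fix, disease, p)
  nm <- .free_names(fix, disease, p)
  th0 <- unlist(.theta_from(s0, fix, p)[nm])
  jitters <- .with_seed(seed,
    lapply(seq_len(n_starts), function(k)
      if (k == 1) rep(0, length(th0))
      else stats::rnorm(length(th0), 0, 0.4)))
  best <- NULL
  for (k in seq_len(n_starts)) {
    thk <- th0 + jitters[[k]]
    opt <- tryCatch(
      stats::nlminb(thk, obj,
                    control = list(iter.max = 600, eval.max = 2500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("optimization failed for all starts")
  gr <- .num_grad(obj, best$par)
  th <- as.list(best$par); names(th) <- nm
  s <- .structural(th, fix, disease, p)
  est <- list(h2 = s$h2, c2 = s$c2, e2 = s$e2,
              rg = s$rg, rc = s$rc, re = s$re,
              v = s$v, mu = s$mu, beta = s$beta,
              h2_d = s$disease$h2)
  structure(list(
    estimates = est,
    loglik = -best$objective,
    convergence = list(code = best$convergence,
                       message = best$message,
                       grad_norm = sqrt(sum(gr^2)),
                       converged = best$convergence == 0 ||
                         sqrt(sum(gr^2)) < 1e-3),
    n_pairs_used = nrow(pt),
    n_free = length(nm),
    measure = measure, phenotype = phenotype,
    disease = disease, fix = fix,
    pt = pt, X = X, theta = best$par, free_names = nm
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<ace_fit> %s x %s (disease profile '%s')\n",
              x$measure, x$phenotype, x$disease$name))
  cat(sprintf("  h2=%.3f c2=%.3f e2=%.3f   rg=%.3f rc=%.3f re=%.3f\n",
              e$h2, e$c2, e$e2, e$rg, e$rc, e$re))
  cat(sprintf("  loglik=%.3f  pairs=%d  grad|=%.2e  converged=%s\n",
              x$loglik, x$n_pairs_used, x$convergence$grad_norm,
              x$convergence$converged))
  invisible(x)
}

# refit with an additional structural fix; optimized from each start in
# `from` (profile searches pass the warm previous solution plus the MLE,
# which keeps the profile log-likelihood from being under-maximized)
.refit_fixed <- function(fit, param, value, from = NULL) {
  fix <- fit$fix
  if (param == "rph_a") fix$rg <- NULL
  fix[[param]] <- value
  p <- ncol(fit$X)
  obj <- .ace_objective(fit$pt, fit$X, fix, fit$disease, p)
  nm <- .free_names(fix, fit$disease, p)
  starts <- from %||% list(fit$estimates)
  if (!is.null(starts$h2)) starts <- list(starts)
  best <- NULL
  for (est in starts) {
    th0 <- unlist(.theta_from(est, fix, p)[nm])
    opt <- tryCatch(
      stats::nlminb(th0, obj,
                    control = list(iter.max = 400, eval.max = 1500,
                                   rel.tol = 1e-7)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) return(list(loglik = -Inf,
                                 structural = list(valid = FALSE)))
  th <- as.list(best$par); names(th) <- nm
  s <- .structural(th, fix, fit$disease, p)
  list(loglik = -best$objective, structural = s)
}

# generic one-sided profile endpoint search (shared with the correlation
# model): prof(value) returns the profile deviance 2*(llmax - llprof)
.profile_endpoint <- function(prof, hat, bound, crit, init_step) {
  dirn <- sign(bound - hat)
  if (dirn == 0) return(list(value = hat, boundary = TRUE))
  step <- init_step
  cur <- hat
  dev_cur <- 0
  repeat {
    nxt <- cur + dirn * step
    at_bound <- FALSE
    if ((dirn > 0 && nxt >= bound) || (dirn < 0 && nxt <= bound)) {
      nxt <- bound
      at_bound <- TRUE
    }
    dev_nxt <- prof(nxt)
    if (is.finite(dev_nxt) && dev_nxt > crit) {
      f <- function(v) prof(v) - crit
      lo_pt <- min(cur, nxt); hi_pt <- max(cur, nxt)
      f_lo <- if (lo_pt == cur) dev_cur - crit else dev_nxt - crit
      f_hi <- if (hi_pt == cur) dev_cur - crit else dev_nxt - crit
      r <- tryCatch(
        stats::uniroot(f, lower = lo_pt, upper = hi_pt,
                       f.lower = f_lo, f.upper = f_hi,
                       tol = max(1e-4, abs(bound - hat) * 1e-3)),
        error = function(e) NULL)
      return(list(value = if (is.null(r)) nxt else r$root,
                  boundary = FALSE))
    }
    if (at_bound || !is.finite(dev_nxt))
      return(list(value = bound, boundary = TRUE))
    cur <- nxt; dev_cur <- dev_nxt
    step <- step * 1.7
  }
}

#' Profile-likelihood confidence interval
#'
#' Endpoints are the parameter values at which twice the drop from the
#' maximized log-likelihood equals the chi-square(1) quantile for `level`
#' (3.841 at 95%). When the profile never crosses before a parameter bound,
#' the bound is returned and flagged — the analogue of printed intervals
#' with `NA`/boundary endpoints.
#'
#' @param fit an `ace_fit` from [fit_bivariate_ace()].
#' @param param one of `"h2"`, `"c2"`, `"rg"`, `"rc"`, `"re"`, `"rph_a"`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` with attribute `boundary` (logical length 2).
#' @export
profile_ci <- function(fit, param, level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  valid <- c("h2", "c2", "rg", "rc", "re", "rph_a")
  if (!param %in% valid)
    stop("param must be one of: ", paste(valid, collapse = ", "))
  if (!is.null(fit$fix[[param]]))
    return(structure(rep(fit$fix[[param]], 2),
                     boundary = c(TRUE, TRUE), fixed = TRUE))
  e <- fit$estimates
  hat <- switch(param, rph_a = e$rg * sqrt(e$h2 * fit$disease$h2),
                e[[param]])
  bounds <- switch(param,
    h2 = c(0, 1 - .e_floor - e$c2 * 0),  # c2 refits freely
    c2 = c(0, 1 - .e_floor),
    rg = c(-1, 1), rc = c(-1, 1), re = c(-1, 1),
    rph_a = sqrt((1 - .e_floor) * fit$disease$h2) * c(-1, 1))
  if (param == "h2") bounds <- c(0, 1 - .e_floor)
  crit <- stats::qchisq(level, 1)
  llmax <- fit$loglik
  warm <- new.env()
  warm$est <- fit$estimates
  prof <- function(v) {
    r <- tryCatch(
      .refit_fixed(fit, param, v,
                   from = list(warm$est, fit$estimates)),
      error = function(e) NULL)
    if (is.null(r) || !is.finite(r$loglik)) return(Inf)
    if (isTRUE(r$structural$valid)) warm$est <- r$structural
    2 * (llmax - r$loglik)
  }
  init <- max(0.02, diff(bounds) / 60)
  lo <- .profile_endpoint(prof, hat, bounds[1], crit, init)
  warm$est <- fit$estimates
  hi <- .profile_endpoint(prof, hat, bounds[2], crit, init)
  structure(c(lo$value, hi$value),
            boundary = c(lo$boundary, hi$boundary), fixed = FALSE)
}

#' Likelihood-ratio test of a nested sub-model
#'
#' @param full,nested `ace_fit` objects (or any lists with a `loglik` field);
#'   `nested` must be a restriction of `full`.
#' @param df number of restricted parameters.
#' @return list with `statistic` (clipped at 0), `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, nested, df) {
  if (df <= 0) stop("df must be >= 1")
  if (nested$loglik > full$loglik + 1e-6)
    stop("nested log-likelihood exceeds the full model's")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Sub-model significance battery
#'
#' Refits the model with each of `rg = 0`, `rph_a = 0` and `h2 = 0` (one
#' restriction at a time, 1 df each) and reports the likelihood-ratio tests —
#' the LRT counterparts of endophenotype criteria 2-4.
#'
#' @param fit an `ace_fit`.
#' @return data frame with one row per restriction.
#' @export
ace_submodel_tests <- function(fit) {
  rows <- lapply(c("rg", "rph_a", "h2"), function(pm) {
    if (!is.null(fit$fix[[pm]])) return(NULL)
    r <- .refit_fixed(fit, pm, 0)
    lrt <- likelihood_ratio_test(fit, r, df = 1)
    data.frame(restriction = paste0(pm, "=0"), statistic = lrt$statistic,
               df = 1, p = lrt$p)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
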