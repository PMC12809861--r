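# Constrained saturated correlation model.
#
# The 4-variate normal over (y1, y2, l1, l2) is parameterized directly by
# correlations: one within-twin cross-trait correlation shared across
# zygosity and birth order, zygosity-specific cross-twin cross-trait and
# cross-twin within-cognition correlations, and the liability cross-twin
# correlations fixed at the disease profile's h2+c2 (MZ) and h2/2+c2 (DZ) —
# the same fixed-parameter ascertainment correction as the ACE model.

.corr_free <- function(p)
  c("mu", "lv", "z_wtct", "z_ctct_mz", "z_ctct_dz",
    "z_ctwt_mz", "z_ctwt_dz",
    if (p > 0) paste0("beta", seq_len(p)))

.corr_structural <- function(theta, fix, p) {
  g <- function(nm) theta[[nm]]
  r <- function(nm, fx) if (!is.null(fx)) fx else tanh(g(nm))
  list(mu = g("mu"), v = exp(g("lv")),
       r_wtct = r("z_wtct", fix$r_wtct),
       r_ctct_mz = r("z_ctct_mz", fix$r_ctct_mz),
       r_ctct_dz = r("z_ctct_dz", fix$r_ctct_dz),
       r_ctwt_mz = r("z_ctwt_mz", fix$r_ctwt_mz),
       r_ctwt_dz = r("z_ctwt_dz", fix$r_ctwt_dz),
       beta = if (p > 0) unlist(theta[paste0("beta", seq_len(p))],
                                use.names = FALSE) else numeric(0))
}

.corr_sigma <- function(s, zyg, fixed_ll) {
  v <- s$v; sv <- sqrt(v)
  ctwt <- if (zyg == "MZ") s$r_ctwt_mz else s$r_ctwt_dz
  ctct <- if (zyg == "MZ") s$r_ctct_mz else s$r_ctct_dz
  S <- matrix(c(
    v,            v * ctwt,     sv * s$r_wtct, sv * ctct,
    v * ctwt,     v,            sv * ctct,     sv * s$r_wtct,
    sv * s$r_wtct, sv * ctct,   1,             fixed_ll,
    sv * ctct,    sv * s$r_wtct, fixed_ll,     1), 4, 4)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  attr(S, "psd") <- min(ev) > 1e-10
  S
}

#' Fit the constrained correlation model
#'
#' Maximum-likelihood correlations of the joint (cognition pair, liability
#' pair) normal under the study's equality constraints: a single within-twin
#' cross-trait correlation `r_wtct` for all participants, zygosity-specific
#' cross-twin cross-trait (`r_ctct`) and cross-twin within-cognition
#' (`r_ctwt`) correlations, and the liability cross-twin correlations fixed
#' at `h2_d + c2_d` (MZ) and `h2_d/2 + c2_d` (DZ/sibling). `r_wtct` is the
#' phenotypic-overlap gate of endophenotype criterion 1.
#'
#' @inheritParams fit_bivariate_ace
#' @param ci character vector of correlation names to compute 95% profile
#'   CIs for (any of `r_wtct`, `r_ctct_mz`, `r_ctct_dz`, `r_ctwt_mz`,
#'   `r_ctwt_dz`); default just the criterion-1 gate.
#' @param level confidence level for the intervals.
#' @return a `correlation_set`: estimates, fixed disease values, CIs,
#'   log-likelihood, convergence info.
#' @export
fit_constrained_correlations <- function(ds, measure, phenotype, disease,
                                         covariates = TRUE,
                                         ci = "r_wtct", level = 0.95,
                                         n_starts = 3, seed = 1) {
  stopifnot(inherits(ds, "twin_data"))
  if (is.character(disease)) disease <- disease_profile(disease)
  pt <- pair_table(ds, measure, phenotype)
  if (nrow(pt) == 0L) stop("empty dataset")
  X <- if (isTRUE(covariates)) encode_covariates(ds) else
    matrix(numeric(0), nrow = nrow(ds$data), ncol = 0)
  p <- ncol(X)
  fixed_mz <- disease$h2 + disease$c2
  fixed_dz <- 0.5 * disease$h2 + disease$c2
  groups <- .fiml_groups(pt)
  obj_fix <- function(fix) {
    function(par) {
      th <- as.list(par); names(th) <- setdiff(.corr_free(p), .fixed_z(fix))
      s <- .corr_structural(th, fix, p)
      smz <- .corr_sigma(s, "MZ", fixed_mz)
      sdz <- .corr_sigma(s, "DZ", fixed_dz)
      if (!attr(smz, "psd") || !attr(sdz, "psd")) return(1e10)
      m <- pair_means(pt, X, s$mu, s$beta)
      ll <- .fiml_ll(groups, list(MZ = smz, DZ = sdz), disease$tau,
                     m$m1, m$m2)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  y_all <- ds$data[[measure]]
  start <- c(mu = mean(y_all, na.rm = TRUE),
             lv = log(max(stats::var(y_all, na.rm = TRUE), 1e-8)),
             z_wtct = 0, z_ctct_mz = 0, z_ctct_dz = 0,
             z_ctwt_mz = atanh(0.4), z_ctwt_dz = atanh(0.2))
  if (p > 0) {
    ok <- !is.na(y_all) & stats::complete.cases(X)
    b0 <- tryCatch(stats::coef(stats::lm(y_all[ok] ~ X[ok, , drop = FALSE])),
                   error = function(e) rep(0, p + 1))
    bb <- unname(b0[-1]); bb[is.na(bb)] <- 0
    start <- c(start, setNames(bb, paste0("beta", seq_len(p))))
  }
  obj <- obj_fix(list())
  jitters <- .with_seed(seed,
    lapply(seq_len(n_starts), function(k)
      if (k == 1) rep(0, length(start))
      else stats::rnorm(length(start), 0, 0.3)))
  best <- NULL
  for (k in seq_len(n_starts)) {
    opt <- tryCatch(
      stats::nlminb(start + jitters[[k]], obj,
                    control = list(iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("optimization failed for all starts")
  th <- as.list(best$par); names(th) <- .corr_free(p)
  s <- .corr_structural(th, list(), p)
  llmax <- -best$objective
  est <- s[c("r_wtct", "r_ctct_mz", "r_ctct_dz", "r_ctwt_mz", "r_ctwt_dz")]
  cis <- list()
  crit <- stats::qchisq(level, 1)
  for (pm in intersect(ci, names(est))) {
    prof <- function(v) {
      fx <- setNames(list(v), pm)
      o2 <- obj_fix(fx)
      st2 <- best$par[setdiff(.corr_free(p), .fixed_z(fx))]
      opt2 <- tryCatch(
        stats::nlminb(st2, o2,
                      control = list(iter.max = 300, eval.max = 1200)),
        error = function(e) NULL)
      if (is.null(opt2) || !is.finite(opt2$objective)) return(Inf)
      2 * (llmax + opt2$objective)
    }
    lo <- .profile_endpoint(prof, est[[pm]], -1, crit, 0.03)
    hi <- .profile_endpoint(prof, est[[pm]],  1, crit, 0.03)
    cis[[pm]] <- structure(c(lo$value, hi$value),
                           boundary = c(lo$boundary, hi$boundary))
  }
  structure(list(
    estimates = est, ci = cis,
    mu = s$mu, v = s$v, beta = s$beta,
    fixed_disease_mz = fixed_mz, fixed_disease_dz = fixed_dz,
    loglik = llmax, level = level,
    convergence = list(code = best$convergence, message = best$message),
    n_pairs_used = nrow(pt), measure = measure, phenotype = phenotype,
    disease = disease
  ), class = "correlation_set")
}

.fixed_z <- function(fix) {
  map <- c(r_wtct = "z_wtct", r_ctct_mz = "z_ctct_mz",
           r_ctct_dz = "z_ctct_dz", r_ctwt_mz = "z_ctwt_mz",
           r_ctwt_dz = "z_ctwt_dz")
  unname(map[names(fix)])
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("<correlation_set> %s x %s (profile '%s')\n",
              x$measure, x$phenotype, x$disease$name))
  e <- x$estimates
  cat(sprintf("  r_wtct=%.3f  ctct MZ/DZ=%.3f/%.3f  ctwt MZ/DZ=%.3f/%.3f\n",
              e$r_wtct, e$r_ctct_mz, e$r_ctct_dz, e$r_ctwt_mz, e$r_ctwt_dz))
  cat(sprintf("  fixed liability cross-twin: MZ=%.3f DZ=%.3f\n",
              x$fixed_disease_mz, x$fixed_disease_dz))
  if (!is.null(x$ci$r_wtct))
    cat(sprintf("  r_wtct %.0f%% CI: (%.3f, %.3f)\n", 100 * x$level,
                x$ci$r_wtct[1], x$ci$r_wtct[2]))
  invisible(x)
}
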