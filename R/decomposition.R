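#' Decompose a phenotypic correlation into A/C/E parts
#'
#' The phenotypic correlation between a standardized cognitive trait and the
#' disease liability splits as
#' `rph = rg*sqrt(h2_x*h2_d) + rc*sqrt(c2_x*c2_d) + re*sqrt(e2_x*e2_d)`,
#' the three terms being the additive-genetic (`rph_a`), shared-environment
#' (`rph_c`) and unique-environment (`rph_e`) contributions.
#'
#' @param rg,rc,re factor correlations in `[-1, 1]`.
#' @param h2_x,c2_x,e2_x standardized variance components of the cognitive
#'   trait (must sum to 1).
#' @param h2_d,c2_d,e2_d variance components of the disease liability (must
#'   sum to 1); pass a [disease_model]'s fields or use [decompose_fit()].
#' @return an `rph_decomposition` with fields `rph_a`, `rph_c`, `rph_e`,
#'   `rph`.
#' @export
#' @examples
#' decompose_rph(rg = 0.42, rc = 0, re = 0.21,
#'               h2_x = 0.30, c2_x = 0.22, e2_x = 0.48,
#'               h2_d = 0.90, c2_d = 0, e2_d = 0.10)
decompose_rph <- function(rg, rc, re, h2_x, c2_x, e2_x, h2_d, c2_d, e2_d) {
  comp <- c(h2_x, c2_x, e2_x, h2_d, c2_d, e2_d)
  if (any(comp < 0)) stop("variance proportions must be non-negative")
  if (abs(h2_x + c2_x + e2_x - 1) > 1e-8 ||
      abs(h2_d + c2_d + e2_d - 1) > 1e-8)
    stop("variance proportions must each sum to 1")
  for (r in c(rg, rc, re))
    if (abs(r) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  rph_a <- rg * sqrt(h2_x * h2_d)
  rph_c <- rc * sqrt(c2_x * c2_d)
  rph_e <- re * sqrt(e2_x * e2_d)
  structure(list(rph_a = rph_a, rph_c = rph_c, rph_e = rph_e,
                 rph = rph_a + rph_c + rph_e),
            class = "rph_decomposition")
}

#' @export
print.rph_decomposition <- function(x, ...) {
  cat(sprintf("<rph_decomposition> rph=%.3f = a:%.3f + c:%.3f + e:%.3f\n",
              x$rph, x$rph_a, x$rph_c, x$rph_e))
  invisible(x)
}

#' @describeIn decompose_rph decompose directly from an `ace_fit`.
#' @param fit an `ace_fit` from [fit_bivariate_ace()].
#' @export
decompose_fit <- function(fit) {
  e <- fit$estimates; d <- fit$disease
  decompose_rph(e$rg, e$rc, e$re, e$h2, e$c2, e$e2, d$h2, d$c2, d$e2)
}

#' Shared heritability implied by a genetic correlation
#'
#' The square of the genetic correlation is the proportion of one trait's
#' heritable variation shared with the other ("genetic sharing").
#'
#' @param rg genetic correlation in `[-1, 1]`.
#' @param rounded round to the nearest whole percent (reporting convention)?
#' @return percentage, `100 * rg^2`.
#' @export
#' @examples
#' genetic_sharing(0.36) # 13
genetic_sharing <- function(rg, rounded = TRUE) {
  if (any(abs(rg) > 1)) stop("rg must lie in [-1, 1]")
  out <- 100 * rg^2
  if (rounded) round(out) else out
}

# reporting convention: two decimals, halves away from zero
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.ci_excludes_zero <- function(ci) {
  if (is.null(ci) || any(is.na(ci))) return(NA)
  # an endpoint pinned at a parameter bound means the profile never crossed
  # there; the interval still counts, significance needs 0 strictly outside
  ci[1] > 0 || ci[2] < 0
}

#' Four-criterion endophenotype decision rule
#'
#' A measure is validated as an endophenotype for a diagnostic phenotype
#' when all of the following hold, each judged by a 95% CI excluding zero:
#' (1) a significant within-twin/sibling cross-trait (phenotypic)
#' correlation — failing this gate excludes the measure from the genetic
#' stage; (2) a significant heritability whose point estimate exceeds 10%;
#' (3) a significant genetic correlation `rg`; (4) a significant
#' additive-genetic contribution `rph_a`.
#'
#' @param r_wtct_ci CI of the within-twin cross-trait correlation.
#' @param h2 point estimate of the cognitive heritability.
#' @param h2_ci CI of `h2`.
#' @param rg_ci CI of `rg`.
#' @param rph_a_ci CI of `rph_a`.
#' @return an `endophenotype_criteria` object with logical (or `NA` =
#'   indeterminate/not-evaluated) fields `c1_phenotypic`, `c2_heritability`,
#'   `c3_rg`, `c4_rph_a` and `is_endophenotype`.
#' @export
endophenotype_criteria <- function(r_wtct_ci, h2, h2_ci, rg_ci, rph_a_ci) {
  c1 <- .ci_excludes_zero(r_wtct_ci)
  if (!isTRUE(c1)) {
    # gate: measure excluded from the genetic stage
    return(structure(list(c1_phenotypic = c1,
                          c2_heritability = NA, c3_rg = NA, c4_rph_a = NA,
                          is_endophenotype = FALSE,
                          gated = TRUE),
                     class = "endophenotype_criteria"))
  }
  h2_sig <- .ci_excludes_zero(h2_ci)
  c2 <- if (is.na(h2_sig)) NA else h2_sig && !is.na(h2) && h2 > 0.10
  c3 <- .ci_excludes_zero(rg_ci)
  c4 <- .ci_excludes_zero(rph_a_ci)
  all4 <- isTRUE(c1) && isTRUE(c2) && isTRUE(c3) && isTRUE(c4)
  structure(list(c1_phenotypic = c1, c2_heritability = c2,
                 c3_rg = c3, c4_rph_a = c4,
                 is_endophenotype = all4, gated = FALSE),
            class = "endophenotype_criteria")
}

#' @export
print.endophenotype_criteria <- function(x, ...) {
  fl <- function(v) if (is.na(v)) "?" else if (v) "pass" else "fail"
  cat("<endophenotype_criteria>",
      if (x$gated) "(excluded at the phenotypic gate)\n" else "\n")
  cat(sprintf("  c1 phenotypic: %s | c2 h2: %s | c3 rg: %s | c4 rph_a: %s\n",
              fl(x$c1_phenotypic), fl(x$c2_heritability), fl(x$c3_rg),
              fl(x$c4_rph_a)))
  cat("  endophenotype:", x$is_endophenotype, "\n")
  invisible(x)
}

#' Evaluate the endophenotype criteria from fitted objects
#'
#' Combines a [fit_constrained_correlations()] result (criterion 1), an
#' [fit_bivariate_ace()] result and its profile CIs (criteria 2-4).
#' CIs not already attached are computed here.
#'
#' @param corr a `correlation_set` for the same measure and phenotype.
#' @param fit an `ace_fit`.
#' @param h2_ci,rg_ci,rph_a_ci optional precomputed profile CIs; computed
#'   via [profile_ci()] when `NULL`.
#' @return an `endophenotype_criteria` object.
#' @export
evaluate_endophenotype <- function(corr, fit, h2_ci = NULL, rg_ci = NULL,
                                   rph_a_ci = NULL) {
  stopifnot(inherits(corr, "correlation_set"), inherits(fit, "ace_fit"))
  if (!identical(corr$measure, fit$measure) ||
      !identical(corr$phenotype, fit$phenotype))
    stop("correlation set and fit refer to different measure/phenotype")
  c1_ci <- corr$ci$r_wtct
  gate <- .ci_excludes_zero(c1_ci)
  if (!isTRUE(gate))
    return(endophenotype_criteria(c1_ci, NA, NULL, NULL, NULL))
  if (is.null(h2_ci)) h2_ci <- profile_ci(fit, "h2")
  if (is.null(rg_ci)) rg_ci <- profile_ci(fit, "rg")
  if (is.null(rph_a_ci)) rph_a_ci <- profile_ci(fit, "rph_a")
  endophenotype_criteria(c1_ci, fit$estimates$h2, h2_ci, rg_ci, rph_a_ci)
}
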