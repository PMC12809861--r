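# Synthetic twin/sibling cohorts with the exact generative structure the
# analysis assumes: bivariate ACE latents, a liability threshold on the
# disease side, covariate effects on the cognitive mean only, and
# study-style (proband-type) pair ascertainment.

#' Simulation configuration
#'
#' Declares the generative "truth": pair counts per zygosity class, the
#' cognitive ACE structure and its factor correlations with the disease
#' liability, the fixed disease model, covariate effect sizes, and the
#' target pair composition for ascertainment. Defaults emulate an IQ-like
#' measure (mean 100, SD 15, h2 = 0.70) in a schizophrenia-style cohort
#' (Maudsley profile, prevalence 0.75%) with a moderate protective genetic
#' correlation (rg = -0.30).
#'
#' @param n_mz,n_dz,n_sib pairs per zygosity class.
#' @param params an [ace_params] for the cognitive trait (its `beta` is
#'   ignored; covariate effects are set via `covariate_effects`).
#' @param disease a [disease_model] or profile name.
#' @param covariate_effects named list: `age` (points per year), `sex`
#'   (points for code 1), `education` (points per year), `centre` (numeric
#'   vector of per-centre mean shifts, first treated as reference).
#' @param centre_probs mixture proportions over centres (sum to 1).
#' @param missing_measure,missing_affect marginal missingness rates.
#' @param composition target pair counts for [ascertain_study_sample()]:
#'   named vector/list with `concordant`, `discordant`, `control`.
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   the config).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mz = 500, n_dz = 400, n_sib = 100,
                       params = ace_params(a = sqrt(0.70) * 15,
                                           c = sqrt(0.10) * 15,
                                           e = sqrt(0.20) * 15,
                                           rg = -0.30, rc = 0, re = -0.05,
                                           mu = 100),
                       disease = disease_profile("maudsley_sz"),
                       covariate_effects = list(age = -0.15, sex = 1.5,
                                                education = 1.2,
                                                centre = c(0, -2, 2)),
                       centre_probs = c(0.45, 0.35, 0.20),
                       missing_measure = 0, missing_affect = 0,
                       composition = c(concordant = 64, discordant = 129,
                                       control = 311),
                       seed = 1L) {
  if (is.character(disease)) disease <- disease_profile(disease)
  stopifnot(inherits(params, "ace_params"), inherits(disease, "disease_model"))
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(n_mz >= 0, n_dz >= 0, n_sib >= 0)
  if (abs(sum(centre_probs) - 1) > 1e-8)
    stop("centre_probs must sum to 1")
  if (length(covariate_effects$centre) != length(centre_probs))
    stop("centre effect vector and centre_probs lengths differ")
  structure(list(n_mz = n_mz, n_dz = n_dz, n_sib = n_sib,
                 params = params, disease = disease,
                 covariate_effects = covariate_effects,
                 centre_probs = centre_probs,
                 missing_measure = missing_measure,
                 missing_affect = missing_affect,
                 composition = composition, seed = as.integer(seed)),
            class = "sim_config")
}

#' Reduced study-like pair composition
#'
#' The full default composition mirrors the analytic cohort's complete-pair
#' structure (64 concordant-affected, 129 discordant and 311 screened
#' control pairs, ~1008 individuals); `scale` shrinks it proportionally for
#' fast tests.
#'
#' @param scale multiplier applied to each stratum count (rounded, min 2).
#' @return named integer vector.
#' @export
cohort_composition <- function(scale = 1) {
  full <- c(concordant = 64, discordant = 129, control = 311)
  out <- pmax(2, round(full * scale))
  setNames(as.integer(out), names(full))
}

# per-pair latent draws: returns matrix of liabilities/trait deviations
# for a block of pairs with kinship RA
.sim_pairs <- function(n, RA, p, dz) {
  if (n == 0L) return(NULL)
  for (r in c(p$rg, p$rc, p$re))
    if (abs(r) > 1) stop("infeasible correlation structure (non-PSD latents)")
  # bivariate standard-normal pair with correlation r
  corr2 <- function(r) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    cbind(z1, r * z1 + sqrt(max(0, 1 - r^2)) * z2)
  }
  # A: shared/unique split reproduces kinship RA for any RA in [0, 1],
  # with the cross-trait correlation rg carried by both components
  Ash <- corr2(p$rg); Au1 <- corr2(p$rg); Au2 <- corr2(p$rg)
  sA <- sqrt(RA); uA <- sqrt(1 - RA)
  Ax1 <- sA * Ash[, 1] + uA * Au1[, 1]
  Ax2 <- sA * Ash[, 1] + uA * Au2[, 1]
  Ad1 <- sA * Ash[, 2] + uA * Au1[, 2]
  Ad2 <- sA * Ash[, 2] + uA * Au2[, 2]
  C <- corr2(p$rc)                       # fully shared within pair
  E1 <- corr2(p$re); E2 <- corr2(p$re)   # member-specific
  y1 <- p$a * Ax1 + p$c * C[, 1] + p$e * E1[, 1]
  y2 <- p$a * Ax2 + p$c * C[, 1] + p$e * E2[, 1]
  l1 <- sqrt(dz$h2) * Ad1 + sqrt(dz$c2) * C[, 2] + sqrt(dz$e2) * E1[, 2]
  l2 <- sqrt(dz$h2) * Ad2 + sqrt(dz$c2) * C[, 2] + sqrt(dz$e2) * E2[, 2]
  cbind(y1 = y1, y2 = y2, l1 = l1, l2 = l2)
}

#' Simulate a population twin/sibling cohort
#'
#' Draws A/C/E latent factors with the model's cross-member correlations
#' (kinship for A, 1 for C, 0 for E) and cross-trait correlations
#' (`rg`, `rc`, `re`), builds the cognitive score as intercept + covariate
#' effects + scaled latents, and sets affection to 1 where the liability
#' exceeds the prevalence threshold. Bit-reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return a [twin_data] with measure `score` and phenotype `dx`, plus
#'   covariates age, sex, education, centre.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    p <- cfg$params; dz <- cfg$disease
    blocks <- list(MZ = c(cfg$n_mz, 1.0), DZ = c(cfg$n_dz, 0.5),
                   SIB = c(cfg$n_sib, 0.5))
    rows <- list()
    pid0 <- 0L
    for (z in names(blocks)) {
      n <- as.integer(blocks[[z]][1])
      if (n == 0L) next
      lat <- .sim_pairs(n, blocks[[z]][2], p, dz)
      ce <- cfg$covariate_effects
      nC <- length(cfg$centre_probs)
      centre_id <- sample.int(nC, n, replace = TRUE, prob = cfg$centre_probs)
      # pair-shared covariates: centre always; age shared for twins, siblings
      # differ by a few years
      age1 <- runif(n, 16, 65)
      age2 <- if (z == "SIB")
        pmin(65, pmax(16, age1 + rnorm(n, 0, 3.6))) else age1
      sex1 <- rbinom2(n)
      sex2 <- if (z == "MZ") sex1 else rbinom2(n)
      edu1 <- trunc_norm(n, 13, 2.5, 6, 22)
      edu2 <- trunc_norm(n, 13, 2.5, 6, 22)
      eff <- function(age, sex, edu)
        ce$age * (age - 40.5) + ce$sex * sex + ce$education * (edu - 13) +
        ce$centre[centre_id]
      y1 <- p$mu + eff(age1, sex1, edu1) + lat[, "y1"]
      y2 <- p$mu + eff(age2, sex2, edu2) + lat[, "y2"]
      d1 <- as.integer(lat[, "l1"] > dz$tau)
      d2 <- as.integer(lat[, "l2"] > dz$tau)
      if (cfg$missing_measure > 0) {
        y1[runif(n) < cfg$missing_measure] <- NA
        y2[runif(n) < cfg$missing_measure] <- NA
      }
      if (cfg$missing_affect > 0) {
        d1[runif(n) < cfg$missing_affect] <- NA
        d2[runif(n) < cfg$missing_affect] <- NA
      }
      pid <- pid0 + seq_len(n)
      pid0 <- pid0 + n
      rows[[z]] <- data.frame(
        pair_id = rep(pid, each = 2),
        member_index = rep(c(1L, 2L), n),
        zygosity = z,
        affected_dx = as.vector(rbind(d1, d2)),
        score = as.vector(rbind(y1, y2)),
        age = as.vector(rbind(age1, age2)),
        sex = as.vector(rbind(sex1, sex2)),
        education = as.vector(rbind(edu1, edu2)),
        centre = rep(paste0("centre", centre_id), each = 2),
        stringsAsFactors = FALSE)
    }
    out <- twin_data(do.call(rbind, rows), measures = "score",
                     phenotypes = "dx")
    attr(out, "sim_meta") <- list(seed = cfg$seed, scheme = "population",
                                  truth = cfg$params, disease = cfg$disease)
    out
  })
}

rbinom2 <- function(n) as.integer(runif(n) < 0.5)

trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Ascertain a study-style sample from a simulated population
#'
#' Stratified pair selection emulating the recruitment frame: the requested
#' numbers of concordant-affected pairs, discordant pairs (exactly one
#' affected member) and screened unaffected control pairs are drawn at
#' random (reproducibly from `seed`) from the eligible population strata.
#'
#' @param pop a [twin_data], typically from [simulate_population()].
#' @param composition named counts `concordant`, `discordant`, `control`;
#'   defaults to the config's target composition.
#' @param phenotype phenotype used for stratification.
#' @param seed selection seed.
#' @return a [twin_data] of the selected pairs; metadata records the scheme.
#' @export
ascertain_study_sample <- function(pop, composition = cohort_composition(),
                                   phenotype = pop$phenotypes[1],
                                   seed = 1L) {
  stopifnot(inherits(pop, "twin_data"))
  comp <- as.list(composition)
  for (k in c("concordant", "discordant", "control"))
    if (is.null(comp[[k]])) stop("composition must name '", k, "'")
  d <- pop$data
  aff <- d[[paste0("affected_", phenotype)]]
  naff <- tapply(aff, d$pair_id, function(a) sum(a, na.rm = TRUE))
  nobs <- tapply(aff, d$pair_id, function(a) sum(!is.na(a)))
  pid <- names(naff)
  strata <- list(
    concordant = pid[nobs == 2 & naff == 2],
    discordant = pid[nobs == 2 & naff == 1],
    control    = pid[nobs == 2 & naff == 0])
  .with_seed(seed, {
    chosen <- character(0)
    for (k in names(strata)) {
      want <- as.integer(comp[[k]])
      have <- strata[[k]]
      if (length(have) < want)
        stop("insufficient eligible pairs in stratum '", k, "': need ",
             want, ", have ", length(have))
      chosen <- c(chosen, sample(have, want))
    }
    out <- twin_data(d[as.character(d$pair_id) %in% chosen, , drop = FALSE],
                     measures = pop$measures, phenotypes = pop$phenotypes)
    attr(out, "sim_meta") <- utils::modifyList(
      attr(pop, "sim_meta") %||% list(),
      list(scheme = "proband_selected", composition = unlist(comp),
           selection_seed = as.integer(seed)))
    out
  })
}
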