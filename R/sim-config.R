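# Simulation configuration for synthetic biobank-style cohorts.

# Stratum-level measurement anchors (means/SDs on the observed scales) used
# when mapping standardized latent variables to assay/covariate units.
.stratum_params <- list(
  men = list(
    age_mean = 57.1, age_sd = 8.10,
    bat_mean = 5.21, bat_sd = 1.54,
    shbg_mean = 39.93, shbg_sd = 16.74,
    alb_mean = 45.53, alb_sd = 2.61,
    pension_age = 65
  ),
  premenopausal = list(
    age_mean = 46.4, age_sd = 4.24,
    bat_mean = 0.37, bat_sd = 0.25,
    shbg_mean = 68.07, shbg_sd = 32.31,
    alb_mean = 44.91, alb_sd = 2.59,
    pension_age = 60
  ),
  postmenopausal = list(
    age_mean = 60.5, age_sd = 5.38,
    bat_mean = 0.36, bat_sd = 0.28,
    shbg_mean = 59.45, shbg_sd = 28.03,
    alb_mean = 45.05, alb_sd = 2.56,
    pension_age = 60
  )
)

STRATA <- names(.stratum_params)

#' Configuration for a synthetic cohort
#'
#' Collects every data-generating assumption of the simulator in one
#' validated object.  The defaults describe the cohort the package's own
#' analyses are exercised on: a null causal effect of the hormone exposure
#' on outcomes (`beta_causal_effect = 0`) with confounding switched on, so
#' that multivariable-adjusted estimates are biased while genetically
#' instrumented estimates are not.  Pleiotropy and reverse (outcome to
#' exposure) feedback are off by default and can be enabled to stress the
#' estimators.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   (0, 0.5]; per-SNP MAFs are drawn uniformly from it.
#' @param ld_block_size SNPs per LD block (block-exchangeable correlation).
#' @param ld_rho Target within-block dosage correlation in `[0, 1)`.
#' @param h2_score Fraction of exposure variance explained by the causal
#'   SNPs, either a single number or a named vector over
#'   `c("men","premenopausal","postmenopausal")`. Defaults mirror polygenic
#'   scores explaining roughly 3.3%, 0.7% and 0.4% of bioavailable
#'   testosterone in the three strata.
#' @param n_causal Number of causal SNPs for the exposure.
#' @param beta_causal_effect Causal effect of the exposure (in SD units) on
#'   each outcome's latent scale.
#' @param conf_exposure,conf_outcome Loadings of the shared standard-normal
#'   confounder U on exposure and outcomes.  Illustrative magnitudes: no
#'   quantitative confounder model is available for the real cohort.
#' @param pleiotropy_alpha Direct effect of the standardized causal-allele
#'   count on outcomes (0 = valid instruments).
#' @param reverse_rho Outcome-to-exposure feedback loading (0 = none).
#' @param strata_props Length-3 proportions for men / premenopausal /
#'   postmenopausal women; must sum to 1.
#' @param age_beta,draw_hour_beta Standardized effects of age and
#'   blood-draw hour on the exposure; both negative by default (circulating
#'   testosterone declines with age and across the day).
#' @param n_centers Number of recruitment centers.
#' @param n_pcs Number of principal-component-like covariate columns.
#' @param p_medication,p_related,p_missing_assay Exclusion-flag rates
#'   (hormone-altering medication, relatedness, missing assay).
#' @param n_causal_edu,h2_edu Architecture of the independent educational
#'   attainment score (used by reverse-direction MR).
#' @param edu_effect_exposure,edu_effect_shbg Standardized effects of the
#'   schooling liability on the exposure and on SHBG, length-3 vectors by
#'   stratum; defaults encode an education effect on women's hormones and
#'   none in men.
#' @param detection_floor Assay detection floor for total testosterone (nM).
#' @param seed Integer seed; fixes the cohort bit-for-bit.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_individuals = 10000,
                       n_snps = 200,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.0,
                       h2_score = c(men = 0.033, premenopausal = 0.007,
                                    postmenopausal = 0.004),
                       n_causal = 40,
                       beta_causal_effect = 0,
                       conf_exposure = 0.30,
                       conf_outcome = 0.25,
                       pleiotropy_alpha = 0,
                       reverse_rho = 0,
                       strata_props = c(men = 0.512, premenopausal = 0.125,
                                        postmenopausal = 0.363),
                       age_beta = -0.10,
                       draw_hour_beta = -0.10,
                       n_centers = 5,
                       n_pcs = 40,
                       p_medication = 0.039,
                       p_related = 0.174,
                       p_missing_assay = 0.052,
                       n_causal_edu = 30,
                       h2_edu = 0.03,
                       edu_effect_exposure = c(men = 0, premenopausal = -0.2,
                                               postmenopausal = -0.2),
                       edu_effect_shbg = c(men = 0, premenopausal = 0.25,
                                           postmenopausal = 0.25),
                       detection_floor = 0.35,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    ld_rho = as.numeric(ld_rho),
    h2_score = .expand_by_stratum(h2_score, "h2_score"),
    n_causal = as.integer(n_causal),
    beta_causal_effect = as.numeric(beta_causal_effect),
    conf_exposure = as.numeric(conf_exposure),
    conf_outcome = as.numeric(conf_outcome),
    pleiotropy_alpha = as.numeric(pleiotropy_alpha),
    reverse_rho = as.numeric(reverse_rho),
    strata_props = .expand_by_stratum(strata_props, "strata_props"),
    age_beta = as.numeric(age_beta),
    draw_hour_beta = as.numeric(draw_hour_beta),
    n_centers = as.integer(n_centers),
    n_pcs = as.integer(n_pcs),
    p_medication = as.numeric(p_medication),
    p_related = as.numeric(p_related),
    p_missing_assay = as.numeric(p_missing_assay),
    n_causal_edu = as.integer(n_causal_edu),
    h2_edu = as.numeric(h2_edu),
    edu_effect_exposure = .expand_by_stratum(edu_effect_exposure,
                                             "edu_effect_exposure"),
    edu_effect_shbg = .expand_by_stratum(edu_effect_shbg, "edu_effect_shbg"),
    detection_floor = as.numeric(detection_floor),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

.expand_by_stratum <- function(x, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), 3L), STRATA)
  }
  if (is.null(names(x))) names(x) <- STRATA
  x <- as.numeric(x[STRATA])
  names(x) <- STRATA
  if (anyNA(x)) stop(sprintf("%s must be named over %s", what,
                             paste(STRATA, collapse = "/")))
  x
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals <= 0L || n_snps <= 0L) {
      stop("sim_config: n_individuals and n_snps must be positive")
    }
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("sim_config: maf_range must lie within (0, 0.5]")
    }
    if (ld_block_size <= 0L) stop("sim_config: ld_block_size must be >= 1")
    if (ld_rho < 0 || ld_rho >= 1) stop("sim_config: ld_rho must be in [0,1)")
    if (any(h2_score < 0) || any(h2_score >= 1)) {
      stop("sim_config: h2_score must be in [0,1)")
    }
    if (n_causal > n_snps) stop("sim_config: n_causal must be <= n_snps")
    if (n_causal_edu < 0L) stop("sim_config: n_causal_edu must be >= 0")
    if (any(strata_props < 0) || abs(sum(strata_props) - 1) > 1e-8) {
      stop("sim_config: strata_props must be non-negative and sum to 1")
    }
    for (p in c(p_medication, p_related, p_missing_assay)) {
      if (p < 0 || p > 1) stop("sim_config: flag probabilities must be in [0,1]")
    }
    if (detection_floor <= 0) stop("sim_config: detection_floor must be > 0")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d   SNPs: %d (blocks of %d, rho = %.3g)\n",
              x$n_individuals, x$n_snps, x$ld_block_size, x$ld_rho))
  cat(sprintf("  causal SNPs: %d   h2_score: %s\n", x$n_causal,
              paste(sprintf("%s=%.3g", STRATA, x$h2_score), collapse = " ")))
  cat(sprintf("  beta = %.3g  confounding (%.2g, %.2g)  pleiotropy %.3g  reverse %.3g\n",
              x$beta_causal_effect, x$conf_exposure, x$conf_outcome,
              x$pleiotropy_alpha, x$reverse_rho))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a simulation configuration
#'
#' Configurations serialize to YAML with field names identical to the
#' `sim_config()` arguments.
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

# Deterministic per-stage sub-seeds derived from the cohort seed; kept
# within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 11L, phenotypes = 23L, flags = 37L, split = 53L,
            boot = 71L, pipeline = 89L)
  s <- (as.double(seed) * 7919 + offs[[stage]]) %% 2147483647
  as.integer(s)
}
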