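# Phenotype simulation on top of simulated genotypes.
#
# Within each stratum (men / premenopausal / postmenopausal women) the
# standardized exposure liability is
#
#   X = sqrt(h2) G* + delta U + a age* + t hour* + g Edu* + sqrt(resid) eps
#
# where G* is the standardized weighted causal-SNP score, U the shared
# confounder, Edu* the (independent) schooling liability and resid the
# variance left over so Var(X) = 1.  Outcomes are built on latents
#   L = beta X + theta U + alpha P + e,   e ~ N(0,1)
# with P the standardized causal-allele count (pleiotropy channel); binary
# outcomes threshold L at a prevalence-matched cut so that causal risk
# differences have a closed form.  Bioavailable testosterone is the
# stratum-anchored affine map of X, and total testosterone is recovered
# through the binding-equilibrium mass balance so that re-deriving the
# hormone panel downstream reproduces the exposure.

.binary_prevalence <- c(
  degree = 0.39, own_home = 0.91, cohabiting = 0.75, risk_taking = 0.27,
  poor_health = 0.25, skilled_job = 0.82, current_smoker = 0.10
)
# orientation: +1 = outcome indicator is the UPPER tail of the advantaged
# latent, -1 = lower tail
.binary_tail <- c(
  degree = +1, own_home = +1, cohabiting = +1, risk_taking = +1,
  poor_health = -1, skilled_job = +1, current_smoker = -1
)
.continuous_scale <- c(income = 20000, tdi = -2.0, bmi = -1.5)
.continuous_anchor <- c(income = 50570, tdi = -1.6, bmi = 27.5)

.std_within <- function(x, g) {
  mu <- stats::ave(x, g, FUN = mean)
  sdv <- stats::ave(x, g, FUN = stats::sd)
  (x - mu) / sdv
}

#' Simulate phenotypes for a genotype set
#'
#' Builds the full synthetic cohort on top of [simulate_genotypes()]:
#' covariates (age, blood-draw hour, recruitment center, PC-like columns),
#' the shared confounder, the hormone panel (bioavailable testosterone as
#' the genetically influenced exposure, SHBG, albumin, and total
#' testosterone recovered through the binding equilibrium), socioeconomic
#' and health outcomes, exclusion flags, and a ground-truth record.
#'
#' @param genotypes Result of [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @return An object of class `cohort`: list with elements `genotypes`,
#'   `snps`, `phenotypes`, `ground_truth`, `config`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- genotypes$genotypes
  snps <- genotypes$snps
  n <- nrow(G)
  m <- ncol(G)
  set.seed(stage_seed(config$seed, "phenotypes"))

  stratum <- sample(STRATA, n, replace = TRUE, prob = config$strata_props)
  cnt <- table(factor(stratum, levels = STRATA))
  if (any(cnt < 2L & config$strata_props > 0)) {
    stop("simulate_phenotypes: every sampled stratum needs at least 2 individuals")
  }
  sp <- .stratum_params
  age <- stats::rnorm(n,
                      unlist(lapply(sp, `[[`, "age_mean"))[stratum],
                      unlist(lapply(sp, `[[`, "age_sd"))[stratum])
  age <- pmin(pmax(age, 39), 73)
  draw_hour <- stats::runif(n, 8, 20)
  center <- sprintf("c%02d", sample.int(config$n_centers, n, replace = TRUE))
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n,
                dimnames = list(NULL, sprintf("pc%d", seq_len(config$n_pcs))))
  U <- stats::rnorm(n)

  # causal architecture for the exposure
  if (config$n_causal > 0L) {
    causal <- sort(sample.int(m, config$n_causal))
    gamma <- stats::rnorm(config$n_causal)
    G_raw <- as.numeric(G[, causal, drop = FALSE] %*% gamma)
    P_raw <- rowSums(G[, causal, drop = FALSE])
    if (stats::sd(G_raw) == 0) stop("h2_score infeasible: causal score is constant")
    G_std <- .std_within(G_raw, stratum)
    P_std <- .std_within(P_raw, stratum)
  } else {
    if (any(config$h2_score > 0)) {
      stop("h2_score infeasible: h2_score > 0 requires n_causal > 0")
    }
    causal <- integer(0); gamma <- numeric(0)
    G_std <- numeric(n); P_std <- numeric(n)
  }

  # independent schooling architecture (reverse-direction MR)
  pool <- setdiff(seq_len(m), causal)
  n_edu <- min(config$n_causal_edu, length(pool))  # capped by available SNPs
  edu_idx <- if (n_edu > 0L) sort(sample(pool, n_edu)) else integer(0)
  edu_gamma <- stats::rnorm(n_edu)
  S_raw <- if (n_edu > 0L) {
    as.numeric(G[, edu_idx, drop = FALSE] %*% edu_gamma)
  } else numeric(n)
  h2_edu_eff <- if (n_edu > 0L && stats::sd(S_raw) > 0) config$h2_edu else 0
  S_std <- if (h2_edu_eff > 0) .std_within(S_raw, stratum) else numeric(n)
  edu_liab <- sqrt(h2_edu_eff) * S_std +
    sqrt(1 - h2_edu_eff) * stats::rnorm(n)
  schooling_years <- 13 + 2.5 * edu_liab
  degree <- as.integer(edu_liab > stats::qnorm(1 - .binary_prevalence["degree"]))

  # exposure liability, Var(X) = 1 within stratum
  h2_i <- config$h2_score[stratum]
  edu_x_i <- config$edu_effect_exposure[stratum]
  age_std <- .std_within(age, stratum)
  hour_std <- (draw_hour - 14) / (12 / sqrt(12))
  resid_var <- 1 - h2_i - config$conf_exposure^2 - config$age_beta^2 -
    config$draw_hour_beta^2 - edu_x_i^2
  if (any(resid_var <= 0.01)) {
    stop("h2_score infeasible: variance components exceed 1 in some stratum")
  }
  X0 <- sqrt(h2_i) * G_std + config$conf_exposure * U +
    config$age_beta * age_std + config$draw_hour_beta * hour_std +
    edu_x_i * edu_liab + sqrt(resid_var) * stats::rnorm(n)

  beta <- config$beta_causal_effect
  theta <- config$conf_outcome
  alpha <- config$pleiotropy_alpha
  latent <- function() beta * X0 + theta * U + alpha * P_std + stats::rnorm(n)

  # continuous outcomes
  L_inc <- latent(); L_tdi <- latent(); L_bmi <- latent(); L_smk <- latent()
  # reverse feedback: the income latent feeds back into the exposure
  X <- X0 + config$reverse_rho * (L_inc - beta * X0)

  income <- .continuous_anchor["income"] + .continuous_scale["income"] * L_inc
  income_category <- cut(income,
    breaks = c(-Inf, 18000, 31000, 52000, 100000, Inf),
    labels = INCOME_LABELS, right = FALSE)
  tdi <- .continuous_anchor["tdi"] + .continuous_scale["tdi"] * L_tdi
  bmi <- .continuous_anchor["bmi"] + .continuous_scale["bmi"] * L_bmi
  smoking_index <- pmax(0, 0.8 * (-L_smk) - 0.2)

  # binary outcomes by liability threshold; cut at the prevalence-matched
  # quantile of the theoretical latent SD
  sd_lat <- sqrt(beta^2 + theta^2 + alpha^2 + 1 +
                 2 * beta * theta * config$conf_exposure)
  bin <- list()
  rd_true <- c()
  for (o in setdiff(names(.binary_prevalence), "degree")) {
    L <- latent()
    pr <- .binary_prevalence[[o]]
    tail <- .binary_tail[[o]]
    cut_o <- sd_lat * stats::qnorm(1 - pr)
    bin[[o]] <- as.integer(tail * L > cut_o)
    # causal risk difference per SD of exposure (do-operator, latents normal)
    s_do <- sqrt(beta^2 + theta^2 + alpha^2 + 1)
    rd_true[o] <- tail * beta * stats::dnorm(cut_o / s_do) / s_do
  }
  rd_true["degree"] <- 0  # degree is schooling-driven; no direct X path

  # employment: age-driven retirement, then liability-ranked categories
  L_emp <- latent()
  pension <- ifelse(stratum == "men", 65, 60)
  retired <- stats::runif(n) < stats::plogis((age - pension + 2) / 2)
  emp <- rep("employed", n)
  emp[retired] <- "retired"
  z_emp <- L_emp / sd_lat
  hm_pr <- ifelse(stratum == "men", 0.007, 0.08)
  emp[!retired & z_emp < stats::qnorm(0.045)] <- "sick_disabled"
  emp[!retired & emp == "employed" &
        z_emp < stats::qnorm(0.045 + 0.03)] <- "unemployed"
  emp[!retired & emp == "employed" &
        stats::runif(n) < hm_pr] <- "homemaker"

  # hormone panel
  bat_mean <- unlist(lapply(sp, `[[`, "bat_mean"))[stratum]
  bat_sd <- unlist(lapply(sp, `[[`, "bat_sd"))[stratum]
  oophorectomy <- as.integer(stratum == "postmenopausal" &
                               stats::runif(n) < 0.25)
  bat <- pmax(bat_mean + bat_sd * (X - 0.2 * oophorectomy), 0.02)
  edu_s_i <- config$edu_effect_shbg[stratum]
  shbg_lat <- edu_s_i * edu_liab + sqrt(1 - edu_s_i^2) * stats::rnorm(n)
  shbg <- pmax(unlist(lapply(sp, `[[`, "shbg_mean"))[stratum] +
                 unlist(lapply(sp, `[[`, "shbg_sd"))[stratum] * shbg_lat, 1)
  albumin <- pmax(unlist(lapply(sp, `[[`, "alb_mean"))[stratum] +
                    unlist(lapply(sp, `[[`, "alb_sd"))[stratum] *
                    stats::rnorm(n), 20)
  total_t <- total_from_bioavailable(bat, shbg, albumin)

  flag_medication <- stats::runif(n) < config$p_medication
  flag_related <- stats::runif(n) < config$p_related
  flag_missing_assay <- stats::runif(n) < config$p_missing_assay
  total_t[flag_missing_assay] <- NA_real_

  phenotypes <- data.frame(
    eid = rownames(G),
    stratum = stratum,
    age = age,
    draw_hour = draw_hour,
    center = center,
    pcs,
    confounder_u = U,
    schooling_years = schooling_years,
    degree = degree,
    oophorectomy = oophorectomy,
    menopause = ifelse(stratum == "men", "na",
                       ifelse(stratum == "premenopausal", "no", "yes")),
    total_t = total_t,
    shbg = shbg,
    albumin = albumin,
    income_category = as.character(income_category),
    tdi = tdi,
    bmi = bmi,
    smoking_index = smoking_index,
    employment_status = emp,
    skilled_job = bin$skilled_job,
    own_home = bin$own_home,
    cohabiting = bin$cohabiting,
    risk_taking = bin$risk_taking,
    poor_health = bin$poor_health,
    current_smoker = bin$current_smoker,
    birth_north = stats::runif(n, 0, 1000),
    birth_east = stats::runif(n, 0, 600),
    household_size = pmin(1L + stats::rpois(n, 1.3), 12L),
    flag_medication = flag_medication,
    flag_related = flag_related,
    flag_missing_assay = flag_missing_assay,
    stringsAsFactors = FALSE
  )
  # "do not know / prefer not to say" risk-taking answers become missing
  phenotypes$risk_taking[stats::runif(n) < 0.02] <- NA_integer_

  truth_cont <- data.frame(
    outcome = names(.continuous_scale),
    type = "continuous",
    scale_factor = as.numeric(.continuous_scale),
    true_effect_per_sd = beta * as.numeric(.continuous_scale),
    stringsAsFactors = FALSE
  )
  truth_bin <- data.frame(
    outcome = names(rd_true),
    type = "binary",
    scale_factor = 1,
    true_effect_per_sd = as.numeric(rd_true),
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    beta_causal_effect = beta,
    conf_exposure = config$conf_exposure,
    conf_outcome = config$conf_outcome,
    pleiotropy_alpha = alpha,
    reverse_rho = config$reverse_rho,
    h2_score = config$h2_score,
    ovb_slope_latent = beta + config$conf_exposure * theta,
    causal_snps = snps$snp_id[causal],
    causal_weights = gamma,
    edu_snps = snps$snp_id[edu_idx],
    edu_weights = edu_gamma,
    edu_effect_exposure = config$edu_effect_exposure,
    edu_effect_shbg = config$edu_effect_shbg,
    outcome_truth = rbind(truth_cont, truth_bin)
  )

  structure(
    list(genotypes = G, snps = snps, phenotypes = phenotypes,
         ground_truth = ground_truth, config = config),
    class = "cohort"
  )
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: [simulate_genotypes()] followed by
#' [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A `cohort` object.
#' @export
simulate_cohort <- function(config) {
  simulate_phenotypes(simulate_genotypes(config), config)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  print(table(x$phenotypes$stratum))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("ground truth: beta = %.3g, confounding (%.2g, %.2g)\n",
                x$ground_truth$beta_causal_effect,
                x$ground_truth$conf_exposure, x$ground_truth$conf_outcome))
  }
  invisible(x)
}

#' Remove flagged individuals from a cohort
#'
#' Drops individuals flagged for hormone-altering medication use,
#' relatedness, or missing assays (set union: each individual is removed
#' once).  Per-reason counts are recorded in the `exclusion_log`
#' attribute.
#'
#' @param cohort A `cohort`.
#' @param reasons Character subset of
#'   `c("medication", "related", "missing_assay")`.
#' @return The filtered cohort (ground truth untouched: it holds only
#'   population-level parameters).
#' @export
apply_exclusions <- function(cohort,
                             reasons = c("medication", "related",
                                         "missing_assay")) {
  reasons <- match.arg(reasons, several.ok = TRUE)
  ph <- cohort$phenotypes
  flags <- list(
    medication = ph$flag_medication,
    related = ph$flag_related,
    missing_assay = ph$flag_missing_assay
  )[reasons]
  drop <- Reduce(`|`, flags)
  log <- c(vapply(flags, sum, 0L), total_removed = sum(drop))
  cohort$phenotypes <- ph[!drop, , drop = FALSE]
  cohort$genotypes <- cohort$genotypes[!drop, , drop = FALSE]
  if (nrow(cohort$phenotypes) == 0L) {
    warning("apply_exclusions: all individuals removed")
  }
  attr(cohort, "exclusion_log") <- log
  cohort
}
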