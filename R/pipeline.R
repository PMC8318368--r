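# Full split-sample analysis driver: exclusions -> hormone derivation ->
# stratified split -> GWAS -> clumping -> PGS in the opposite split ->
# per-split MR + multivariable comparator + diagnostics -> fixed-effect
# meta across splits -> Fisher test vs the meta multivariable estimate ->
# two-sample sensitivity suite; plus negative controls and the
# reverse-direction (education -> hormone) analysis.

#' Analysis settings for the pipeline
#'
#' @param exposure Phenotype column used as exposure (default derived
#'   bioavailable testosterone).
#' @param outcomes Character vector of outcome names from
#'   [default_outcome_specs()] (default: a compact set).
#' @param strata Strata to analyze.
#' @param p_threshold,window_kb,r2_threshold Clumping parameters (named
#'   defaults: genome-wide 5e-8, 10,000 kb, r-squared 0.001).
#' @param n_pcs PCs used as covariates (default 40).
#' @param oophorectomy_covariate Include oophorectomy as a GWAS/analysis
#'   covariate for postmenopausal women (main analysis on).
#' @param sensitivity Run the two-sample sensitivity suite per split.
#' @param n_boot Bootstrap replicates for weighted median/mode.
#' @param weak_f_floor Weak-instrument flag threshold.
#' @return List of class `mr_settings`.
#' @export
mr_settings <- function(exposure = "bioavailable_t",
                        outcomes = c("income", "tdi", "degree",
                                     "poor_health"),
                        strata = STRATA,
                        p_threshold = 5e-8,
                        window_kb = 10000,
                        r2_threshold = 0.001,
                        n_pcs = 40L,
                        oophorectomy_covariate = TRUE,
                        sensitivity = TRUE,
                        n_boot = 1000L,
                        weak_f_floor = 10) {
  structure(list(
    exposure = exposure, outcomes = outcomes,
    strata = match.arg(strata, STRATA, several.ok = TRUE),
    p_threshold = p_threshold, window_kb = window_kb,
    r2_threshold = r2_threshold, n_pcs = as.integer(n_pcs),
    oophorectomy_covariate = oophorectomy_covariate,
    sensitivity = sensitivity, n_boot = as.integer(n_boot),
    weak_f_floor = weak_f_floor
  ), class = "mr_settings")
}

.stratum_covariates <- function(ph, settings, stratum) {
  standard_covariates(
    ph, n_pcs = settings$n_pcs,
    oophorectomy = settings$oophorectomy_covariate &&
      stratum == "postmenopausal"
  )
}

# One stratum, both splits: instruments, estimates, diagnostics.
.run_stratum <- function(cohort_s, stratum, outcome_tab, settings, seed) {
  specs <- default_outcome_specs()
  specs <- specs[specs$name %in% settings$outcomes, , drop = FALSE]
  halves <- split_sample(cohort_s, seed)
  exposure_sd <- stats::sd(cohort_s$phenotypes[[settings$exposure]],
                           na.rm = TRUE)

  # discovery per split
  disc <- lapply(halves, function(h) {
    cov <- .stratum_covariates(h$phenotypes, settings, stratum)
    ss <- run_gwas(h, settings$exposure, cov)
    inst <- clump(ss, ld_accessor(h$genotypes),
                  p_threshold = settings$p_threshold,
                  window_kb = settings$window_kb,
                  r2_threshold = settings$r2_threshold)
    list(sumstats = ss, instruments = inst)
  })

  estimates <- list(); comparisons <- list(); sens_rows <- list()
  diagnostics <- list()
  for (k in 1:2) {
    est_half <- halves[[k]]
    inst <- disc[[3 - k]]$instruments   # instruments from the other split
    split_lab <- paste0("split", k)
    if (nrow(inst) == 0L) {
      stop(sprintf("pipeline: no genome-wide-significant instruments for %s (%s)",
                   stratum, split_lab))
    }
    ph <- est_half$phenotypes
    cov <- .stratum_covariates(ph, settings, stratum)
    pgs <- compute_pgs(est_half$genotypes, inst)
    otab <- outcome_tab[match(ph$eid, outcome_tab$eid), , drop = FALSE]
    fstat <- first_stage_f(ph[[settings$exposure]], pgs, cov)
    diagnostics[[split_lab]] <- list(
      f_stat = fstat, n_instruments = nrow(inst),
      pgs_r2 = score_r2(pgs, ph[[settings$exposure]], cov)
    )
    for (i in seq_len(nrow(specs))) {
      o <- specs$name[i]; otype <- specs$type[i]
      ivr <- iv_estimate(otab[[o]], ph[[settings$exposure]], pgs, cov,
                         outcome_type = otype, outcome_name = o,
                         stratum = stratum, split = split_lab,
                         weak_f_floor = settings$weak_f_floor)
      mv <- multivariable_estimate(otab[[o]], ph[[settings$exposure]], cov,
                                   outcome_type = otype, outcome_name = o,
                                   stratum = stratum, split = split_lab)
      ivr <- standardize_per_sd(ivr, exposure_sd)
      mv <- standardize_per_sd(mv, exposure_sd)
      estimates[[paste(o, split_lab, "mr")]] <- ivr
      estimates[[paste(o, split_lab, "mv")]] <- mv
      comparisons[[paste(o, split_lab, "hausman")]] <- hausman_test(ivr, mv)

      if (settings$sensitivity && nrow(inst) >= 3L && otype == "continuous") {
        out_ss <- run_gwas(
          subset_cohort(est_half, !is.na(otab[[o]])),
          otab[[o]][!is.na(otab[[o]])], cov[!is.na(otab[[o]]), , drop = FALSE]
        )
        h <- harmonize(
          structure(as.data.frame(inst), class = c("sumstats", "data.frame")),
          out_ss
        )
        if (nrow(h) >= 3L) {
          suite <- mr_sensitivity_suite(h, n_boot = settings$n_boot,
                                        seed = seed + k)
          for (mres in suite$results) {
            sens_rows[[paste(o, split_lab, mres$method)]] <- data.frame(
              outcome = o, stratum = stratum, split = split_lab,
              method = mres$method, beta = mres$beta, se = mres$se,
              ci_low = mres$ci[1], ci_high = mres$ci[2], p = mres$p,
              n_snp = mres$n_snp,
              q = if (!is.null(mres$q)) mres$q else NA_real_,
              egger_intercept = if (!is.null(mres$intercept)) mres$intercept
              else NA_real_,
              egger_intercept_p = if (!is.null(mres$intercept_p))
                mres$intercept_p else NA_real_,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }

  # meta across splits + Fisher tests
  for (i in seq_len(nrow(specs))) {
    o <- specs$name[i]
    meta_mr <- meta_fixed(list(estimates[[paste(o, "split1", "mr")]],
                               estimates[[paste(o, "split2", "mr")]]))
    meta_mv <- meta_fixed(list(estimates[[paste(o, "split1", "mv")]],
                               estimates[[paste(o, "split2", "mv")]]))
    estimates[[paste(o, "meta", "mr")]] <- meta_mr
    estimates[[paste(o, "meta", "mv")]] <- meta_mv
    comparisons[[paste(o, "meta", "fisher")]] <-
      fisher_difference_test(meta_mr, meta_mv)
  }

  list(estimates = estimates, comparisons = comparisons,
       sensitivity = if (length(sens_rows)) do.call(rbind, sens_rows),
       diagnostics = diagnostics, exposure_sd = exposure_sd,
       instruments = lapply(disc, `[[`, "instruments"))
}

#' Run the full split-sample MR pipeline
#'
#' For each requested stratum: exclusions, hormone derivation, stratified
#' split, GWAS per split, LD clumping, PGS built in the opposite split,
#' per-split 2SLS and multivariable estimates (expressed per within-
#' stratum SD of the exposure; binary outcomes as percentage points),
#' Hausman tests, fixed-effect meta-analysis across the splits, Fisher
#' tests between the meta estimates, the two-sample sensitivity suite,
#' and first-stage diagnostics.  Everything is deterministic given the
#' config seed.
#'
#' @param x A `sim_config` (the cohort is simulated) or a `cohort`.
#' @param settings An [mr_settings()].
#' @return An `mr_report`: `results` (estimates table), `comparisons`,
#'   `sensitivity`, `diagnostics`, `exposure_sd`, `provenance`, and the
#'   per-stratum `instruments`.
#' @export
run_full_pipeline <- function(x, settings = mr_settings()) {
  cohort <- if (inherits(x, "sim_config")) simulate_cohort(x) else x
  stopifnot(inherits(cohort, "cohort"))
  seed <- stage_seed(cohort$config$seed, "pipeline")

  cohort <- apply_exclusions(cohort)
  excl_log <- attr(cohort, "exclusion_log")
  cohort$phenotypes <- derive_hormones(cohort$phenotypes,
                                       cohort$config$detection_floor)
  outcome_tab <- code_outcomes(cohort)

  strata_res <- list()
  for (s in intersect(settings$strata, unique(cohort$phenotypes$stratum))) {
    sub <- subset_cohort(cohort, cohort$phenotypes$stratum == s)
    strata_res[[s]] <- .run_stratum(sub, s, outcome_tab, settings, seed)
  }

  results <- do.call(rbind, lapply(strata_res, function(r) {
    estimates_table(r$estimates)
  }))
  rownames(results) <- NULL
  comparisons <- do.call(rbind, lapply(names(strata_res), function(s) {
    r <- strata_res[[s]]
    do.call(rbind, lapply(names(r$comparisons), function(nm) {
      cmp <- r$comparisons[[nm]]
      parts <- strsplit(nm, " ")[[1]]
      data.frame(outcome = parts[1], stratum = s, split = parts[2],
                 test = cmp$test, statistic = cmp$statistic, p = cmp$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(comparisons)) rownames(comparisons) <- NULL
  sensitivity <- do.call(rbind, lapply(strata_res, `[[`, "sensitivity"))
  if (!is.null(sensitivity)) rownames(sensitivity) <- NULL

  structure(list(
    results = results,
    comparisons = comparisons,
    sensitivity = sensitivity,
    diagnostics = lapply(strata_res, `[[`, "diagnostics"),
    exposure_sd = vapply(strata_res, `[[`, 0, "exposure_sd"),
    instruments = lapply(strata_res, `[[`, "instruments"),
    exclusions = excl_log,
    ground_truth = cohort$ground_truth,
    provenance = list(
      seed = cohort$config$seed,
      config = unclass(cohort$config),
      settings = unclass(settings),
      package_version = as.character(utils::packageVersion("splitmr")),
      r_version = R.version.string
    )
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Split-sample MR report\n")
  cat(sprintf("  strata: %s\n", paste(names(x$diagnostics), collapse = ", ")))
  meta <- x$results[x$results$split == "meta", , drop = FALSE]
  cat(sprintf("  %d estimates (%d meta rows), %d comparison tests\n",
              nrow(x$results), nrow(meta), nrow(x$comparisons)))
  for (s in names(x$diagnostics)) {
    d <- x$diagnostics[[s]]
    cat(sprintf("  %s: F = %.3g / %.3g, instruments = %d / %d\n", s,
                d$split1$f_stat, d$split2$f_stat,
                d$split1$n_instruments, d$split2$n_instruments))
  }
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes the results, comparison and sensitivity tables as tab-delimited
#' text plus a YAML provenance document.
#'
#' @param report An `mr_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(.fmt_num_cols(report$results),
                     file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.fmt_num_cols(report$comparisons),
                     file.path(dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$sensitivity)) {
    utils::write.table(.fmt_num_cols(report$sensitivity),
                       file.path(dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Negative-control analysis: place of birth
#'
#' MR and multivariable estimates of the exposure against the (simulated,
#' independent) North and East birth coordinates.  Both are expected to be
#' null; systematic non-null estimates would indicate bias.
#'
#' @param cohort A `cohort` with derived hormones.
#' @param score Instrument score vector aligned with the phenotype rows.
#' @param exposure Exposure column name.
#' @param covariates Optional covariate matrix.
#' @return Named list: for each coordinate, a list with `mr` and
#'   `multivariable` estimates.
#' @export
negative_control <- function(cohort, score, exposure = "bioavailable_t",
                             covariates = NULL) {
  ph <- cohort$phenotypes
  stopifnot(all(c("birth_north", "birth_east") %in% names(ph)))
  out <- list()
  for (coord in c("birth_north", "birth_east")) {
    out[[coord]] <- list(
      mr = iv_estimate(ph[[coord]], ph[[exposure]], score, covariates,
                       outcome_name = coord),
      multivariable = multivariable_estimate(ph[[coord]], ph[[exposure]],
                                             covariates,
                                             outcome_name = coord)
    )
  }
  out
}

#' Reverse-direction MR: educational attainment on hormones
#'
#' Uses the independently simulated schooling architecture: a GWAS of
#' schooling years in split 1 identifies education SNPs (clumped at
#' `p_threshold`); a PGS built from them instruments degree status in
#' split 2 for one-sample MR on each hormone (expressed per within-
#' stratum SD of the hormone), and per-SNP schooling/hormone associations
#' from the two splits feed the two-sample suite (per extra year of
#' schooling).
#'
#' @param cohort A `cohort` with derived hormones.
#' @param hormones Hormone columns to analyze.
#' @param p_threshold Selection threshold for education SNPs.
#' @param n_boot,seed Bootstrap settings for median/mode.
#' @return List with `onesample` (per hormone, `mr_estimate`) and
#'   `twosample` (per hormone, list of `mr_method_result`).
#' @export
reverse_mr <- function(cohort, hormones = c("bioavailable_t", "free_t",
                                            "shbg"),
                       p_threshold = 5e-8, n_boot = 200L,
                       seed = cohort$config$seed) {
  halves <- split_sample(cohort, seed)
  h1 <- halves$split1; h2 <- halves$split2
  edu_ss <- run_gwas(h1, "schooling_years", NULL)
  inst <- clump(edu_ss, ld_accessor(h1$genotypes), p_threshold = p_threshold)
  if (nrow(inst) == 0L) {
    stop("reverse_mr: no education SNPs pass the selection threshold")
  }
  pgs <- compute_pgs(h2$genotypes, inst)
  ph2 <- h2$phenotypes
  onesample <- list(); twosample <- list()
  for (hm in hormones) {
    sd_h <- stats::ave(ph2[[hm]], ph2$stratum,
                       FUN = function(v) stats::sd(v, na.rm = TRUE))
    y_std <- ph2[[hm]] / sd_h  # per within-stratum SD of the hormone
    onesample[[hm]] <- iv_estimate(y_std, ph2$degree, pgs,
                                   outcome_name = hm, outcome_type = "continuous")
    horm_ss <- run_gwas(subset_cohort(h2, !is.na(y_std)),
                        y_std[!is.na(y_std)], NULL)
    # per extra year of schooling: exposure betas on the schooling-years scale
    hh <- harmonize(
      structure(as.data.frame(inst), class = c("sumstats", "data.frame")),
      horm_ss
    )
    if (nrow(hh) >= 3L) {
      twosample[[hm]] <- mr_sensitivity_suite(hh, n_boot = n_boot,
                                              seed = seed)$results
    }
  }
  list(onesample = onesample, twosample = twosample,
       instruments = inst)
}
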