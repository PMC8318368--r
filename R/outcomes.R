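# Outcome coding: income midpoints, employment contrasts, deprivation
# tertiles, pension-age masking.

INCOME_LABELS <- c("<£18,000", "£18,000 to £30,999",
                   "£31,000 to £51,999",
                   "£52,000 to £100,000", ">£100,000")
INCOME_MIDPOINTS <- c(15000, 24500, 41500, 76000, 150000)
names(INCOME_MIDPOINTS) <- INCOME_LABELS

#' Code household-income categories
#'
#' Maps the five banded income categories to their range midpoints
#' (open-ended bands get nominal values: 15,000 and 150,000) and to the
#' dichotomy at 52,000 (1 for the upper two bands).
#'
#' @param category Character vector of income-band labels.
#' @return Data frame with columns `midpoint` and `high` (binary).
#' @export
code_income <- function(category) {
  idx <- match(category, INCOME_LABELS)
  bad <- !is.na(category) & is.na(idx)
  if (any(bad)) {
    stop(sprintf("code_income: unknown category label(s): %s",
                 paste(unique(category[bad]), collapse = ", ")))
  }
  data.frame(midpoint = unname(INCOME_MIDPOINTS[idx]),
             high = as.integer(idx >= 4L))
}

#' Equivalized household income
#'
#' Household income divided by the number of people in the household,
#' with the household size capped at 12 (a secondary-analysis coding).
#'
#' @param income Household income (midpoint-coded).
#' @param household_size Number of people in the household.
#' @return Equivalized income.
#' @export
equivalized_income <- function(income, household_size) {
  income / pmin(household_size, 12)
}

#' Default outcome specifications
#'
#' One row per analyzed outcome: name, type (continuous/binary), the
#' phenotype coding rule, and whether the outcome is masked for
#' individuals at or above the state pension age at recruitment (65 for
#' men, 60 for women) — income and employment outcomes are closely tied to
#' current labor-market involvement.
#'
#' @return Data frame of class `outcome_spec`.
#' @export
default_outcome_specs <- function() {
  spec <- data.frame(
    name = c("income", "income_high", "tdi", "tdi_deprived", "bmi",
             "smoking_index", "current_smoker",
             "emp_homemaker", "emp_sick_disabled", "emp_retired",
             "emp_unemployed", "skilled_job", "degree", "own_home",
             "cohabiting", "risk_taking", "poor_health"),
    type = c("continuous", "binary", "continuous", "binary", "continuous",
             "continuous", "binary",
             "binary", "binary", "binary", "binary", "binary", "binary",
             "binary", "binary", "binary", "binary"),
    pension_masked = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                       FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("outcome_spec", "data.frame")
  spec
}

.emp_contrast <- function(status, case) {
  out <- rep(NA_integer_, length(status))
  out[status == "employed"] <- 0L
  out[status == case] <- 1L
  out
}

#' Code the outcome table for a cohort
#'
#' Applies every coding rule: income midpoints and the 52,000 dichotomy;
#' deprivation tertiles (cut points computed within the non-missing
#' analyzed rows of each stratum, most deprived tertile vs the rest); four
#' employment contrasts, each against the same employed reference with the
#' other categories set missing; and pass-through binaries.  Individuals
#' at or above the stratum pension age (65 men / 60 women) have income and
#' employment outcomes masked.  Every row maps to coded-or-missing for
#' every outcome; per-outcome missingness reasons are in the
#' `coding_log` attribute and sum to the row count.
#'
#' @param cohort A `cohort`.
#' @param specs An `outcome_spec` table (default [default_outcome_specs()]).
#' @return Data frame: `eid` plus one column per outcome, with a
#'   `coding_log` attribute.
#' @export
code_outcomes <- function(cohort, specs = default_outcome_specs()) {
  ph <- cohort$phenotypes
  needed <- c("income_category", "tdi", "bmi", "smoking_index",
              "current_smoker", "employment_status", "skilled_job",
              "degree", "own_home", "cohabiting", "risk_taking",
              "poor_health", "age", "stratum")
  absent <- setdiff(needed, names(ph))
  if (length(absent)) {
    stop(sprintf("code_outcomes: phenotype fields missing: %s",
                 paste(absent, collapse = ", ")))
  }
  pension <- ifelse(ph$stratum == "men", 65, 60)
  over_pension <- ph$age >= pension

  inc <- code_income(ph$income_category)
  # deprivation tertile cut within each stratum's non-missing rows
  tdi_dep <- rep(NA_integer_, nrow(ph))
  for (s in unique(ph$stratum)) {
    i <- ph$stratum == s & !is.na(ph$tdi)
    cut2 <- stats::quantile(ph$tdi[i], 2 / 3, names = FALSE, type = 7)
    tdi_dep[i] <- as.integer(ph$tdi[i] > cut2)
  }

  out <- data.frame(
    eid = ph$eid,
    income = inc$midpoint,
    income_high = inc$high,
    tdi = ph$tdi,
    tdi_deprived = tdi_dep,
    bmi = ph$bmi,
    smoking_index = ph$smoking_index,
    current_smoker = ph$current_smoker,
    emp_homemaker = .emp_contrast(ph$employment_status, "homemaker"),
    emp_sick_disabled = .emp_contrast(ph$employment_status, "sick_disabled"),
    emp_retired = .emp_contrast(ph$employment_status, "retired"),
    emp_unemployed = .emp_contrast(ph$employment_status, "unemployed"),
    skilled_job = ph$skilled_job,
    degree = ph$degree,
    own_home = ph$own_home,
    cohabiting = ph$cohabiting,
    risk_taking = ph$risk_taking,
    poor_health = ph$poor_health,
    stringsAsFactors = FALSE
  )

  log <- list()
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    source_missing <- sum(is.na(out[[nm]]))
    masked <- 0L
    if (specs$pension_masked[i]) {
      masked <- sum(over_pension & !is.na(out[[nm]]))
      out[[nm]][over_pension] <- NA
    }
    log[[nm]] <- c(coded = sum(!is.na(out[[nm]])),
                   masked_pension_age = masked,
                   missing_source = source_missing)
  }
  out <- out[, c("eid", specs$name)]
  attr(out, "coding_log") <- log
  out
}
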