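# One-sample MR by two-stage least squares, multivariable comparators,
# weak-instrument diagnostics, estimate-difference tests, and fixed-effect
# meta-analysis across splits.
#
# The additive structural mean model with a single instrument and linear
# stages is estimated by 2SLS, to which it reduces exactly (an equivalence,
# not an approximation).  Binary outcomes are fitted identically as linear
# probability models, so coefficients are risk differences.

CI_Z <- 1.96  # two-sided 95% multiplier used for every interval

#' Construct an estimate record
#'
#' Container for a single effect estimate: beta, robust SE, 95% CI
#' (`beta +/- 1.96 se`), two-sided p (standard normal), sample size,
#' method and provenance labels, and a scale tag
#' (`"per_unit"`, `"per_sd"`, or `"pp_per_sd"` for binary outcomes
#' expressed in absolute percentage points per SD of exposure).
#'
#' @param beta,se Point estimate and standard error.
#' @param n Sample size.
#' @param method Estimator label, e.g. `"MR-2SLS"` or
#'   `"multivariable-OLS"`.
#' @param outcome,stratum,split Provenance labels.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param scale Scale tag.
#' @param f_stat Optional first-stage F statistic.
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(beta, se, n = NA_integer_, method = "custom",
                        outcome = NA_character_, stratum = NA_character_,
                        split = NA_character_, outcome_type = "continuous",
                        scale = "per_unit", f_stat = NA_real_) {
  stopifnot(is.finite(beta), se >= 0)
  z <- if (se > 0) beta / se else sign(beta) * Inf
  structure(list(
    beta = beta, se = se,
    ci = c(lower = beta - CI_Z * se, upper = beta + CI_Z * se),
    p = 2 * stats::pnorm(-abs(z)),
    n = n, method = method, outcome = outcome, stratum = stratum,
    split = split, outcome_type = outcome_type, scale = scale,
    f_stat = f_stat
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate%s%s\n", x$method,
              if (!is.na(x$outcome)) paste0(" for ", x$outcome) else "",
              if (!is.na(x$split)) paste0(" [", x$split, "]") else ""))
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, n = %s\n",
              x$beta, x$se, x$ci[1], x$ci[2], x$p, format(x$n)))
  cat(sprintf("  scale: %s", x$scale))
  if (is.finite(x$f_stat)) cat(sprintf("   first-stage F = %.4g", x$f_stat))
  cat("\n")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) c(exposure = object$beta)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  matrix(object$ci, 1, dimnames = list("exposure", c("lower", "upper")))
}

.resolve_col <- function(x, data) {
  if (is.character(x) && length(x) == 1L) data[[x]] else as.numeric(x)
}

# HC1 sandwich covariance given design matrix (with intercept), residuals.
.hc1_vcov <- function(X, u) {
  n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * u, X * u)
  bread %*% meat %*% bread * n / (n - k)
}

#' Two-stage least squares (one-sample MR)
#'
#' Stage 1 regresses the exposure on the instrument score plus covariates;
#' stage 2 regresses the outcome on the stage-1 fitted exposure plus the
#' same covariates.  The exposure coefficient is returned with a
#' heteroskedasticity-robust (HC1) standard error computed from the proper
#' IV sandwich (residuals use the observed, not fitted, exposure).  Binary
#' outcomes are fitted identically (linear probability model: the
#' coefficient is a risk difference).  A weak first stage (robust F below
#' `weak_f_floor`) is flagged, not rejected.
#'
#' @param outcome,exposure,instrument Numeric vectors or column names into
#'   `data`.
#' @param covariates Optional covariate matrix (no intercept column).
#' @param data Optional phenotype data frame for name lookup.
#' @param robust Use the HC1 sandwich (otherwise homoskedastic).
#' @param weak_f_floor Flag threshold for the first-stage F.
#' @param outcome_type `"continuous"` or `"binary"`; binary results carry
#'   risk-difference scale tags downstream.
#' @param outcome_name,stratum,split Provenance labels.
#' @return An `mr_estimate` with method `"MR-2SLS"`, carrying the robust
#'   first-stage F and a `weak_instrument` attribute.
#' @export
iv_estimate <- function(outcome, exposure, instrument, covariates = NULL,
                        data = NULL, robust = TRUE, weak_f_floor = 10,
                        outcome_type = c("continuous", "binary"),
                        outcome_name = NA_character_,
                        stratum = NA_character_, split = NA_character_) {
  outcome_type <- match.arg(outcome_type)
  y <- .resolve_col(outcome, data)
  x <- .resolve_col(exposure, data)
  z <- .resolve_col(instrument, data)
  keep <- !is.na(y) & !is.na(x) & !is.na(z)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; x <- x[keep]; z <- z[keep]
  if (stats::sd(y) == 0) stop("iv_estimate: outcome is constant")
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(y)

  Z <- cbind(`(Intercept)` = 1, instrument = z, C)
  Xm <- cbind(`(Intercept)` = 1, exposure = x, C)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("iv_estimate: collinear instrument/covariates")
  z_proj <- qr.resid(qr(cbind(rep(1, n), C)), z)
  if (stats::sd(z_proj) < 1e-12) {
    stop("iv_estimate: instrument is constant after covariate projection")
  }
  Xhat <- qr.fitted(qrZ, Xm)
  XtX <- crossprod(Xhat)
  b <- solve(XtX, crossprod(Xhat, y))
  u <- as.numeric(y - Xm %*% b)
  k <- ncol(Xm)
  V <- if (robust) {
    .hc1_vcov(Xhat, u)
  } else {
    solve(XtX) * sum(u^2) / (n - k)
  }
  se <- unname(sqrt(diag(V))[2L])
  fstat <- first_stage_f(x, z, C, robust = robust)
  est <- mr_estimate(as.numeric(b[2L]), se, n = n, method = "MR-2SLS",
                     outcome = outcome_name, stratum = stratum, split = split,
                     outcome_type = outcome_type, scale = "per_unit",
                     f_stat = fstat)
  attr(est, "weak_instrument") <- is.finite(fstat) && fstat < weak_f_floor
  est
}

#' Multivariable-adjusted (observational) estimate
#'
#' Least-squares coefficient of the outcome on the exposure plus
#' covariates, with HC1-robust SE: the no-instrument comparator to
#' [iv_estimate()].  Binary outcomes are linear probability models.
#'
#' @inheritParams iv_estimate
#' @return An `mr_estimate` with method `"multivariable-OLS"`.
#' @export
multivariable_estimate <- function(outcome, exposure, covariates = NULL,
                                   data = NULL, robust = TRUE,
                                   outcome_type = c("continuous", "binary"),
                                   outcome_name = NA_character_,
                                   stratum = NA_character_,
                                   split = NA_character_) {
  outcome_type <- match.arg(outcome_type)
  y <- .resolve_col(outcome, data)
  x <- .resolve_col(exposure, data)
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; x <- x[keep]
  if (stats::sd(y) == 0) stop("multivariable_estimate: outcome is constant")
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  Xm <- cbind(`(Intercept)` = 1, exposure = x, C)
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    stop("multivariable_estimate: collinear covariates")
  }
  b <- qr.coef(qrX, y)
  u <- as.numeric(qr.resid(qrX, y))
  n <- length(y); k <- ncol(Xm)
  V <- if (robust) .hc1_vcov(Xm, u) else {
    solve(crossprod(Xm)) * sum(u^2) / (n - k)
  }
  mr_estimate(as.numeric(b[2L]), unname(sqrt(diag(V))[2L]), n = n,
              method = "multivariable-OLS", outcome = outcome_name,
              stratum = stratum, split = split, outcome_type = outcome_type,
              scale = "per_unit")
}

#' Robust first-stage F statistic for a single instrument
#'
#' The exposure is regressed on the score plus covariates; with one
#' excluded instrument the robust F equals `(beta1 / robust SE1)^2`.  An
#' exact linear relation between exposure and score yields `Inf`.
#'
#' @param exposure,score Numeric vectors.
#' @param covariates Optional covariate matrix.
#' @param robust Use the HC1 sandwich.
#' @return The F statistic (possibly `Inf`).
#' @export
first_stage_f <- function(exposure, score, covariates = NULL, robust = TRUE) {
  keep <- !is.na(exposure) & !is.na(score)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- exposure[keep]; z <- score[keep]
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  Xm <- cbind(`(Intercept)` = 1, score = z, C)
  qrX <- qr(Xm)
  b <- qr.coef(qrX, x)
  u <- as.numeric(qr.resid(qrX, x))
  if (sum(u^2) < 1e-12 * sum(x^2)) return(Inf)
  n <- length(x); k <- ncol(Xm)
  V <- if (robust) .hc1_vcov(Xm, u) else {
    solve(crossprod(Xm)) * sum(u^2) / (n - k)
  }
  as.numeric((b[2L] / sqrt(diag(V)[2L]))^2)
}

.check_same_scale <- function(e1, e2, what) {
  if (!identical(e1$scale, e2$scale)) {
    stop(sprintf("%s: estimates are on different scales ('%s' vs '%s')",
                 what, e1$scale, e2$scale))
  }
}

#' Fisher z test for a difference between two estimates
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, two-sided p from the standard
#' normal.  Assumes independence of the two estimates; when applied to MR
#' and multivariable estimates from the same individuals that assumption
#' is only approximate (a documented limitation, applied as specified).
#'
#' @param est1,est2 `mr_estimate` or `mr_meta` objects on the same scale.
#' @return An `mr_comparison` (statistic, two-sided p, test name).
#' @export
fisher_difference_test <- function(est1, est2) {
  .check_same_scale(est1, est2, "fisher_difference_test")
  z <- (est1$beta - est2$beta) / sqrt(est1$se^2 + est2$se^2)
  structure(list(statistic = z, p = 2 * stats::pnorm(-abs(z)),
                 test = "Fisher", estimates = list(est1, est2)),
            class = "mr_comparison")
}

#' Hausman test comparing IV and OLS estimates
#'
#' `(b_IV - b_OLS)^2 / (se_IV^2 - se_OLS^2)`, p from chi-squared with one
#' degree of freedom.  If the variance difference is not positive the test
#' is reported as undefined (statistic `NA` with a reason), not an error.
#'
#' @param iv,ols `mr_estimate`s for the same outcome and split.
#' @return An `mr_comparison` with test name `"Hausman"`.
#' @export
hausman_test <- function(iv, ols) {
  .check_same_scale(iv, ols, "hausman_test")
  vd <- iv$se^2 - ols$se^2
  if (!is.finite(vd) || vd <= 0) {
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          test = "Hausman",
                          note = "undefined: Var(IV) <= Var(OLS)",
                          estimates = list(iv, ols)),
                     class = "mr_comparison"))
  }
  stat <- (iv$beta - ols$beta)^2 / vd
  structure(list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 test = "Hausman", estimates = list(iv, ols)),
            class = "mr_comparison")
}

#' @export
print.mr_comparison <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat(sprintf("%s test: %s\n", x$test, x$note))
  } else {
    cat(sprintf("%s test: statistic = %.4g, two-sided p = %.3g\n",
                x$test, x$statistic, x$p))
  }
  invisible(x)
}

#' Fixed-effect meta-analysis of estimates
#'
#' Inverse-variance weights `w_i = 1/se_i^2`; pooled beta is the weighted
#' mean, pooled SE `1/sqrt(sum w)`.  Cochran's Q across the components is
#' reported.  An infinite component SE contributes zero weight.
#'
#' @param estimates List of two or more `mr_estimate`s on the same outcome
#'   and scale.
#' @return An `mr_meta`: pooled estimate plus components and Q.
#' @export
meta_fixed <- function(estimates) {
  stopifnot(length(estimates) >= 2L)
  scales <- vapply(estimates, `[[`, "", "scale")
  if (length(unique(scales)) != 1L) {
    stop("meta_fixed: estimates are on different scales")
  }
  b <- vapply(estimates, `[[`, 0, "beta")
  se <- vapply(estimates, `[[`, 0, "se")
  if (any(se <= 0)) stop("meta_fixed: SEs must be positive")
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (b - pooled)^2)
  z <- pooled / pooled_se
  structure(list(
    beta = pooled, se = pooled_se,
    ci = c(lower = pooled - CI_Z * pooled_se,
           upper = pooled + CI_Z * pooled_se),
    p = 2 * stats::pnorm(-abs(z)),
    q = q, q_df = length(b) - 1L,
    q_p = stats::pchisq(q, length(b) - 1L, lower.tail = FALSE),
    n = sum(vapply(estimates, `[[`, 0L, "n")),
    method = paste0("meta-", estimates[[1L]]$method),
    outcome = estimates[[1L]]$outcome,
    stratum = estimates[[1L]]$stratum,
    split = "meta",
    outcome_type = estimates[[1L]]$outcome_type,
    scale = scales[1L],
    f_stat = NA_real_,
    components = estimates
  ), class = c("mr_meta", "mr_estimate"))
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d estimates (%s)\n",
              length(x$components), x$method))
  cat(sprintf("  pooled beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  heterogeneity Q = %.4g (df %d, p = %.3g)\n",
              x$q, x$q_df, x$q_p))
  invisible(x)
}

#' Express an estimate per SD of the exposure
#'
#' Beta, SE and CI are multiplied by the exposure SD; binary-outcome
#' estimates are additionally multiplied by 100 so they read as absolute
#' percentage-point changes per SD, and the scale tag is updated.
#'
#' @param est An `mr_estimate` (or `mr_meta`) on the raw per-unit scale.
#' @param exposure_sd SD of the exposure (positive), estimated within the
#'   relevant stratum.
#' @return The rescaled estimate.
#' @export
standardize_per_sd <- function(est, exposure_sd) {
  stopifnot(inherits(est, "mr_estimate"))
  if (!is.finite(exposure_sd) || exposure_sd <= 0) {
    stop("standardize_per_sd: exposure_sd must be positive")
  }
  fac <- exposure_sd * if (identical(est$outcome_type, "binary")) 100 else 1
  est$beta <- est$beta * fac
  est$se <- est$se * fac
  est$ci <- est$ci * fac
  est$scale <- if (identical(est$outcome_type, "binary")) "pp_per_sd" else "per_sd"
  est
}

#' Flatten estimates into the results-table schema
#'
#' @param ... `mr_estimate` / `mr_meta` objects (or lists of them).
#' @return Data frame with columns outcome, stratum, split, method, beta,
#'   se, ci_low, ci_high, p, n, scale, f_stat.
#' @export
estimates_table <- function(...) {
  ests <- unlist(list(...), recursive = FALSE)
  if (inherits(ests, "mr_estimate")) ests <- list(ests)
  rows <- lapply(ests, function(e) {
    data.frame(outcome = e$outcome, stratum = e$stratum, split = e$split,
               method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci[1], ci_high = e$ci[2], p = e$p, n = e$n,
               scale = e$scale, f_stat = e$f_stat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
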