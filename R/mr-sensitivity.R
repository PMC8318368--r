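# Two-sample, summary-statistic MR estimators and pleiotropy diagnostics:
# harmonization, IVW, MR-Egger, weighted median, weighted mode, Cochran's Q.
#
# Wald-ratio SEs are first order (se_outcome / |beta_exposure|, exposure-
# side uncertainty ignored: the standard NOME-style simplification), so
# IVW is algebraically identical to a fixed-effect meta-analysis of the
# per-SNP ratios.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs by id, re-orients outcome effects to the exposure's effect
#' allele (sign-flipping the outcome beta and reflecting its EAF when the
#' allele pair is swapped, allowing for strand complements), and drops
#' non-overlapping or irreconcilable SNPs with a per-SNP reason log.
#' Palindromic (A/T, C/G) SNPs are retained by default — strand is
#' unambiguous in simulated data — and dropped under `strict = TRUE` for
#' real-format inputs.  SNPs with a zero exposure beta are dropped (the
#' Wald ratio is undefined).
#'
#' @param exposure,outcome `sumstats` tables.
#' @param strict Drop palindromic SNPs.
#' @return A `harmonized_set` data frame: per SNP, beta/se on both sides,
#'   the shared effect allele, Wald `ratio`, first-order `ratio_se` and
#'   inverse-variance `weight`; the drop log is in attribute `dropped`.
#' @export
harmonize <- function(exposure, outcome, strict = FALSE) {
  validate_sumstats(exposure)
  validate_sumstats(outcome)
  m <- match(exposure$snp_id, outcome$snp_id)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note_drop <- function(ids, why) {
    if (length(ids) == 0L) return(dropped)
    rbind(dropped, data.frame(snp_id = ids, reason = why,
                              stringsAsFactors = FALSE))
  }
  dropped <- note_drop(exposure$snp_id[is.na(m)], "absent from outcome")
  ex <- as.data.frame(exposure)[!is.na(m), , drop = FALSE]
  ou <- as.data.frame(outcome)[m[!is.na(m)], , drop = FALSE]

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  flip_same <- .complement[ex$effect_allele] == ou$effect_allele &
    .complement[ex$other_allele] == ou$other_allele
  flip_swap <- .complement[ex$effect_allele] == ou$other_allele &
    .complement[ex$other_allele] == ou$effect_allele
  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)
  # for palindromic SNPs "strand flip" and "swap" are indistinguishable;
  # treat them as same-orientation (simulated strands are unambiguous)
  ok_same <- same | (flip_same & !pal)
  ok_swap <- (swap | (flip_swap & !pal)) & !ok_same
  bad <- !(ok_same | ok_swap)
  if (any(bad)) dropped <- note_drop(ex$snp_id[bad], "irreconcilable alleles")
  if (strict && any(pal & !bad)) {
    dropped <- note_drop(ex$snp_id[pal & !bad], "palindromic (strict)")
    bad <- bad | pal
  }
  keep <- !bad
  ex <- ex[keep, , drop = FALSE]; ou <- ou[keep, , drop = FALSE]
  sgn <- ifelse(ok_swap[keep], -1, 1)
  bo <- sgn * ou$beta
  zero <- ex$beta == 0
  if (any(zero)) {
    dropped <- note_drop(ex$snp_id[zero], "zero exposure beta")
  }
  ex <- ex[!zero, , drop = FALSE]; ou <- ou[!zero, , drop = FALSE]
  bo <- bo[!zero]

  h <- data.frame(
    snp_id = ex$snp_id,
    effect_allele = ex$effect_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = bo,
    se_outcome = ou$se,
    stringsAsFactors = FALSE
  )
  h$ratio <- h$beta_outcome / h$beta_exposure
  h$ratio_se <- h$se_outcome / abs(h$beta_exposure)
  h$weight <- 1 / h$ratio_se^2
  structure(h, class = c("harmonized_set", "data.frame"), dropped = dropped)
}

.as_harmonized <- function(h) {
  stopifnot(all(c("beta_exposure", "se_exposure", "beta_outcome",
                  "se_outcome") %in% names(h)))
  if (is.null(h$ratio)) h$ratio <- h$beta_outcome / h$beta_exposure
  if (is.null(h$ratio_se)) h$ratio_se <- h$se_outcome / abs(h$beta_exposure)
  if (is.null(h$weight)) h$weight <- 1 / h$ratio_se^2
  h
}

new_mr_method_result <- function(method, beta, se, n_snp, df = NA,
                                 use_t = FALSE, extra = list()) {
  z <- beta / se
  p <- if (use_t) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  structure(c(list(
    method = method, beta = beta, se = se,
    ci = c(lower = beta - CI_Z * se, upper = beta + CI_Z * se),
    p = p, n_snp = n_snp
  ), extra), class = "mr_method_result")
}

#' @export
print.mr_method_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g (%d SNPs)\n",
              x$method, x$beta, x$se, x$ci[1], x$ci[2], x$p, x$n_snp))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.4g (df %d, p = %.3g)\n",
                x$q, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Slope of the zero-intercept weighted regression of outcome betas on
#' exposure betas with weights `1/se_outcome^2` — algebraically the
#' precision-weighted mean of the Wald ratios under first-order SEs.
#' Cochran's Q about the slope is reported; when `Q/df > 1` the SE is
#' inflated multiplicatively by `sqrt(Q/df)` (never deflated).
#'
#' @param h A `harmonized_set` (at least one SNP).
#' @return An `mr_method_result` with fields `q`, `q_df`, `q_p`.
#' @export
ivw <- function(h) {
  h <- .as_harmonized(h)
  if (nrow(h) < 1L) stop("ivw: empty harmonized set")
  w <- 1 / h$se_outcome^2
  beta <- sum(w * h$beta_exposure * h$beta_outcome) /
    sum(w * h$beta_exposure^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exposure^2))
  k <- nrow(h)
  q <- sum(h$weight * (h$ratio - beta)^2)
  infl <- if (k > 1L) max(1, sqrt(q / (k - 1L))) else 1
  new_mr_method_result(
    "IVW", beta, se_fixed * infl, k,
    extra = list(q = q, q_df = max(k - 1L, 0L),
                 q_p = if (k > 1L) stats::pchisq(q, k - 1L, lower.tail = FALSE)
                 else NA_real_)
  )
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas WITH a free
#' intercept (weights `1/se_outcome^2`), after orienting every exposure
#' beta positive (outcome betas flipped with them).  The slope is the
#' causal estimate; a non-zero intercept indicates directional pleiotropy.
#' SEs use multiplicative random-effects scaling (residual sigma floored
#' at 1) and p-values the t distribution with `k - 2` df.
#'
#' @param h A `harmonized_set` with at least three SNPs.
#' @return An `mr_method_result` with `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
egger <- function(h) {
  h <- .as_harmonized(h)
  k <- nrow(h)
  if (k < 3L) stop("egger: at least 3 SNPs required")
  sgn <- sign(h$beta_exposure)
  bx <- h$beta_exposure * sgn
  by <- h$beta_outcome * sgn
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # fixed-effect SE = lm SE / sigma; inflate back only when sigma > 1
  scale <- max(1, sm$sigma) / sm$sigma
  slope_se <- sm$coefficients["bx", "Std. Error"] * scale
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * scale
  slope <- sm$coefficients["bx", "Estimate"]
  int <- sm$coefficients["(Intercept)", "Estimate"]
  new_mr_method_result(
    "MR-Egger", slope, slope_se, k, df = k - 2L, use_t = TRUE,
    extra = list(intercept = int, intercept_se = int_se,
                 intercept_p = 2 * stats::pt(-abs(int / int_se), k - 2L))
  )
}

.weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]; w <- weight[o] / sum(weight)
  cw <- cumsum(w) - w / 2
  if (cw[1L] >= 0.5) return(r[1L])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

# run expr under a fixed seed, restoring the caller's RNG stream after
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.parametric_boot <- function(h, point_fun, n_boot, seed) {
  .with_seed(stage_seed(seed, "boot"), .parametric_boot_impl(h, point_fun,
                                                             n_boot))
}

.parametric_boot_impl <- function(h, point_fun, n_boot) {
  reps <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(h), h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(nrow(h), h$beta_outcome, h$se_outcome)
    bx[bx == 0] <- 1e-12
    point_fun(by / bx, (abs(bx) / h$se_outcome)^2)
  }, 0)
  stats::sd(reps)
}

#' Weighted-median MR estimate
#'
#' Wald ratios are ordered; with standardized cumulative weights
#' `p_j = (sum_{i<=j} w_i - w_j/2) / sum w`, the estimate is the linear
#' interpolation of the ratios at `p = 0.5`.  Consistent when at least
#' half the total weight comes from valid instruments.  The SE is a seeded
#' parametric bootstrap over the summary statistics.
#'
#' @param h A `harmonized_set` with at least three SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_method_result`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  h <- .as_harmonized(h)
  if (nrow(h) < 3L) stop("weighted_median: at least 3 SNPs required")
  beta <- .weighted_median_point(h$ratio, h$weight)
  se <- .parametric_boot(h, .weighted_median_point, n_boot, seed)
  new_mr_method_result("weighted-median", beta, se, nrow(h),
                       extra = list(n_boot = n_boot, seed = seed))
}

.weighted_mode_point <- function(ratio, weight, bandwidth_factor = 1) {
  spread <- stats::mad(ratio)
  if (spread == 0) return(stats::median(ratio))
  bw <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  d <- stats::density(ratio, weights = weight / sum(weight), bw = bw,
                      n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted-mode MR estimate
#'
#' The estimate is the argmax of a weight-scaled normal-kernel density
#' over the Wald ratios; the bandwidth is `bandwidth_factor` times a
#' median-absolute-deviation-based spread (Silverman-style scaling).
#' Consistent when the largest group of instruments sharing one ratio is
#' valid.  Zero spread returns the common ratio; SE by seeded parametric
#' bootstrap.
#'
#' @param h A `harmonized_set` with at least three SNPs.
#' @param bandwidth_factor Kernel bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return An `mr_method_result`.
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  h <- .as_harmonized(h)
  if (nrow(h) < 3L) stop("weighted_mode: at least 3 SNPs required")
  beta <- .weighted_mode_point(h$ratio, h$weight, bandwidth_factor)
  se <- .parametric_boot(
    h, function(r, w) .weighted_mode_point(r, w, bandwidth_factor),
    n_boot, seed
  )
  new_mr_method_result("weighted-mode", beta, se, nrow(h),
                       extra = list(bandwidth_factor = bandwidth_factor,
                                    n_boot = n_boot, seed = seed))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (ratio_i - beta_ref)^2` over the per-SNP Wald ratios with
#' inverse-variance weights; df `k - 1`, p from chi-squared.
#'
#' @param h A `harmonized_set` with at least two SNPs.
#' @param beta_ref Reference estimate (default: the IVW slope).
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(h, beta_ref = NULL) {
  h <- .as_harmonized(h)
  if (nrow(h) < 2L) stop("cochran_q: at least 2 SNPs required")
  if (is.null(beta_ref)) beta_ref <- ivw(h)$beta
  q <- sum(h$weight * (h$ratio - beta_ref)^2)
  df <- nrow(h) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Run the full two-sample sensitivity suite
#'
#' IVW, MR-Egger (when at least 3 SNPs), weighted median and weighted mode
#' on one harmonized set, plus a per-SNP diagnostics table (ratio, weight,
#' leave-one-out IVW).
#'
#' @param h A `harmonized_set`.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Integer seed.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @return List with `results` (list of `mr_method_result`) and
#'   `snp_diagnostics` (data frame).
#' @export
mr_sensitivity_suite <- function(h, n_boot = 1000, seed = 1L,
                                 bandwidth_factor = 1) {
  h <- .as_harmonized(h)
  res <- list(ivw = ivw(h))
  if (nrow(h) >= 3L) {
    res$egger <- egger(h)
    res$weighted_median <- weighted_median(h, n_boot, seed)
    res$weighted_mode <- weighted_mode(h, bandwidth_factor, n_boot, seed)
  }
  loo <- if (nrow(h) > 2L) {
    vapply(seq_len(nrow(h)), function(i) ivw(h[-i, ])$beta, 0)
  } else rep(NA_real_, nrow(h))
  list(
    results = res,
    snp_diagnostics = data.frame(
      snp_id = if (!is.null(h$snp_id)) h$snp_id else seq_len(nrow(h)),
      ratio = h$ratio, weight = h$weight, loo_ivw = loo,
      stringsAsFactors = FALSE
    )
  )
}
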