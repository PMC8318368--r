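# Two-sample summary-statistic estimators and diagnostics.

.mk_ss <- function(ids, ea, oa, beta, se, chr = 1L) {
  k <- length(ids)
  ss <- data.frame(snp_id = ids, chr = chr, pos = seq_len(k) * 1000L,
                   effect_allele = ea, other_allele = oa,
                   eaf = 0.3, beta = beta, se = se,
                   p = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = 1000L,
                   stringsAsFactors = FALSE)
  class(ss) <- c("sumstats", "data.frame")
  ss
}

test_that("harmonization aligns effect alleles and logs drops", {
  ids <- c("s1", "s2", "s3", "s4")
  ex <- .mk_ss(ids, c("A", "A", "C", "A"), c("G", "G", "G", "T"),
               beta = c(0.1, 0.2, 0.3, 0.4), se = 0.05)
  # s1 identical, s2 swapped alleles, s3 identical, s4 palindromic
  ou <- .mk_ss(ids, c("A", "G", "C", "A"), c("G", "A", "G", "T"),
               beta = c(1, 1, 1, 1), se = 0.1)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_outcome, c(1, -1, 1, 1))  # hand-aligned table
  expect_equal(h$ratio, c(1, -1, 1, 1) / c(0.1, 0.2, 0.3, 0.4))
  expect_equal(h$ratio_se, 0.1 / abs(c(0.1, 0.2, 0.3, 0.4)))

  # strict mode drops the palindromic SNP
  h2 <- harmonize(ex, ou, strict = TRUE)
  expect_false("s4" %in% h2$snp_id)
  expect_true("s4" %in% attr(h2, "dropped")$snp_id)

  # irreconcilable allele pair dropped with reason; missing SNP logged
  ou_bad <- .mk_ss(c("s1", "s2", "s3"), c("A", "C", "C"), c("G", "A", "G"),
                   beta = 1, se = 0.1)
  h3 <- harmonize(ex, ou_bad)
  d <- attr(h3, "dropped")
  expect_true(any(d$snp_id == "s2" & d$reason == "irreconcilable alleles"))
  expect_true(any(d$snp_id == "s4" & d$reason == "absent from outcome"))
  expect_equal(h3$snp_id, c("s1", "s3"))

  # zero exposure beta cannot form a Wald ratio
  ex0 <- .mk_ss("s1", "A", "G", beta = 0, se = 0.05)
  ou0 <- .mk_ss("s1", "A", "G", beta = 1, se = 0.1)
  expect_equal(nrow(harmonize(ex0, ou0)), 0)
})

test_that("IVW matches the weighted zero-intercept regression oracle", {
  h <- data.frame(beta_exposure = c(0.1, 0.2, 0.4), se_exposure = 0.01,
                  beta_outcome = c(0.06, 0.10, 0.18), se_outcome = 0.01)
  res <- ivw(h)
  expect_equal(res$beta, 0.098 / 0.21, tolerance = 1e-12)

  # constant ratios: estimate is the ratio, Q = 0
  hc <- data.frame(beta_exposure = c(0.1, 0.2, 0.3), se_exposure = 0.01,
                   beta_outcome = 0.5 * c(0.1, 0.2, 0.3), se_outcome = 0.02)
  resc <- ivw(hc)
  expect_equal(resc$beta, 0.5, tolerance = 1e-12)
  expect_equal(resc$q, 0, tolerance = 1e-20)

  # single SNP: the Wald ratio itself
  h1 <- data.frame(beta_exposure = 0.25, se_exposure = 0.01,
                   beta_outcome = 0.1, se_outcome = 0.05)
  expect_equal(ivw(h1)$beta, 0.4, tolerance = 1e-12)
  expect_error(ivw(h1[0, ]), "empty")
})

test_that("IVW is fixed-effect meta-analysis of the Wald ratios", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    bx <- runif(k, 0.1, 0.4)
    by <- 0.3 * bx + rnorm(k, sd = 1e-4)  # tiny spread: Q/df < 1
    so <- runif(k, 0.01, 0.05)
    h <- data.frame(beta_exposure = bx, se_exposure = 0.01,
                    beta_outcome = by, se_outcome = so)
    res <- ivw(h)
    ratios <- by / bx
    rse <- so / abs(bx)
    meta <- meta_fixed(lapply(seq_len(k), function(j) {
      mr_estimate(ratios[j], rse[j])
    }))
    expect_equal(res$beta, meta$beta, tolerance = 1e-10)
    if (res$q < k - 1) expect_equal(res$se, meta$se, tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relation and flips orientation", {
  bx <- c(0.1, -0.2, 0.3, 0.15, -0.25)
  # affine in the positively oriented exposure betas
  by_pos <- 0.02 + 0.5 * abs(bx)
  by <- by_pos * sign(bx) * 0 + ifelse(bx < 0, -0, 0) + by_pos
  # orientation: flipping a SNP's (bx, by) signs must not change results
  h <- data.frame(beta_exposure = abs(bx), se_exposure = 0.01,
                  beta_outcome = by_pos, se_outcome = c(0.01, 0.02, 0.01, 0.03, 0.02))
  res <- egger(h)
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_equal(res$intercept, 0.02, tolerance = 1e-10)

  h_flip <- h
  h_flip$beta_exposure[2] <- -h$beta_exposure[2]
  h_flip$beta_outcome[2] <- -h$beta_outcome[2]
  res_flip <- egger(h_flip)
  expect_equal(res_flip$beta, res$beta, tolerance = 1e-12)
  expect_equal(res_flip$intercept, res$intercept, tolerance = 1e-12)

  expect_error(egger(h[1:2, ]), "3 SNPs")
})

test_that("weighted median interpolates the 50% weight point", {
  h <- data.frame(beta_exposure = c(1, 1, 1), se_exposure = 0.01,
                  beta_outcome = c(1, 2, 3), se_outcome = 1)
  res <- weighted_median(h, n_boot = 50, seed = 4)
  expect_equal(res$beta, 2, tolerance = 1e-12)

  # a SNP holding > 50% of the weight pins the estimate near its ratio
  hd <- data.frame(beta_exposure = c(1, 1, 1, 1), se_exposure = 0.01,
                   beta_outcome = c(5, 0.5, 0.52, 0.48),
                   se_outcome = c(0.05, 1, 1, 1))
  resd <- weighted_median(hd, n_boot = 50, seed = 4)
  expect_lt(abs(resd$beta - 5), 0.5)

  # seeded bootstrap is reproducible
  r1 <- weighted_median(h, n_boot = 200, seed = 9)
  r2 <- weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(r1$se, r2$se)
  expect_error(weighted_median(h[1:2, ]), "3 SNPs")
})

test_that("weighted mode finds the dominant ratio cluster", {
  h <- data.frame(beta_exposure = rep(1, 6), se_exposure = 0.01,
                  beta_outcome = c(0.49, 0.5, 0.51, 0.5, 0.52, 5),
                  se_outcome = c(rep(0.05, 5), 1))
  res <- weighted_mode(h, n_boot = 50, seed = 2)
  expect_lt(abs(res$beta - 0.5), 0.1)

  # all ratios identical: that value with ~zero SE
  hc <- data.frame(beta_exposure = c(1, 2, 4), se_exposure = 0.01,
                   beta_outcome = c(0.3, 0.6, 1.2), se_outcome = 0.05)
  resc <- weighted_mode(hc, n_boot = 50, seed = 2)
  expect_equal(resc$beta, 0.3, tolerance = 1e-10)

  r1 <- weighted_mode(h, n_boot = 100, seed = 7)
  r2 <- weighted_mode(h, n_boot = 100, seed = 7)
  expect_identical(r1$se, r2$se)

  # grid-argmax oracle on a denser configuration
  set.seed(12)
  hg <- data.frame(beta_exposure = rep(1, 15), se_exposure = 0.01,
                   beta_outcome = c(rnorm(12, 0.5, 0.02), 2, 2.1, 3),
                   se_outcome = 0.05)
  resg <- weighted_mode(hg, n_boot = 20, seed = 3)
  ratio <- hg$beta_outcome; w <- (1 / (hg$se_outcome / abs(hg$beta_exposure))^2)
  bw <- 0.9 * mad(ratio) * length(ratio)^(-0.2)
  grid <- seq(min(ratio) - 1, max(ratio) + 1, length.out = 20000)
  dens <- sapply(grid, function(g0) sum(w * dnorm((g0 - ratio) / bw)))
  expect_equal(resg$beta, grid[which.max(dens)], tolerance = 0.01)
})

test_that("Cochran's Q matches hand computation and is order-invariant", {
  # ratios 0.4 and 0.6 with ratio weights 100 about their IVW mean 0.5
  h <- data.frame(beta_exposure = c(1, 1), se_exposure = 0.01,
                  beta_outcome = c(0.4, 0.6), se_outcome = 0.1)
  cq <- cochran_q(h)
  expect_equal(cq$q, 2.0, tolerance = 1e-10)
  expect_equal(cq$df, 1)

  # equal ratios: Q = 0, p = 1
  h0 <- data.frame(beta_exposure = c(0.2, 0.4), se_exposure = 0.01,
                   beta_outcome = c(0.1, 0.2), se_outcome = 0.05)
  cq0 <- cochran_q(h0)
  expect_equal(cq0$q, 0, tolerance = 1e-20)
  expect_equal(cq0$p, 1)

  hp <- h[2:1, ]
  expect_equal(cochran_q(hp)$q, cq$q, tolerance = 1e-12)
  expect_error(cochran_q(h[1, ]), "2 SNPs")
})

test_that("estimators center on truth with valid instruments, median resists invalids", {
  set.seed(61)
  n_rep <- 200
  res <- replicate(n_rep, {
    # near-noiseless exposure side so NOME holds and dilution is negligible
    h <- sim_sumstats_pair(k = 30, b = 0.3, se_x = 0.002)
    c(ivw = ivw(h)$beta, egger = egger(h)$beta,
      med = .wm <- weighted_median(h, n_boot = 2, seed = 1)$beta)
  })
  expect_lt(abs(mean(res["ivw", ]) - 0.3), 0.01)
  expect_lt(abs(mean(res["egger", ]) - 0.3), 0.05)
  expect_lt(abs(mean(res["med", ]) - 0.3), 0.02)

  # 40% invalid instruments with directional pleiotropy: IVW biased,
  # weighted median stays near truth
  res2 <- replicate(n_rep, {
    k <- 50
    gx <- runif(k, 0.05, 0.2)
    alpha <- c(rep(0.05, 20), rep(0, 30))  # 40% invalid, directional
    h <- data.frame(beta_exposure = rnorm(k, gx, 0.002), se_exposure = 0.002,
                    beta_outcome = rnorm(k, 0.3 * gx + alpha, 0.02),
                    se_outcome = 0.02)
    c(ivw = ivw(h)$beta,
      med = weighted_median(h, n_boot = 2, seed = 1)$beta)
  })
  bias_ivw <- abs(mean(res2["ivw", ]) - 0.3)
  bias_med <- abs(mean(res2["med", ]) - 0.3)
  expect_gt(bias_ivw, 0.05)
  expect_lt(bias_med, bias_ivw)  # qualitative ordering
})

test_that("sensitivity suite returns all methods and leave-one-out rows", {
  set.seed(71)
  h <- sim_sumstats_pair(k = 12, b = 0.2)
  out <- mr_sensitivity_suite(h, n_boot = 30, seed = 5)
  expect_setequal(names(out$results),
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  expect_equal(nrow(out$snp_diagnostics), 12)
  expect_true(all(is.finite(out$snp_diagnostics$loo_ivw)))
  # Egger carries an intercept; IVW does not
  expect_false(is.null(out$results$egger$intercept))
  expect_true(is.null(out$results$ivw$intercept))
})
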