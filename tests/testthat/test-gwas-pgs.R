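# Split-sample design, per-SNP GWAS, clumping, polygenic scores.

test_that("split_sample partitions each stratum into near-equal halves", {
  co <- demo_cohort()
  halves <- split_sample(co, seed = 42)
  e1 <- halves$split1$phenotypes$eid
  e2 <- halves$split2$phenotypes$eid
  expect_length(intersect(e1, e2), 0)
  expect_setequal(c(e1, e2), co$phenotypes$eid)
  for (s in unique(co$phenotypes$stratum)) {
    n1 <- sum(halves$split1$phenotypes$stratum == s)
    n2 <- sum(halves$split2$phenotypes$stratum == s)
    expect_lte(abs(n1 - n2), 1)
  }
  # deterministic under the seed
  again <- split_sample(co, seed = 42)
  expect_identical(again$split1$phenotypes$eid, e1)
  other <- split_sample(co, seed = 43)
  expect_false(identical(other$split1$phenotypes$eid, e1))
})

test_that("split_sample rejects strata too small to halve", {
  co <- demo_cohort()
  tiny <- subset_idx <- which(co$phenotypes$stratum == "men")[1]
  sub <- co
  sub$phenotypes <- rbind(
    co$phenotypes[co$phenotypes$stratum == "premenopausal", ],
    co$phenotypes[tiny, ]
  )
  sub$genotypes <- co$genotypes[sub$phenotypes$eid, ]
  expect_error(split_sample(sub, 1), "fewer than 2")
})

test_that("noise-free phenotype gives an exact per-SNP fit", {
  set.seed(9)
  g <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  ph <- data.frame(eid = sprintf("i%02d", 1:20))
  co <- manual_cohort(g, ph)
  ss <- run_gwas(co, 0.5 * g[, 1])
  expect_equal(ss$beta[1], 0.5, tolerance = 1e-10)
  expect_lt(ss$se[1], 1e-6)
  expect_equal(ss$n[1], 20)
})

test_that("GWAS beta/SE/p match the least-squares oracle on a toy table", {
  g <- matrix(c(0, 1, 2, 1, 0,
                2, 2, 0, 1, 1), 5, 2)
  cov1 <- matrix(c(1.2, -0.5, 0.3, 0.9, -1.1), 5, 1,
                 dimnames = list(NULL, "z"))
  y <- c(2.1, 1.4, 3.3, 0.7, 1.9)
  co <- manual_cohort(g, data.frame(eid = paste0("i", 1:5)))
  ss <- run_gwas(co, y, cov1)
  for (j in 1:2) {
    fit <- summary(lm(y ~ g[, j] + cov1))
    expect_equal(ss$beta[j], fit$coefficients[2, "Estimate"],
                 tolerance = 1e-10)
    expect_equal(ss$se[j], fit$coefficients[2, "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(ss$p[j], fit$coefficients[2, "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("null SNPs show nominal type-I error and uniform-ish p", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 400, n_causal = 0,
                    h2_score = 0, n_pcs = 2, strata_props = c(1, 0, 0),
                    seed = 77)
  co <- simulate_cohort(cfg)
  set.seed(123)
  y <- rnorm(nrow(co$genotypes))
  ss <- run_gwas(co, y)
  frac <- mean(ss$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(ss)))
})

test_that("GWAS rejects rank-deficient covariates and skips constant SNPs", {
  g <- cbind(matrix(sample(0:2, 30, TRUE), 15, 2), 1L)  # third SNP constant
  co <- manual_cohort(g, data.frame(eid = paste0("i", 1:15)))
  y <- rnorm(15)
  bad_cov <- cbind(a = rep(1, 15), b = rep(2, 15))
  expect_error(run_gwas(co, y, bad_cov), "rank-deficient")
  expect_warning(ss <- run_gwas(co, y), "constant")
  expect_equal(nrow(ss), 2)
})

test_that("clumping applies the p/window/r2 rule", {
  # no significant SNP -> empty set
  co <- demo_cohort()
  ph <- derive_hormones(co$phenotypes)
  null_ss <- run_gwas(co, rnorm(nrow(co$genotypes)))
  inst <- clump(null_ss, ld_accessor(co$genotypes), p_threshold = 5e-8)
  expect_equal(nrow(inst), 0)

  # two linked close SNPs: only the smaller p survives
  g <- matrix(sample(0:2, 400, TRUE), 200, 2)
  g[, 2] <- ifelse(runif(200) < 0.95, g[, 1], 2 - g[, 1])  # r2 ~ 0.8
  snps <- data.frame(snp_id = c("a", "b"), chr = 1L, pos = c(1000L, 2000L),
                     effect_allele = "A", other_allele = "G",
                     maf = colMeans(g) / 2)
  ss <- data.frame(snps, eaf = colMeans(g) / 2, beta = c(1, 0.9),
                   se = c(0.1, 0.1), p = c(1e-10, 1e-9), n = 200L)
  class(ss) <- c("sumstats", "data.frame")
  inst <- clump(ss, ld_accessor(`colnames<-`(g, c("a", "b"))))
  expect_equal(inst$snp_id, "a")
})

test_that("greedy clumping matches the exhaustive oracle on small instances", {
  set.seed(2024)
  for (rep in 1:25) {
    k <- sample(4:10, 1)
    n <- 300
    # genotypes with random pairwise linkage
    g <- matrix(sample(0:2, n * k, TRUE), n, k)
    for (j in seq(2, k, by = 2)) {
      mix <- runif(n) < runif(1, 0.5, 1)
      g[mix, j] <- g[mix, j - 1]
    }
    colnames(g) <- paste0("s", 1:k)
    ss <- data.frame(
      snp_id = colnames(g),
      chr = sample(1:2, k, TRUE),
      pos = sample.int(2e7, k),
      effect_allele = "A", other_allele = "G",
      eaf = colMeans(g) / 2,
      beta = rnorm(k), se = runif(k, 0.05, 0.2),
      p = 10^-runif(k, 2, 12),
      n = n, stringsAsFactors = FALSE
    )
    class(ss) <- c("sumstats", "data.frame")
    r2mat <- cor(g)^2
    pth <- 1e-4; win <- sample(c(100, 5000, 10000), 1); r2th <- 0.1
    got <- clump(ss, ld_accessor(g), p_threshold = pth,
                 window_kb = win, r2_threshold = r2th)
    want <- clump_oracle(ss, r2mat, pth, win, r2th)
    expect_identical(got$snp_id, want)
    # row-order invariance
    perm <- ss[sample.int(k), ]
    class(perm) <- c("sumstats", "data.frame")
    got2 <- clump(perm, ld_accessor(g), p_threshold = pth,
                  window_kb = win, r2_threshold = r2th)
    expect_identical(got2$snp_id, want)
  }
})

test_that("polygenic scores re-orient negative weights and sum correctly", {
  g <- matrix(c(2L, 1L,
                1L, 0L), 2, 2, byrow = TRUE)
  colnames(g) <- c("s1", "s2")
  inst <- data.frame(snp_id = c("s1", "s2"), weight = c(0.5, -0.2))
  # s2 re-signed: dosage flipped to 2-g, weight 0.2
  expect_equal(compute_pgs(g, inst),
               c(0.5 * 2 + 0.2 * (2 - 1), 0.5 * 1 + 0.2 * (2 - 0)))
  # permuting SNP order leaves scores unchanged
  expect_equal(compute_pgs(g, inst[2:1, ]), compute_pgs(g, inst))
  # all-zero weights -> zero
  expect_equal(compute_pgs(g, data.frame(snp_id = "s1", weight = 0)), c(0, 0))
  expect_error(compute_pgs(g, data.frame(snp_id = "nope", weight = 1)),
               "missing")
})

test_that("score_r2 identities hold at the extremes", {
  set.seed(5)
  s <- rnorm(5000)
  expect_equal(score_r2(s, s), 1, tolerance = 1e-12)
  expect_lt(score_r2(s, rnorm(5000)), 0.002)
  expect_error(score_r2(rep(1, 10), rnorm(10)), "constant")
})

test_that("a PGS built in one split is valid in the other", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 40, n_causal = 10,
                    h2_score = 0.1, n_pcs = 2, strata_props = c(1, 0, 0),
                    seed = 55)
  co <- simulate_cohort(cfg)
  co$phenotypes <- derive_hormones(co$phenotypes)
  halves <- split_sample(co, 1)
  ss <- run_gwas(halves$split1, "bioavailable_t")
  inst <- clump(ss, ld_accessor(halves$split1$genotypes), p_threshold = 1e-3)
  expect_gt(nrow(inst), 3)
  pgs <- compute_pgs(halves$split2$genotypes, inst)
  r2 <- score_r2(pgs, halves$split2$phenotypes$bioavailable_t)
  # out-of-sample score should recover close to the causal h2
  expect_lt(abs(r2 - 0.1), 0.03)
  # and the two splits' causal-SNP betas agree within combined SEs
  ss2 <- run_gwas(halves$split2, "bioavailable_t")
  gt <- co$ground_truth
  i1 <- match(gt$causal_snps, ss$snp_id)
  i2 <- match(gt$causal_snps, ss2$snp_id)
  zdiff <- abs(ss$beta[i1] - ss2$beta[i2]) /
    sqrt(ss$se[i1]^2 + ss2$se[i2]^2)
  expect_gte(mean(zdiff < 3), 0.95)
})

test_that("sumstats and instrument tables round-trip through text files", {
  co <- demo_cohort()
  ph <- derive_hormones(co$phenotypes)
  ss <- run_gwas(co, ph$bioavailable_t)
  f <- withr::local_tempfile()
  write_sumstats(ss, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr[1:10], c("snp_id", "chr", "pos", "effect_allele",
                                "other_allele", "eaf", "beta", "se", "p", "n"))
  back <- read_sumstats(f)
  expect_equal(back$beta, ss$beta)
  expect_equal(back$p, ss$p)

  inst <- clump(ss, ld_accessor(co$genotypes), p_threshold = 1e-3)
  f2 <- withr::local_tempfile()
  write_instruments(inst, f2)
  back2 <- read_instruments(f2)
  expect_equal(back2$weight, inst$weight)
  expect_equal(attr(back2, "window_kb"), attr(inst, "window_kb"))
})
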