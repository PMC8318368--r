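# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A moderate mixed-strata cohort with strong, sparse genetic architecture
# (so desk-scale GWAS clears the genome-wide threshold).
demo_cohort <- function() {
  fixture("demo_cohort", function() {
    simulate_cohort(sim_config(
      n_individuals = 4000, n_snps = 60, n_causal = 8,
      h2_score = 0.2, ld_block_size = 4, ld_rho = 0.3,
      strata_props = c(men = 0.6, premenopausal = 0.2,
                       postmenopausal = 0.2),
      n_pcs = 4, seed = 7
    ))
  })
}

# Hand-built minimal cohort wrapper around explicit genotypes/phenotypes,
# for exact-oracle regression tests.
manual_cohort <- function(genotypes, phenotypes, snps = NULL) {
  m <- ncol(genotypes)
  if (is.null(snps)) {
    snps <- data.frame(
      snp_id = paste0("s", seq_len(m)), chr = 1L,
      pos = seq_len(m) * 1000L, effect_allele = "A", other_allele = "G",
      maf = colMeans(genotypes) / 2, stringsAsFactors = FALSE
    )
  }
  colnames(genotypes) <- snps$snp_id
  rownames(genotypes) <- phenotypes$eid
  structure(list(genotypes = genotypes, snps = snps,
                 phenotypes = phenotypes, ground_truth = NULL,
                 config = sim_config(n_individuals = nrow(genotypes),
                                     n_snps = m, n_causal = 0,
                                     h2_score = 0, seed = 1)),
            class = "cohort")
}

# Independent brute-force implementation of the greedy clumping rule,
# written plainly for oracle comparisons.
clump_oracle <- function(ss, r2mat, p_threshold, window_kb, r2_threshold) {
  cand <- ss[ss$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chr, cand$pos), , drop = FALSE]
  kept <- character(0)
  alive <- rep(TRUE, nrow(cand))
  repeat {
    i <- which(alive)
    if (!length(i)) break
    top <- i[1]
    kept <- c(kept, cand$snp_id[top])
    alive[top] <- FALSE
    for (j in which(alive)) {
      same_chr <- cand$chr[j] == cand$chr[top]
      close <- abs(cand$pos[j] - cand$pos[top]) <= window_kb * 1000
      linked <- r2mat[cand$snp_id[top], cand$snp_id[j]] > r2_threshold
      if (same_chr && close && linked) alive[j] <- FALSE
    }
  }
  kept
}

# Summary statistics for a toy two-sample setting: k SNPs with true
# exposure effects gx, causal slope b, directional pleiotropy alpha.
sim_sumstats_pair <- function(k = 40, b = 0, alpha = 0, se_x = 0.01,
                              se_y = 0.02) {
  gx <- runif(k, 0.05, 0.2)
  bx <- rnorm(k, gx, se_x)
  by <- rnorm(k, b * gx + alpha, se_y)
  data.frame(beta_exposure = bx, se_exposure = se_x,
             beta_outcome = by, se_outcome = se_y)
}
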