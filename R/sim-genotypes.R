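# Genotype simulation: biallelic dosages with block-exchangeable LD.
#
# Each haplotype draws a latent Gaussian per SNP with a one-factor,
# block-exchangeable correlation structure; the allele is the indicator of
# the latent exceeding the MAF threshold, and the dosage is the sum over
# the two haplotypes.  Thresholding attenuates correlation, so the latent
# factor loading is calibrated numerically so that the DOSAGE correlation
# within a block matches the requested ld_rho (an invertible target that
# LD-clumping tests can check against).

# Correlation between two threshold indicators at allele frequency p when
# the latent correlation is l (both thresholds equal).
.threshold_corr <- function(l, p) {
  if (l <= 0) return(0)
  t <- stats::qnorm(1 - p)
  f <- function(z) {
    stats::dnorm(z) *
      stats::pnorm((sqrt(l) * z - t) / sqrt(1 - l))^2
  }
  p11 <- stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  (p11 - p^2) / (p * (1 - p))
}

# Latent correlation achieving a target dosage correlation at frequency p.
.latent_rho <- function(target, p) {
  if (target <= 0) return(0)
  stats::uniroot(function(l) .threshold_corr(l, p) - target,
                 lower = target, upper = 0.99999, tol = 1e-8)$root
}

#' Simulate biallelic genotype dosages with block LD
#'
#' Generates an `n_individuals` by `n_snps` dosage matrix (values 0/1/2)
#' with per-SNP minor allele frequencies drawn uniformly from
#' `maf_range` and block-exchangeable LD: dosage correlation about
#' `ld_rho` within blocks of `ld_block_size` SNPs and zero across blocks.
#' Blocks are laid out along chromosomes 1-22 with 50 kb between adjacent
#' SNPs and 50,000 kb between blocks, so LD blocks are well separated in
#' physical distance.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (integer matrix, columns named by SNP id)
#'   and `snps` (data.frame: snp_id, chr, pos, effect_allele, other_allele,
#'   maf).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  set.seed(stage_seed(config$seed, "genotypes"))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]
  n_block <- max(block)

  # physical layout: cycle blocks over chromosomes, 5e7 bp between blocks
  chr_of_block <- ((seq_len(n_block) - 1L) %% 22L) + 1L
  block_rank <- stats::ave(seq_len(n_block), chr_of_block, FUN = seq_along)
  within_idx <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- (block_rank[block] - 1L) * 5e7 + within_idx * 5e4
  chr <- chr_of_block[block]

  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), "")

  geno <- matrix(0L, n, m)
  thr <- stats::qnorm(1 - maf)
  for (b in seq_len(n_block)) {
    idx <- which(block == b)
    l <- if (config$ld_rho > 0) {
      .latent_rho(config$ld_rho, mean(maf[idx]))
    } else 0
    d <- matrix(0L, n, length(idx))
    for (h in 1:2) {  # two haplotypes per individual
      f <- stats::rnorm(n)
      z <- sqrt(l) * f +
        sqrt(1 - l) * matrix(stats::rnorm(n * length(idx)), n)
      d <- d + (z > rep(thr[idx], each = n))
    }
    geno[, idx] <- d
  }
  storage.mode(geno) <- "integer"

  snps <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(m)),
    chr = chr,
    pos = as.integer(pos),
    effect_allele = ea,
    other_allele = oa,
    maf = maf,
    stringsAsFactors = FALSE
  )
  colnames(geno) <- snps$snp_id
  rownames(geno) <- sprintf("id%06d", seq_len(n))
  list(genotypes = geno, snps = snps)
}
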