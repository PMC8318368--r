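# Greedy LD clumping and polygenic-score construction.

#' Pairwise dosage correlation accessor from a genotype matrix
#'
#' Returns a function `r2(id1, id2)` giving the squared Pearson correlation
#' of the two SNPs' dosages.  LD is computed in the same sample that
#' produced the summary statistics (in-sample LD keeps the two splits
#' independent of each other).
#'
#' @param genotypes Dosage matrix with SNP-id column names.
#' @return Function of two SNP ids returning r-squared.
#' @export
ld_accessor <- function(genotypes) {
  function(id1, id2) {
    stats::cor(genotypes[, id1], genotypes[, id2])^2
  }
}

#' Greedy LD clumping of genome-wide-significant SNPs
#'
#' Candidates are SNPs with `p < p_threshold`.  Repeatedly the
#' smallest-p remaining candidate is retained as an index SNP, and every
#' remaining candidate on the same chromosome within `window_kb`
#' (center-to-center) AND with squared correlation above `r2_threshold` is
#' discarded.  Ties in p are broken by ascending (chromosome, position).
#' The defaults mirror the standard genome-wide pipeline: p below 5e-8, a
#' 10,000 kb window, and r-squared 0.001.
#'
#' @param sumstats A `sumstats` table.
#' @param ld An [ld_accessor()] covering all candidate SNPs.
#' @param p_threshold Significance threshold for candidacy.
#' @param window_kb Clumping window in kb, center-to-center, same
#'   chromosome only.
#' @param r2_threshold Squared-correlation threshold.
#' @return An `instrument_set`: the retained rows ordered by p, with a
#'   `weight` column (the GWAS beta) and the clumping parameters stored as
#'   attributes.
#' @export
clump <- function(sumstats, ld, p_threshold = 5e-8,
                  window_kb = 10000, r2_threshold = 0.001) {
  validate_sumstats(sumstats)
  cand <- as.data.frame(sumstats)[sumstats$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chr, cand$pos), , drop = FALSE]
  keep <- character(0)
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    keep <- c(keep, top$snp_id)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    near <- cand$chr == top$chr &
      abs(cand$pos - top$pos) <= window_kb * 1000
    if (any(near)) {
      r2 <- vapply(cand$snp_id[near], function(id) ld(top$snp_id, id), 0)
      drop_ids <- cand$snp_id[near][r2 > r2_threshold]
      cand <- cand[!cand$snp_id %in% drop_ids, , drop = FALSE]
    }
  }
  out <- as.data.frame(sumstats)[match(keep, sumstats$snp_id), , drop = FALSE]
  out$weight <- out$beta
  rownames(out) <- NULL
  structure(out,
            class = c("instrument_set", "data.frame"),
            p_threshold = p_threshold, window_kb = window_kb,
            r2_threshold = r2_threshold)
}

#' Compute a polygenic score
#'
#' Score per individual: the weighted sum of exposure-increasing allele
#' dosages.  Weights are the per-allele GWAS betas; SNPs whose weight is
#' negative are re-oriented (dosage flipped to `2 - g`, weight negated) so
#' every weight counts copies of the exposure-increasing allele.
#'
#' @param genotypes Dosage matrix (columns named by SNP id) with effect
#'   alleles in the orientation of the instrument table.
#' @param instruments An `instrument_set` (or any data frame with
#'   `snp_id` and `weight`).
#' @return Numeric score per individual.
#' @export
compute_pgs <- function(genotypes, instruments) {
  miss <- setdiff(instruments$snp_id, colnames(genotypes))
  if (length(miss)) {
    stop(sprintf("compute_pgs: SNP(s) missing from genotypes: %s",
                 paste(miss, collapse = ", ")))
  }
  G <- genotypes[, instruments$snp_id, drop = FALSE]
  w <- instruments$weight
  flip <- !is.na(w) & w < 0
  if (any(flip)) {
    G[, flip] <- 2 - G[, flip, drop = FALSE]
    w[flip] <- -w[flip]
  }
  as.numeric(G %*% w)
}

#' Incremental variance explained by a score
#'
#' R-squared gained by adding the score to a covariate-only regression of
#' the phenotype: `1 - RSS(full) / RSS(covariates)` on the residualized
#' scale.
#'
#' @param score Numeric score vector.
#' @param phenotype Numeric phenotype vector.
#' @param covariates Optional covariate matrix (intercept always included).
#' @return Fraction of residual variance explained, in `[0, 1]`.
#' @export
score_r2 <- function(score, phenotype, covariates = NULL) {
  keep <- !is.na(score) & !is.na(phenotype)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  score <- score[keep]; phenotype <- phenotype[keep]
  if (stats::sd(score) == 0) stop("score_r2: constant score")
  C <- cbind(rep(1, length(phenotype)),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  qrC <- qr(C)
  y_r <- qr.resid(qrC, phenotype)
  s_r <- qr.resid(qrC, score)
  stats::cor(y_r, s_r)^2
}

#' Write / read an instrument set
#'
#' The `sumstats` schema plus a `weight` column; clumping parameters are
#' stored in a header comment and restored on read.
#'
#' @param instruments An `instrument_set`.
#' @param path File path.
#' @return `read_instruments()` returns the `instrument_set`.
#' @export
write_instruments <- function(instruments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p_threshold=%.17g window_kb=%.17g r2_threshold=%.17g",
                     attr(instruments, "p_threshold"),
                     attr(instruments, "window_kb"),
                     attr(instruments, "r2_threshold")), con)
  utils::write.table(.fmt_num_cols(as.data.frame(instruments)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instruments
#' @export
read_instruments <- function(path) {
  hdr <- readLines(path, n = 1L)
  pars <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  structure(out, class = c("instrument_set", "data.frame"),
            p_threshold = pars[1], window_kb = pars[2], r2_threshold = pars[3])
}
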