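# Split-sample design and per-SNP least-squares GWAS.

subset_cohort <- function(cohort, idx) {
  cohort$phenotypes <- cohort$phenotypes[idx, , drop = FALSE]
  cohort$genotypes <- cohort$genotypes[idx, , drop = FALSE]
  cohort
}

#' Split a cohort into two disjoint halves, stratified by stratum
#'
#' Each stratum is randomly halved (sizes differing by at most one, the odd
#' member's side decided by the seeded RNG), so SNP discovery in one half
#' and estimation in the other share no individuals.
#'
#' @param cohort A `cohort`.
#' @param seed Integer seed; the partition is deterministic given it.
#' @return List with elements `split1` and `split2` (both `cohort`s).
#' @export
split_sample <- function(cohort, seed = cohort$config$seed) {
  ph <- cohort$phenotypes
  if (nrow(ph) == 0L) stop("split_sample: empty cohort")
  set.seed(stage_seed(seed, "split"))
  in1 <- logical(nrow(ph))
  for (s in unique(ph$stratum)) {
    idx <- which(ph$stratum == s)
    if (length(idx) < 2L) {
      stop(sprintf("split_sample: stratum '%s' has fewer than 2 members", s))
    }
    idx <- sample(idx)
    k <- length(idx) %/% 2L
    if (length(idx) %% 2L == 1L && stats::runif(1) < 0.5) k <- k + 1L
    in1[idx[seq_len(k)]] <- TRUE
  }
  list(split1 = subset_cohort(cohort, in1),
       split2 = subset_cohort(cohort, !in1))
}

#' Standard covariate design matrix for hormone analyses
#'
#' Builds the covariate set used throughout: age and blood-draw hour as
#' centered linear, squared and cubed terms (centering before powering for
#' numerical conditioning; the exposure coefficient is unaffected),
#' recruitment-center indicator columns, the principal-component-like
#' columns, and optionally the oophorectomy indicator.
#'
#' @param phenotypes Phenotype data frame.
#' @param n_pcs Number of PC columns to include.
#' @param oophorectomy Include the oophorectomy indicator?
#' @param polynomial Use cubic polynomials in age/draw hour (otherwise
#'   linear only).
#' @return Numeric matrix without an intercept column.
#' @export
standard_covariates <- function(phenotypes, n_pcs = 40L,
                                oophorectomy = FALSE, polynomial = TRUE) {
  a <- phenotypes$age - mean(phenotypes$age, na.rm = TRUE)
  h <- phenotypes$draw_hour - mean(phenotypes$draw_hour, na.rm = TRUE)
  X <- cbind(age1 = a, hour1 = h)
  if (polynomial) {
    X <- cbind(X, age2 = a^2, age3 = a^3, hour2 = h^2, hour3 = h^3)
  }
  centers <- sort(unique(phenotypes$center))
  if (length(centers) > 1L) {
    cm <- stats::model.matrix(~ factor(phenotypes$center, levels = centers))[, -1, drop = FALSE]
    colnames(cm) <- paste0("center_", centers[-1])
    X <- cbind(X, cm)
  }
  pc_cols <- grep("^pc[0-9]+$", names(phenotypes), value = TRUE)
  pc_cols <- pc_cols[seq_len(min(n_pcs, length(pc_cols)))]
  if (length(pc_cols)) X <- cbind(X, as.matrix(phenotypes[pc_cols]))
  if (oophorectomy && "oophorectomy" %in% names(phenotypes)) {
    X <- cbind(X, oophorectomy = phenotypes$oophorectomy)
  }
  X
}

#' Per-SNP least-squares GWAS
#'
#' Regresses the phenotype on each SNP dosage plus covariates by ordinary
#' least squares (Frisch-Waugh residualization, so one pass over the
#' covariates serves all SNPs).  P-values use the t distribution with
#' residual degrees of freedom.  Rows with missing phenotype or covariates
#' are dropped listwise; SNPs with constant dosage in the analyzed sample
#' are skipped with a warning.
#'
#' @param cohort A `cohort` (typically one split).
#' @param phenotype Column name in the phenotype table, or a numeric vector
#'   aligned with it.
#' @param covariates Covariate matrix from [standard_covariates()], or NULL
#'   for an intercept-only adjustment.
#' @return A `sumstats` data frame: snp_id, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n.
#' @export
run_gwas <- function(cohort, phenotype, covariates = NULL) {
  ph <- cohort$phenotypes
  y <- if (is.character(phenotype)) {
    stopifnot(phenotype %in% names(ph))
    ph[[phenotype]]
  } else as.numeric(phenotype)
  G <- cohort$genotypes
  stopifnot(length(y) == nrow(G))

  keep <- !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("run_gwas: dropping %d rows with missing data", n_drop))
  }
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  n <- length(y)

  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("run_gwas: rank-deficient covariate matrix")
  y_r <- qr.resid(qrC, y)
  G_r <- qr.resid(qrC, G)

  gss <- colSums(G_r^2)
  constant <- gss < 1e-10
  if (any(constant)) {
    warning(sprintf("run_gwas: skipping %d constant-dosage SNPs",
                    sum(constant)))
  }
  beta <- colSums(G_r * y_r) / gss
  df <- n - ncol(C) - 1L
  rss <- sum(y_r^2) - beta^2 * gss
  se <- sqrt(pmax(rss, 0) / df / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0,1] even for exact fits

  out <- data.frame(
    snp_id = cohort$snps$snp_id,
    chr = cohort$snps$chr,
    pos = cohort$snps$pos,
    effect_allele = cohort$snps$effect_allele,
    other_allele = cohort$snps$other_allele,
    eaf = colMeans(G) / 2,
    beta = beta,
    se = se,
    p = p,
    n = n,
    stringsAsFactors = FALSE
  )
  out <- out[!constant, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "df") <- df
  class(out) <- c("sumstats", "data.frame")
  out
}

validate_sumstats <- function(ss) {
  stopifnot(all(c("snp_id", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "p", "n") %in% names(ss)))
  if (any(ss$se <= 0, na.rm = TRUE)) stop("sumstats: SE must be > 0")
  if (any(ss$p <= 0 | ss$p > 1, na.rm = TRUE)) {
    stop("sumstats: p must be in (0, 1]")
  }
  invisible(ss)
}

#' Write / read a GWAS summary-statistics table
#'
#' Plain tab-delimited text with the fixed header
#' `snp_id chr pos effect_allele other_allele eaf beta se p n`.
#'
#' @param ss A `sumstats` data frame.
#' @param path File path.
#' @return `read_sumstats()` returns the `sumstats` table.
#' @export
write_sumstats <- function(ss, path) {
  cols <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  extra <- setdiff(names(ss), cols)
  utils::write.table(.fmt_num_cols(as.data.frame(ss)[c(cols, extra)]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(ss) <- c("sumstats", "data.frame")
  validate_sumstats(ss)
}
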