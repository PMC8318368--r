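# Cohort serialization: a directory of plain-text files.
#   genotypes.tsv   dense dosage matrix, rows = individuals, cols = SNPs
#   snps.tsv        SNP sidecar table
#   phenotypes.tsv  covariates + hormone panel + outcomes + flags
#   ground_truth.yaml, config.yaml
# Doubles are written with 17 significant digits so that re-read values are
# bit-identical.

.fmt_num_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write / read a cohort directory
#'
#' Serializes a `cohort` as plain-delimited text plus YAML ground truth and
#' configuration; `read_cohort()` restores it losslessly (doubles are
#' written with 17 significant digits).
#'
#' @param cohort A `cohort` object.
#' @param dir Directory to create/fill.
#' @return `read_cohort()` returns the restored `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- as.data.frame(cohort$genotypes)
  gm <- cbind(eid = rownames(cohort$genotypes), gm)
  utils::write.table(gm, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(.fmt_num_cols(cohort$snps), file.path(dir, "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.fmt_num_cols(cohort$phenotypes),
                     file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$outcome_truth <- as.list(gt$outcome_truth)
    # yaml drops names of atomic vectors; named vectors go out as maps
    gt <- lapply(gt, function(x) {
      if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
    })
    yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"),
                     precision = 17L)
  }
  write_sim_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  gm <- utils::read.table(file.path(dir, "genotypes.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  eid <- gm$eid
  G <- as.matrix(gm[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- eid
  snps <- utils::read.table(file.path(dir, "snps.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  ph <- utils::read.table(file.path(dir, "phenotypes.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  gt_path <- file.path(dir, "ground_truth.yaml")
  gt <- NULL
  if (file.exists(gt_path)) {
    gt <- yaml::read_yaml(gt_path)
    gt$outcome_truth <- as.data.frame(gt$outcome_truth,
                                      stringsAsFactors = FALSE)
    for (nm in c("h2_score", "edu_effect_exposure", "edu_effect_shbg")) {
      gt[[nm]] <- unlist(gt[[nm]])
    }
  }
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  structure(list(genotypes = G, snps = snps, phenotypes = ph,
                 ground_truth = gt, config = cfg),
            class = "cohort")
}
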