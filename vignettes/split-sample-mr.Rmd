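---
title: "Split-sample Mendelian randomization with splitmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-sample Mendelian randomization with splitmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The question the package addresses

Observational associations between circulating hormones — here
testosterone — and socioeconomic position (income, employment, education,
neighborhood deprivation) are hard to interpret: confounding and reverse
causation can produce associations of either sign even after covariate
adjustment. Mendelian randomization (MR) uses genetic variants as
instrumental variables: because genotypes are fixed at conception, a
polygenic score (PGS) for the hormone is not affected by later
socioeconomic events, and — if the instrument assumptions hold — the
instrumented estimate identifies the causal effect.

`splitmr` implements the complete split-sample one-sample MR workflow and
a two-sample sensitivity suite, together with a synthetic biobank-style
cohort generator whose causal structure (confounding, pleiotropy, reverse
feedback) is configurable. The generator is first-class, tested code: it
is how every downstream stage is validated, by parameter recovery against
a known data-generating process rather than against restricted-access
cohort data.

## The hormone model

Total testosterone \(T\) partitions between a free pool \(FT\), an
albumin-bound pool, and an SHBG-bound pool. With the albumin association
lumped into the unit-specific constant \(0.5217\) per g/L and SHBG
binding treated as 1:1 with unit association per nM, mass balance gives

\[
T \;=\; (1 + 0.5217A)\,FT \;+\; \frac{S\,FT}{1 + FT},
\]

whose positive root is the closed form in `free_testosterone()`;
bioavailable testosterone is the free plus albumin-bound pool,
\(BAT = FT(1 + 0.5217A)\). The package's tests solve the mass balance
numerically and verify the closed form to below 1e-8 nM. Units are
enforced (nM, nM, g/L) and never auto-converted, because the constant is
unit-specific. Assay values below the detection limit (default 0.35 nM)
are floored *before* derivation, mirroring how censored immunoassay
readings are coded in practice. A known approximation: applying the
closed form to cohort *means* of \(T, S, A\) is not identical to the mean
of per-person derived values (Jensen's inequality); it agrees to 2
decimals for male-typical values but less well at the low female range.

## The synthetic cohort

`sim_config()` fixes every generative assumption; `simulate_cohort()` is
bit-reproducible given the seed (per-stage sub-seeds are derived
deterministically from it).

**Genotypes.** Biallelic dosages 0/1/2, per-SNP MAF uniform on
`maf_range`, and block-exchangeable LD: each haplotype draws a latent
one-factor Gaussian per block and thresholds it at the MAF quantile.
Thresholding attenuates correlation, so the latent loading is calibrated
numerically (via the bivariate threshold integral) so that the *dosage*
correlation hits `ld_rho` — an invertible target that the clumping tests
can check. Blocks are separated by 50,000 kb so physical windows and LD
blocks coincide. This is deliberately not a human LD map; it is a
structure whose ground truth is known exactly.

**Exposure.** Within each stratum (men, premenopausal, postmenopausal
women) the standardized exposure liability is

\[
X = \sqrt{h^2}\,G^* + \delta U + a\,\mathrm{age}^* + t\,\mathrm{hour}^* +
    g\,\mathrm{Edu}^* + \sqrt{\text{resid}}\;\varepsilon ,
\]

with \(G^*\) the standardized weighted causal-SNP score, \(U\) a shared
standard-normal confounder, and the residual chosen so
\(\operatorname{Var}(X)=1\); infeasible variance budgets are rejected.
Bioavailable testosterone is the stratum-anchored affine map of \(X\)
(anchors: 5.21 ± 1.54 nM in men, 0.37 ± 0.25 and 0.36 ± 0.28 nM in pre-
and postmenopausal women), SHBG and albumin are drawn around their
stratum means, and total testosterone is recovered through the binding
mass balance — so re-deriving the hormone panel downstream reproduces the
exposure exactly.

**Outcomes.** Each outcome has a latent
\(L = \beta X + \theta U + \alpha P + e\), where \(P\) is the
standardized causal-allele count (the directional-pleiotropy channel).
Continuous outcomes are affine in \(L\) (income, deprivation index, BMI);
binary outcomes threshold \(L\) at a prevalence-matched cut. The
liability-threshold choice (rather than a logistic model) is deliberate:
causal risk differences then have a closed form, which is what the
linear-probability-model estimates are validated against. Reverse
causation (`reverse_rho`) feeds the income latent back into the exposure;
education has its own independent SNP architecture and can causally shift
SHBG and the exposure, which is what the reverse-direction MR recovers.

**Defaults are the study conditions.** The default configuration encodes
a *null* causal effect of the exposure on outcomes with confounding
switched on — so multivariable-adjusted estimates are biased while
instrumented estimates are not, the central contrast the package is built
to reproduce. Stratum proportions (0.512/0.125/0.363), hormone anchors,
PGS variance fractions (3.3%, 0.7%, 0.4%), the 0.35 nM floor, and the
exclusion-flag rates (medication 3.9%, relatedness 17.4%, missing assay
5.2%) mirror the large UK cohort setting this design targets. The
confounder loadings (0.30 on exposure, 0.25 on outcomes) and age/draw-hour
effects (both −0.10; testosterone declines with age and across the day)
are **illustrative** — no quantitative confounder model exists to copy —
and they are labelled as such wherever they matter.

## The analysis pipeline

```{r, eval = FALSE}
library(splitmr)
cfg <- sim_config(n_individuals = 6000, n_snps = 40, n_causal = 6,
                  h2_score = 0.25, n_pcs = 3,
                  strata_props = c(men = 1, premenopausal = 0,
                                   postmenopausal = 0), seed = 1)
report <- run_full_pipeline(cfg, mr_settings(
  outcomes = c("tdi", "degree"), strata = "men",
  p_threshold = 1e-5, n_pcs = 3))
report$results[report$results$split == "meta", ]
```

Stages, per stratum:

1. **Exclusions** (`apply_exclusions()`): union of medication,
   relatedness and missing-assay flags, with per-reason counts.
2. **Hormone derivation** (`derive_hormones()`): floor, then FT and BAT.
3. **Split** (`split_sample()`): a stratified random halving; SNP
   discovery in one half, estimation in the other, so the PGS weights
   share no individuals with the analysis sample (overlap bias is the
   reason the split exists).
4. **GWAS** (`run_gwas()`): per-SNP least squares with covariates via
   Frisch–Waugh residualization. P-values use the t distribution with
   residual degrees of freedom — exact at small n, indistinguishable from
   normal at biobank n.
5. **Clumping** (`clump()`): greedy — smallest p first, discarding
   candidates within the window (center-to-center kb, same chromosome)
   and above the r² threshold. Named defaults 5e-8 / 10,000 kb / 0.001.
   Ties in p break by ascending (chromosome, position); LD is computed in
   the same split that produced the statistics, keeping splits
   independent. Both choices are ours to make — the upstream convention
   does not pin them down — and both are asserted against an exhaustive
   oracle in tests.
6. **PGS** (`compute_pgs()`): raw per-allele betas as weights,
   re-oriented so every weight counts exposure-increasing alleles.
7. **Estimation** (`iv_estimate()`, `multivariable_estimate()`): the
   additive structural mean model is fit by two-stage least squares, to
   which it reduces exactly for linear stages with a single instrument
   (an equivalence, not an approximation). Binary outcomes are fit
   identically as linear probability models, so coefficients are risk
   differences; after `standardize_per_sd()` they read as absolute
   percentage points per SD of exposure. Standard errors are
   heteroskedasticity-consistent sandwich estimates with HC1 small-sample
   scaling — the common software default robust flavor — computed from
   the proper IV bread/meat (residuals use the observed exposure).
   Confidence intervals are `beta ± 1.96·SE` with the literal 1.96, and
   all p-values are two-sided with no multiplicity correction.
8. **Diagnostics**: the robust first-stage F for the single score
   instrument is `(beta/robust SE)²` from stage 1; weak instruments are
   flagged (default floor 10), never silently dropped.
9. **Comparison and pooling**: Hausman tests within each split
   (`(b_IV − b_OLS)²/(SE_IV² − SE_OLS²)`, χ²₁; reported as undefined when
   the variance difference is not positive), fixed-effect meta-analysis
   across the two splits, and a Fisher z test between the pooled MR and
   pooled multivariable estimates. The Fisher test assumes the two
   estimates are independent; applied to estimates from the same
   individuals that is only approximate — implemented as specified,
   limitation noted.

## The two-sample sensitivity suite

`harmonize()` aligns outcome to exposure effect alleles (sign flips for
swapped pairs, strand complements recognized; palindromic SNPs are kept
by default because simulated strands are unambiguous, and dropped under
`strict = TRUE` for real-format inputs). Wald-ratio standard errors are
first order (`se_out/|b_exp|`), the standard no-measurement-error
simplification; this makes IVW *algebraically identical* to fixed-effect
meta-analysis of the ratios, an identity the tests assert to 1e-10 and
the known source of small discrepancies versus exact-ratio SEs.

- **IVW**: zero-intercept weighted regression; multiplicative
  random-effects SE inflation by `sqrt(Q/df)` only when `Q/df > 1`,
  never deflation.
- **MR-Egger**: the same regression with a free intercept after orienting
  exposure betas positive; the intercept estimates directional
  pleiotropy; p-values from t with k−2 df.
- **Weighted median**: interpolation of ordered ratios at 50% cumulative
  weight; robust to up to half the weight being invalid.
- **Weighted mode**: argmax of a weight-scaled normal-kernel density,
  bandwidth = `bandwidth_factor` × a MAD-based spread with Silverman
  scaling. The factor defaults to 1.0 and is surfaced in results because
  no upstream value exists to copy.
- **Cochran's Q** about the IVW estimate, df = k−1.

Bootstrap SEs (median, mode) default to 1,000 parametric replicates; all
stochastic steps take explicit seeds and restore the caller's RNG stream.

## Outcome coding

`code_income()` maps the five income bands to midpoints (15,000; 24,500;
41,500; 76,000; 150,000) with a dichotomy at 52,000. Employment is four
contrasts against the same employed reference, each dropping the other
non-reference categories (our reading of the shared-reference question —
the alternative would change only the reference group's composition).
Deprivation is dichotomized at the most-deprived tertile, cut points
computed within the analyzed non-missing rows of each stratum (the
quantile population is unstated upstream; the stratum is the natural
choice since all analyses are stratified). Income and employment outcomes
are masked for individuals at or above the state pension age at
recruitment (65 men / 60 women, mask applied at `age >= pension age`).
Equivalized income divides household income by household size capped
at 12.

## What passing tests do and do not show

The simulation validates *estimator behavior under a known causal
structure*: unbiasedness and ~95% CI coverage of 2SLS under valid
instruments, the omitted-variable-bias formula for the observational
comparator, null preservation under confounding and reverse feedback,
Egger intercept size and power against directional pleiotropy, and the
clumping/PGS identities. It does not emulate real human LD, fine-scale
population structure, genotyping error, informative missingness
(missingness here is completely at random), or selection into the cohort
— so passing tests certify the statistical machinery, not robustness to
those real-data complications.

## Numerical choices and problem sizes

Degenerate inputs are rejected with messages (negative hormone inputs,
rank-deficient covariates, constant scores/outcomes, infeasible variance
budgets); constant-dosage SNPs are skipped with a warning; FT is clipped
to `[0, T]` with a 1e-12 guard against floating-point rounding. The test
suite works at deliberately modest problem sizes — cohorts of 3,000 to
60,000 individuals, 10 to 400 SNPs, 200-replicate Monte Carlo batches —
chosen so each check has adequate power while the whole suite stays
interactive; sparser, stronger architectures (e.g. 6 SNPs explaining 25%
of variance) are used where a desk-scale GWAS must clear the genome-wide
threshold, and the n = 60,000 / R² = 3.3% instrument-strength setting
reproduces first-stage F ≈ 2,000, comfortably above the conventional
weak-instrument floor of 1,000 reported for male-cohort analyses at this
scale.

## Known limitations

One-sample 2SLS here supports a single (score) instrument;
multi-instrument estimation lives in the summary-statistic suite.
Logistic/probit models are intentionally absent (linear probability
models keep MR and observational risk differences comparable). The
Kleibergen–Paap-style F is implemented as the single-instrument robust F;
no clustering structure is modeled. Within-family designs, real LD maps
and real-format genotype ingestion are out of scope.
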