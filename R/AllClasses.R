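#' @import methods
#' @importFrom stats pnorm qnorm dnorm pchisq qchisq pf qf pt dt quantile
#'   rnorm runif rbinom rexp sd mad density lm coef p.adjust setNames
#' @importFrom utils head modifyList
NULL

## Canonical column set for a summary-statistics table. Optional flag columns
## (p_underflow, chi2_capped) may follow these.
SUMSTATS_COLS <- c("SNP", "CHR", "POS", "A1", "A2", "EAF", "BETA", "SE", "P", "N")

#' Per-study metadata for a GWAS
#'
#' Carries the trait-level information a two-sample MR analysis needs beyond
#' the per-SNP table: what the trait is, its measurement unit, the sample
#' size, and — for binary traits — the case count and assumed population
#' prevalence (required for any liability-scale conversion).
#'
#' @slot trait_name Character label for the trait.
#' @slot trait_type Either \code{"continuous"} or \code{"binary"}.
#' @slot unit Unit of the per-allele effect (e.g. \code{"ln pmol/L"},
#'   \code{"mmol/L"}, \code{"log-odds"}).
#' @slot n Total sample size.
#' @slot n_cases Number of cases (binary traits; \code{NA} otherwise).
#' @slot prevalence Assumed population prevalence in (0,1) (binary traits;
#'   \code{NA} otherwise).
#' @slot ancestry_label Free-text ancestry descriptor.
#'
#' @seealso [studyMeta()] for the user-facing constructor.
#' @export
setClass("StudyMeta",
  representation(
    trait_name = "character",
    trait_type = "character",
    unit = "character",
    n = "numeric",
    n_cases = "numeric",
    prevalence = "numeric",
    ancestry_label = "character"
  ),
  prototype(
    trait_type = "continuous", unit = "", n = NA_real_,
    n_cases = NA_real_, prevalence = NA_real_, ancestry_label = "EUR"
  )
)

setValidity("StudyMeta", function(object) {
  msg <- character()
  if (!object@trait_type %in% c("continuous", "binary"))
    msg <- c(msg, "trait_type must be 'continuous' or 'binary'")
  if (object@trait_type == "binary" && !is.na(object@n_cases) &&
      !is.na(object@n) && object@n_cases > object@n)
    msg <- c(msg, "n_cases must be <= n")
  if (!is.na(object@prevalence) &&
      (object@prevalence <= 0 || object@prevalence >= 1))
    msg <- c(msg, "prevalence must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct study metadata
#'
#' @param trait_name Trait label.
#' @param trait_type \code{"continuous"} (default) or \code{"binary"}.
#' @param unit Unit of effect.
#' @param n Total sample size.
#' @param n_cases Case count for binary traits.
#' @param prevalence Population prevalence for binary traits.
#' @param ancestry_label Ancestry descriptor.
#' @return A [StudyMeta-class] object.
#' @examples
#' studyMeta("fasting insulin", n = 108557, unit = "ln pmol/L")
#' @export
studyMeta <- function(trait_name, trait_type = "continuous", unit = "",
                      n = NA_real_, n_cases = NA_real_,
                      prevalence = NA_real_, ancestry_label = "EUR") {
  new("StudyMeta",
    trait_name = as.character(trait_name), trait_type = trait_type,
    unit = unit, n = as.numeric(n), n_cases = as.numeric(n_cases),
    prevalence = as.numeric(prevalence), ancestry_label = ancestry_label)
}

#' A validated GWAS summary-statistics table plus its study metadata
#'
#' The per-SNP table uses the canonical columns \code{SNP, CHR, POS, A1, A2,
#' EAF, BETA, SE, P, N} (1-based positions, upper-case alleles, \code{BETA}
#' in study units — log-odds for binary traits). Rows are guaranteed to have
#' passed the record-level invariants enforced by [readSumstats()]; the
#' counts of rows dropped at read time are retained in \code{dropCounts}.
#'
#' @slot variants data.frame in canonical column order.
#' @slot meta A [StudyMeta-class].
#' @slot dropCounts Named integer vector of rows removed per validation rule.
#' @export
setClass("GwasSumstats",
  representation(
    variants = "data.frame",
    meta = "StudyMeta",
    dropCounts = "integer"
  )
)

setValidity("GwasSumstats", function(object) {
  miss <- setdiff(SUMSTATS_COLS, names(object@variants))
  if (length(miss))
    return(paste("missing canonical columns:", paste(miss, collapse = ", ")))
  TRUE
})

#' An exposure/outcome-aligned instrument set
#'
#' One row per exposure instrument, carrying both effect pairs after allele
#' harmonization, plus the provenance of what harmonization did
#' (\code{action}): \code{aligned}, \code{flipped}, \code{palindromic_inferred},
#' \code{removed_palindromic}, \code{removed_missing} or
#' \code{removed_mismatch}. Rows whose action starts with \code{removed} carry
#' no usable outcome effect and are excluded from estimation by [usable()].
#'
#' @slot instruments data.frame with columns \code{SNP, beta_exp, se_exp,
#'   beta_out, se_out, eaf_exp, eaf_out, p_exp, p_out, n_exp, n_out, action}.
#' @slot exposure,outcome Trait labels.
#' @export
setClass("HarmonizedSet",
  representation(
    instruments = "data.frame",
    exposure = "character",
    outcome = "character"
  ),
  prototype(exposure = "exposure", outcome = "outcome")
)

setValidity("HarmonizedSet", function(object) {
  need <- c("SNP", "beta_exp", "se_exp", "beta_out", "se_out", "action")
  miss <- setdiff(need, names(object@instruments))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  us <- !startsWith(object@instruments$action, "removed")
  if (any(us) && (any(object@instruments$se_exp[us] <= 0) ||
                  any(object@instruments$se_out[us] <= 0)))
    return("usable instruments must have positive standard errors")
  TRUE
})

#' One estimator's causal estimate
#'
#' @slot method Estimator tag (\code{"ivw"}, \code{"egger"}, ...).
#' @slot beta Causal effect per unit of the exposure.
#' @slot se Standard error.
#' @slot ci_low,ci_high 95\% confidence bounds.
#' @slot pvalue Two-sided p-value (normal reference).
#' @slot k_used Number of instruments used.
#' @slot extra Method-specific list (Egger intercept and its SE/p; I2 of the
#'   instrument-exposure effects; PRESSO outlier indices and global p; ...).
#' @export
setClass("MRFit",
  representation(
    method = "character",
    beta = "numeric",
    se = "numeric",
    ci_low = "numeric",
    ci_high = "numeric",
    pvalue = "numeric",
    k_used = "integer",
    extra = "list"
  ),
  prototype(extra = list())
)

setValidity("MRFit", function(object) {
  msg <- character()
  if (!is.na(object@se) && object@se < 0) msg <- c(msg, "se must be >= 0")
  if (!is.na(object@ci_low) && !is.na(object@ci_high) &&
      (object@ci_low > object@beta + 1e-12 ||
       object@ci_high < object@beta - 1e-12))
    msg <- c(msg, "beta must lie inside [ci_low, ci_high]")
  if (object@k_used < 1L) msg <- c(msg, "k_used must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Steiger directionality test result
#'
#' @slot r2_exposure Variance in the exposure explained by the instruments.
#' @slot r2_outcome Variance in the outcome explained by the instruments
#'   (liability scale when the outcome is binary).
#' @slot correct_direction TRUE iff r2_exposure > r2_outcome.
#' @slot p_direction Two-sided p for equality of the two correlations.
#' @slot prevalence_used Prevalence used for the liability conversion
#'   (\code{NA} for continuous outcomes).
#' @export
setClass("SteigerResult",
  representation(
    r2_exposure = "numeric",
    r2_outcome = "numeric",
    correct_direction = "logical",
    p_direction = "numeric",
    prevalence_used = "numeric"
  )
)

#' Pleiotropy/heterogeneity diagnostics for one exposure-outcome model
#'
#' @slot q_stat Cochran's Q over per-instrument ratio estimates.
#' @slot q_df Degrees of freedom (k - 1).
#' @slot q_p Chi-square p-value.
#' @slot egger_intercept,egger_intercept_se,egger_intercept_p MR-Egger
#'   intercept test of directional pleiotropy.
#' @slot presso_global_p MR-PRESSO global heterogeneity p.
#' @slot loo_estimates data.frame of leave-one-out IVW fits
#'   (SNP, beta, se, flagged).
#' @slot steiger A [SteigerResult-class] (or list of them at several
#'   prevalence bounds).
#' @export
setClass("SensitivityReport",
  representation(
    q_stat = "numeric",
    q_df = "integer",
    q_p = "numeric",
    egger_intercept = "numeric",
    egger_intercept_se = "numeric",
    egger_intercept_p = "numeric",
    presso_global_p = "numeric",
    loo_estimates = "data.frame",
    steiger = "list"
  )
)

setValidity("SensitivityReport", function(object) {
  if (!is.na(object@q_stat) && object@q_stat < 0) "q_stat must be >= 0" else TRUE
})

#' Latent causal variable model result
#'
#' @slot gcp Posterior-mean genetic causality proportion in [-1, 1]; positive
#'   values mean trait 1 is partially genetically causal for trait 2.
#' @slot gcp_se Block-jackknife standard error of the posterior mean.
#' @slot p_gcp_zero Two-sided p for GCP = 0.
#' @slot p_full_causal_fwd p for H0: GCP = 1 (full causality trait1 -> trait2).
#' @slot p_full_causal_rev p for H0: GCP = -1.
#' @slot rho_g Genetic correlation estimate.
#' @slot h2 Length-2 vector of SNP-heritability estimates.
#' @export
setClass("LCVResult",
  representation(
    gcp = "numeric",
    gcp_se = "numeric",
    p_gcp_zero = "numeric",
    p_full_causal_fwd = "numeric",
    p_full_causal_rev = "numeric",
    rho_g = "numeric",
    h2 = "numeric"
  )
)

setValidity("LCVResult", function(object) {
  if (object@gcp < -1 - 1e-9 || object@gcp > 1 + 1e-9)
    "gcp must lie in [-1, 1]" else TRUE
})

#' Generating parameters of a synthetic two-sample MR dataset
#'
#' Records everything needed to regenerate a dataset bit-identically and to
#' score estimator recovery against ground truth.
#'
#' @slot beta_causal True causal effect of exposure on outcome.
#' @slot pleiotropy_model One of \code{none, balanced, directional, correlated}.
#' @slot pleiotropy_mean,pleiotropy_sd Parameters of the per-instrument direct
#'   effects; the \code{correlated} model adds \code{pleiotropy_cor} times the
#'   exposure effect (violating InSIDE).
#' @slot frac_invalid Fraction of instruments carrying pleiotropic effects.
#' @slot n_iv Number of true instruments.
#' @slot n_null Number of background null SNPs.
#' @slot n_exp,n_out GWAS sample sizes.
#' @slot case_prop_out Case proportion of the (binary) outcome GWAS; outcome
#'   standard errors scale with \eqn{1/\sqrt{2f(1-f) n P(1-P)}}.
#' @slot maf_range Allele-frequency interval instruments are drawn from.
#' @slot r2_total Total exposure variance explained by the instrument set.
#' @slot prop_palindromic Fraction of SNPs given palindromic allele pairs.
#' @slot ld_blocks Integer vector of LD-block sizes (instruments are padded
#'   with correlated partners); empty for independent instruments.
#' @slot ld_r Within-block LD correlation.
#' @slot seed RNG seed; identical SimTruth implies bit-identical output.
#' @export
setClass("SimTruth",
  representation(
    beta_causal = "numeric",
    pleiotropy_model = "character",
    pleiotropy_mean = "numeric",
    pleiotropy_sd = "numeric",
    pleiotropy_cor = "numeric",
    frac_invalid = "numeric",
    n_iv = "integer",
    n_null = "integer",
    n_exp = "numeric",
    n_out = "numeric",
    case_prop_out = "numeric",
    maf_range = "numeric",
    r2_total = "numeric",
    prop_palindromic = "numeric",
    ld_blocks = "integer",
    ld_r = "numeric",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (!object@pleiotropy_model %in%
      c("none", "balanced", "directional", "correlated"))
    msg <- c(msg, "unknown pleiotropy_model")
  if (object@n_iv < 1L) msg <- c(msg, "n_iv must be >= 1")
  if (object@r2_total <= 0 || object@r2_total >= 1)
    msg <- c(msg, "r2_total must lie in (0,1)")
  if (length(object@maf_range) != 2L || any(object@maf_range <= 0) ||
      any(object@maf_range > 0.5))
    msg <- c(msg, "maf_range must be an interval within (0, 0.5]")
  if (length(msg)) msg else TRUE
})
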