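#' Accessors for ivmr classes
#'
#' Slot access for the package's S4 containers. \code{variants()} returns the
#' canonical per-SNP table of a [GwasSumstats-class]; \code{instruments()}
#' the full harmonized table (including removed rows) of a
#' [HarmonizedSet-class]; \code{usable()} only the rows that estimation may
#' use; \code{dropCounts()} the per-rule read/munge attrition.
#'
#' @param x An ivmr object.
#' @return A data.frame, [StudyMeta-class], or named vector as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setMethod("variants", "GwasSumstats", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("studyMetaOf", function(x) standardGeneric("studyMetaOf"))
#' @rdname accessors
#' @export
setMethod("studyMetaOf", "GwasSumstats", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("dropCounts", function(x) standardGeneric("dropCounts"))
#' @rdname accessors
#' @export
setMethod("dropCounts", "GwasSumstats", function(x) x@dropCounts)

#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setMethod("instruments", "HarmonizedSet", function(x) x@instruments)

#' @rdname accessors
#' @export
setGeneric("usable", function(x) standardGeneric("usable"))
#' @rdname accessors
#' @export
setMethod("usable", "HarmonizedSet", function(x) {
  x@instruments[!startsWith(x@instruments$action, "removed"), , drop = FALSE]
})

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setMethod("mrBeta", "MRFit", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname accessors
#' @export
setMethod("mrSE", "MRFit", function(x) x@se)

#' @rdname accessors
#' @export
setGeneric("mrPvalue", function(x) standardGeneric("mrPvalue"))
#' @rdname accessors
#' @export
setMethod("mrPvalue", "MRFit", function(x) x@pvalue)

#' @rdname accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))
#' @rdname accessors
#' @export
setMethod("mrCI", "MRFit", function(x) c(x@ci_low, x@ci_high))

#' @rdname accessors
#' @export
setGeneric("mrExtra", function(x) standardGeneric("mrExtra"))
#' @rdname accessors
#' @export
setMethod("mrExtra", "MRFit", function(x) x@extra)

#' @rdname accessors
#' @export
setGeneric("gcp", function(x) standardGeneric("gcp"))
#' @rdname accessors
#' @export
setMethod("gcp", "LCVResult", function(x) x@gcp)

setMethod("show", "StudyMeta", function(object) {
  cat("StudyMeta:", object@trait_name,
      sprintf("(%s, unit '%s', n = %s)", object@trait_type, object@unit,
              format(object@n, big.mark = ",")), "\n")
  if (object@trait_type == "binary")
    cat("  cases:", object@n_cases, " prevalence:", object@prevalence, "\n")
})

setMethod("show", "GwasSumstats", function(object) {
  cat("GwasSumstats:", nrow(object@variants), "variants for trait",
      sQuote(object@meta@trait_name), "\n")
  if (sum(object@dropCounts) > 0) {
    dc <- object@dropCounts[object@dropCounts > 0]
    cat("  dropped at read:",
        paste(sprintf("%s=%d", names(dc), dc), collapse = ", "), "\n")
  }
})

setMethod("show", "HarmonizedSet", function(object) {
  tab <- table(object@instruments$action)
  cat(sprintf("HarmonizedSet: %s -> %s (%d instruments, %d usable)\n",
              object@exposure, object@outcome, nrow(object@instruments),
              nrow(usable(object))))
  cat("  actions:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
})

setMethod("show", "MRFit", function(object) {
  cat(sprintf("MRFit [%s]: beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              object@method, object@beta, object@se, object@ci_low,
              object@ci_high, object@pvalue, object@k_used))
  if (length(object@extra)) {
    keys <- names(object@extra)
    scal <- vapply(object@extra, function(v) is.numeric(v) && length(v) == 1L,
                   logical(1))
    if (any(scal))
      cat("  extra:", paste(sprintf("%s=%.3g", keys[scal],
          unlist(object@extra[scal])), collapse = ", "), "\n")
  }
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("Steiger: r2_exposure = %.4g, r2_outcome = %.4g -> %s (p = %.3g)\n",
              object@r2_exposure, object@r2_outcome,
              if (isTRUE(object@correct_direction)) "direction supported"
              else "direction NOT supported", object@p_direction))
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("SensitivityReport: Q = %.3f (df %d, p = %.3g); Egger intercept = %.3g (p = %.3g); PRESSO global p = %.3g\n",
              object@q_stat, object@q_df, object@q_p, object@egger_intercept,
              object@egger_intercept_p, object@presso_global_p))
  if (nrow(object@loo_estimates))
    cat("  leave-one-out flags:", sum(object@loo_estimates$flagged), "of",
        nrow(object@loo_estimates), "\n")
})

setMethod("show", "LCVResult", function(object) {
  cat(sprintf("LCVResult: GCP = %.3f (SE %.3f), p[GCP=0] = %.3g\n",
              object@gcp, object@gcp_se, object@p_gcp_zero))
  cat(sprintf("  p[GCP=+1] = %.3g, p[GCP=-1] = %.3g, rho_g = %.3f\n",
              object@p_full_causal_fwd, object@p_full_causal_rev,
              object@rho_g))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: beta_causal = %.3g, pleiotropy = %s, %d IVs (+%d null SNPs), n_exp = %g, n_out = %g, seed = %d\n",
              object@beta_causal, object@pleiotropy_model, object@n_iv,
              object@n_null, object@n_exp, object@n_out, object@seed))
})
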