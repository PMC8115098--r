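## Heterogeneity, pleiotropy, directionality, multiple-testing and
## scale-conversion procedures.

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (r_j - \hat\beta)^2} over the Wald ratios with IVW
#' weights \eqn{w_j = \beta_{exp,j}^2/se_{out,j}^2}; p from chi-square with
#' \eqn{k - 1} degrees of freedom. Excess heterogeneity among ratio
#' estimates suggests horizontal pleiotropy.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @param beta_hat The IVW point estimate; recomputed from \code{h} when
#'   omitted.
#' @return List with \code{Q}, \code{df}, \code{p}.
#' @export
cochranQ <- function(h, beta_hat = NULL) {
  df <- .h_df(h, 2L, "Cochran's Q")
  w <- df$beta_exp^2 / df$se_out^2
  r <- df$beta_out / df$beta_exp
  if (is.null(beta_hat)) beta_hat <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta_hat)^2)
  k <- nrow(df)
  list(Q = q, df = k - 1L, p = pchisq(q, k - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Refits the multiplicative random-effects IVW omitting each instrument in
#' turn, flagging omissions that move the estimate outside the full-set 95\%
#' confidence interval or change its sign — evidence that a single
#' instrument drives the result. The reference interval is the
#' \emph{fixed-effects} one: an influential outlier inflates the
#' multiplicative random-effects interval in proportion to its own
#' displacement, which would make the flag a no-op.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame (>= 3 usable
#'   instruments).
#' @return data.frame with columns \code{SNP}, \code{beta}, \code{se},
#'   \code{flagged}; the full-set fit is attached as attribute
#'   \code{"full_fit"}.
#' @export
leaveOneOut <- function(h) {
  df <- .h_df(h, 3L, "leave-one-out")
  full <- mrIVW(df)
  ref <- mrIVW(df, "fixed")
  out <- data.frame(SNP = df$SNP, beta = NA_real_, se = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(df))) {
    fit <- mrIVW(df[-j, , drop = FALSE])
    out$beta[j] <- fit@beta
    out$se[j] <- fit@se
    out$flagged[j] <- fit@beta < ref@ci_low || fit@beta > ref@ci_high ||
      (sign(fit@beta) != sign(full@beta) && full@beta != 0)
  }
  attr(out, "full_fit") <- full
  out
}

#' Liability-scale conversion of variance explained
#'
#' Converts an observed-scale (0/1 regression) r-squared for a binary trait
#' to the liability scale under the threshold model:
#' \deqn{r^2_{liab} = r^2_{obs} \frac{K^2 (1-K)^2}{z^2 P (1-P)}}
#' with \eqn{K} the population prevalence, \eqn{P} the sample case
#' proportion, and \eqn{z} the standard-normal density at the liability
#' threshold \eqn{\Phi^{-1}(1-K)}.
#'
#' @param r2_observed Observed-scale variance explained.
#' @param prevalence Population prevalence K in (0,1).
#' @param case_proportion Sample case proportion P in (0,1).
#' @return Liability-scale r-squared.
#' @export
liabilityR2 <- function(r2_observed, prevalence, case_proportion) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0,1)")
  if (case_proportion <= 0 || case_proportion >= 1)
    stop("case_proportion must lie in (0,1)")
  z <- dnorm(qnorm(1 - prevalence))
  r2_observed * prevalence^2 * (1 - prevalence)^2 /
    (z^2 * case_proportion * (1 - case_proportion))
}

#' Liability-scale rescaling of a binary-exposure causal effect
#'
#' A binary exposure's log-odds unit is hard to interpret (one unit is a
#' 2.72-fold multiplicative increase in odds). This rescales the estimate to
#' the change in outcome per standard deviation of liability to the
#' disorder: \deqn{\beta_{liab} = \beta_{obs} \frac{z}{K(1-K)}} with \eqn{z}
#' the standard-normal density at \eqn{\Phi^{-1}(1-K)}.
#'
#' @param beta_observed Observed-scale (log-odds exposure) estimate.
#' @param prevalence Population prevalence K in (0,1).
#' @return Liability-scale estimate.
#' @examples
#' liabilityBeta(0.017, 0.007)   # ~0.048
#' liabilityBeta(-0.015, 0.009)  # ~-0.041
#' @export
liabilityBeta <- function(beta_observed, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0,1)")
  z <- dnorm(qnorm(1 - prevalence))
  beta_observed * z / (prevalence * (1 - prevalence))
}

#' Steiger directionality test
#'
#' Tests whether the instruments explain more variance in the exposure than
#' in the outcome — evidence that the assumed causal direction is correct.
#' Per-SNP variance explained comes from [r2FromPN()] and is summed over
#' instruments on each side; a binary outcome's r-squared is converted to
#' the liability scale via [liabilityR2()] at the supplied prevalence. The
#' p-value compares the two implied correlations between independent samples
#' by Fisher z transform with variance \eqn{1/(n-3)} on each side.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame carrying
#'   \code{p_exp, n_exp, p_out, n_out} columns.
#' @param outcome_meta A [StudyMeta-class] for the outcome; required to
#'   detect a binary outcome and supply its case proportion.
#' @param prevalence Population prevalence for a binary outcome (defaults to
#'   the value in \code{outcome_meta}); ignored for continuous outcomes.
#' @return A [SteigerResult-class].
#' @export
mrSteiger <- function(h, outcome_meta = NULL, prevalence = NULL) {
  df <- .h_df(h, 1L, "Steiger")
  need <- c("p_exp", "n_exp", "p_out", "n_out")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Steiger needs per-SNP p and n on both sides; missing: ",
         paste(miss, collapse = ", "))
  r2_exp <- sum(r2FromPN(df$p_exp, df$n_exp))
  r2_out <- sum(r2FromPN(df$p_out, df$n_out))
  prev_used <- NA_real_
  binary <- !is.null(outcome_meta) && outcome_meta@trait_type == "binary"
  if (binary) {
    if (is.null(prevalence)) prevalence <- outcome_meta@prevalence
    if (is.null(prevalence) || is.na(prevalence))
      stop("prevalence required for a binary outcome")
    prop <- if (!is.na(outcome_meta@n_cases) && !is.na(outcome_meta@n))
      outcome_meta@n_cases / outcome_meta@n else prevalence
    r2_out <- liabilityR2(r2_out, prevalence, prop)
    prev_used <- prevalence
  }
  n1 <- mean(df$n_exp)
  n2 <- mean(df$n_out)
  z1 <- atanh(sqrt(pmin(r2_exp, 1 - 1e-12)))
  z2 <- atanh(sqrt(pmin(r2_out, 1 - 1e-12)))
  zstat <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * pnorm(-abs(zstat))
  new("SteigerResult", r2_exposure = r2_exp, r2_outcome = r2_out,
      correct_direction = r2_exp > r2_out,
      p_direction = max(p, .Machine$double.xmin),
      prevalence_used = prev_used)
}

#' Odds ratio with confidence interval from a log-odds estimate
#'
#' @param beta Log-odds estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return Named vector \code{or}, \code{ci_low}, \code{ci_high}.
#' @examples
#' orCI(-0.72, 0.20)  # OR 0.49 [0.33, 0.72]
#' @export
orCI <- function(beta, se, level = 0.95) {
  stopifnot(se > 0)
  z <- qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Concentration after a one-natural-log-unit increase
#'
#' Contextualizes effects expressed per ln-unit of a concentration: one unit
#' up from \code{concentration} is \eqn{e \cdot} \code{concentration}.
#'
#' @param concentration Positive concentration (e.g. pmol/L).
#' @return The concentration after a one-ln-unit increase.
#' @examples
#' unitContext(30.97)  # ~84.19
#' @export
unitContext <- function(concentration) {
  if (any(concentration <= 0)) stop("concentration must be positive")
  exp(log(concentration) + 1)
}

#' Multiple-testing correction
#'
#' Bonferroni returns the corrected threshold \eqn{\alpha/m} and flags
#' \eqn{p <} threshold; Benjamini-Hochberg returns step-up adjusted p-values
#' (via [stats::p.adjust()]) flagged at \eqn{\alpha}.
#'
#' @param pvalues P-values in (0, 1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @param alpha Family-wise / false-discovery level (default 0.05).
#' @return List with \code{significant} (logical) plus \code{threshold}
#'   (bonferroni) or \code{adjusted} (bh).
#' @examples
#' multipleTesting(2.27e-4, "bonferroni", alpha = 0.05 / 1 * 0.05)
#' @export
multipleTesting <- function(pvalues, method = c("bonferroni", "bh"),
                            alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvalues)) stop("no p-values supplied")
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  if (method == "bonferroni") {
    thr <- alpha / length(pvalues)
    list(threshold = thr, significant = pvalues < thr)
  } else {
    adj <- p.adjust(pvalues, method = "BH")
    list(adjusted = adj, significant = adj < alpha)
  }
}

#' Full sensitivity report for one exposure-outcome model
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, the MR-PRESSO global
#' test, leave-one-out estimates and the Steiger directionality test(s) into
#' a [SensitivityReport-class]. Steiger is run once per element of
#' \code{prevalence_bounds} when the outcome is binary (both bounds of a
#' prevalence estimate are conventionally reported).
#'
#' @param h A [HarmonizedSet-class].
#' @param outcome_meta A [StudyMeta-class] for the outcome (or \code{NULL}).
#' @param prevalence_bounds Numeric vector of prevalences for the Steiger
#'   liability conversion of a binary outcome.
#' @param n_sim,seed Passed to [mrPresso()].
#' @return A [SensitivityReport-class].
#' @export
sensitivityReport <- function(h, outcome_meta = NULL,
                              prevalence_bounds = NULL,
                              n_sim = 1000, seed = 1) {
  df <- .h_df(h, 3L, "sensitivity report")
  ivw <- mrIVW(df)
  q <- cochranQ(df, ivw@beta)
  eg <- mrEgger(df)
  presso_p <- if (nrow(df) >= 4) mrPresso(df, n_sim = n_sim, seed = seed)@extra$global_p
              else NA_real_
  loo <- leaveOneOut(df)
  steiger <- list()
  if (all(c("p_exp", "n_exp", "p_out", "n_out") %in% names(df))) {
    if (!is.null(outcome_meta) && outcome_meta@trait_type == "binary") {
      if (is.null(prevalence_bounds))
        prevalence_bounds <- outcome_meta@prevalence
      steiger <- lapply(prevalence_bounds, function(k)
        mrSteiger(df, outcome_meta, prevalence = k))
    } else {
      steiger <- list(mrSteiger(df, outcome_meta))
    }
  }
  new("SensitivityReport",
      q_stat = q$Q, q_df = as.integer(q$df), q_p = q$p,
      egger_intercept = eg@extra$intercept,
      egger_intercept_se = eg@extra$intercept_se,
      egger_intercept_p = eg@extra$intercept_p,
      presso_global_p = presso_p,
      loo_estimates = loo, steiger = steiger)
}

#' Serialize a sensitivity report
#'
#' Writes a tab-delimited table of the scalar diagnostics plus the
#' leave-one-out estimates, and a short structured text summary.
#'
#' @param report A [SensitivityReport-class].
#' @param path_prefix Output prefix; writes \code{<prefix>_sensitivity.tsv},
#'   \code{<prefix>_loo.tsv} and \code{<prefix>_summary.txt}.
#' @return Character vector of the paths written, invisibly.
#' @export
writeSensitivityReport <- function(report, path_prefix) {
  scalars <- data.frame(
    statistic = c("cochran_q", "cochran_q_df", "cochran_q_p",
                  "egger_intercept", "egger_intercept_se",
                  "egger_intercept_p", "presso_global_p"),
    value = c(report@q_stat, report@q_df, report@q_p,
              report@egger_intercept, report@egger_intercept_se,
              report@egger_intercept_p, report@presso_global_p)
  )
  for (i in seq_along(report@steiger)) {
    s <- report@steiger[[i]]
    scalars <- rbind(scalars, data.frame(
      statistic = paste0(c("steiger_r2_exposure", "steiger_r2_outcome",
                           "steiger_correct", "steiger_p",
                           "steiger_prevalence"), "_", i),
      value = c(s@r2_exposure, s@r2_outcome,
                as.numeric(s@correct_direction), s@p_direction,
                s@prevalence_used)))
  }
  p1 <- paste0(path_prefix, "_sensitivity.tsv")
  p2 <- paste0(path_prefix, "_loo.tsv")
  p3 <- paste0(path_prefix, "_summary.txt")
  data.table::fwrite(scalars, p1, sep = "\t")
  data.table::fwrite(report@loo_estimates, p2, sep = "\t")
  con <- file(p3, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(show(report)), con)
  invisible(c(p1, p2, p3))
}
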