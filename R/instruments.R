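## Instrument selection, LD clumping, allele harmonization, and strength.

.variant_df <- function(x) {
  if (is(x, "GwasSumstats")) x@variants else as.data.frame(x)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic (strand-ambiguous) when its allele pair is its own
#' reverse complement: A/T or C/G.
#'
#' @param a1,a2 Character vectors of single-base alleles.
#' @return Logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.complement <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Select genome-wide-significant instruments
#'
#' Returns the variants with \eqn{p <} \code{p_threshold}, sorted by
#' ascending p-value (ties broken by SNP ID).
#'
#' @param x A [GwasSumstats-class] or canonical data.frame.
#' @param p_threshold Significance level (default \code{5e-8}).
#' @return data.frame of selected variants (possibly empty).
#' @export
selectInstruments <- function(x, p_threshold = 5e-8) {
  df <- .variant_df(x)
  sel <- df[df$P < p_threshold, , drop = FALSE]
  sel[order(sel$P, sel$SNP), , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the most significant remaining SNP and discards all
#' remaining SNPs within \code{window_kb} of it (same chromosome) whose LD
#' r-squared with it is at least \code{r2_threshold}. With no LD matrix all
#' pairs are treated as independent (with a warning). Ties in p are broken
#' by SNP ID.
#'
#' @param x Candidate instruments ([GwasSumstats-class] or data.frame),
#'   normally the output of [selectInstruments()].
#' @param ld Square r-squared matrix with SNP-ID dimnames covering all
#'   in-window candidate pairs, or \code{NULL}.
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return data.frame of retained (index) variants, sorted by p.
#' @export
clumpInstruments <- function(x, ld = NULL, r2_threshold = 0.001,
                             window_kb = 10000) {
  df <- .variant_df(x)
  df <- df[order(df$P, df$SNP), , drop = FALSE]
  if (nrow(df) <= 1L) return(df)
  if (is.null(ld))
    warning("no LD matrix supplied; treating all candidate pairs as independent")
  alive <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    j <- which(alive)
    if (!length(j)) break
    inwin <- df$CHR[j] == df$CHR[i] &
      abs(df$POS[j] - df$POS[i]) <= window_kb * 1000
    jw <- j[inwin]
    if (!length(jw) || is.null(ld)) next
    pair_ok <- df$SNP[i] %in% rownames(ld) & df$SNP[jw] %in% colnames(ld)
    if (!all(pair_ok))
      stop("LD matrix missing entries for in-window pairs of ", df$SNP[i])
    r2 <- ld[df$SNP[i], df$SNP[jw]]
    alive[jw[r2 >= r2_threshold]] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' Matches on SNP ID and aligns outcome effects to the exposure's effect
#' allele. Alleles that agree are aligned as-is; swapped effect/other alleles
#' flip the outcome beta's sign (and reflect the outcome frequency); strand
#' complements are complemented first and then aligned or flipped. Palindromic
#' SNPs cannot be resolved by allele codes: their orientation is inferred
#' from allele frequencies, and they are kept (action
#' \code{palindromic_inferred}) only when both frequencies lie outside the
#' ambiguity window \eqn{[0.5 - w, 0.5 + w]} and fall on the same side of
#' 0.5; otherwise they are marked \code{removed_palindromic}. Exposure
#' instruments absent from the outcome are marked \code{removed_missing};
#' non-complementary allele mismatches \code{removed_mismatch}. No record is
#' ever silently dropped and exposure effects are never altered.
#'
#' @param exposure_ivs Selected exposure instruments
#'   ([GwasSumstats-class] or data.frame).
#' @param outcome Outcome GWAS ([GwasSumstats-class] or data.frame).
#' @param eaf_ambiguity Half-width of the palindrome ambiguity window
#'   (default 0.08, i.e. frequencies in [0.42, 0.58] are ambiguous).
#' @param exposure_name,outcome_name Trait labels for the result.
#' @return A [HarmonizedSet-class].
#' @export
harmonizeInstruments <- function(exposure_ivs, outcome, eaf_ambiguity = 0.08,
                                 exposure_name = "exposure",
                                 outcome_name = "outcome") {
  ex <- .variant_df(exposure_ivs)
  ou <- .variant_df(outcome)
  if (is(exposure_ivs, "GwasSumstats") && exposure_name == "exposure")
    exposure_name <- exposure_ivs@meta@trait_name
  if (is(outcome, "GwasSumstats") && outcome_name == "outcome")
    outcome_name <- outcome@meta@trait_name
  idx <- match(ex$SNP, ou$SNP)
  k <- nrow(ex)
  res <- data.frame(
    SNP = ex$SNP,
    beta_exp = ex$BETA, se_exp = ex$SE,
    beta_out = NA_real_, se_out = NA_real_,
    eaf_exp = ex$EAF, eaf_out = NA_real_,
    p_exp = ex$P, p_out = NA_real_,
    n_exp = ex$N, n_out = NA_real_,
    action = "removed_missing",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(k)) {
    j <- idx[i]
    if (is.na(j)) next
    ea_x <- ex$A1[i]; oa_x <- ex$A2[i]
    ea_y <- ou$A1[j]; oa_y <- ou$A2[j]
    b_out <- ou$BETA[j]; eaf_out <- ou$EAF[j]
    res$se_out[i] <- ou$SE[j]
    res$p_out[i] <- ou$P[j]
    res$n_out[i] <- ou$N[j]
    if (isPalindromic(ea_x, oa_x)) {
      if (!isPalindromic(ea_y, oa_y) ||
          !setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        res$action[i] <- "removed_mismatch"
        next
      }
      fx <- res$eaf_exp[i]; fy <- eaf_out
      amb <- function(f) is.na(f) || abs(f - 0.5) <= eaf_ambiguity
      if (amb(fx) || amb(fy) || (fx - 0.5) * (fy - 0.5) < 0) {
        res$action[i] <- "removed_palindromic"
        next
      }
      ## concordant frequencies: reported orientations agree, but the outcome
      ## may still list the complementary pair in swapped order; frequency
      ## concordance is the deciding evidence either way.
      res$beta_out[i] <- if (ea_y == ea_x) b_out else -b_out
      res$eaf_out[i] <- if (ea_y == ea_x) fy else 1 - fy
      res$action[i] <- "palindromic_inferred"
      next
    }
    harm <- NULL
    if (ea_y == ea_x && oa_y == oa_x) {
      harm <- list(b = b_out, f = eaf_out, act = "aligned")
    } else if (ea_y == oa_x && oa_y == ea_x) {
      harm <- list(b = -b_out, f = 1 - eaf_out, act = "flipped")
    } else {
      cy <- unname(.complement(ea_y)); co <- unname(.complement(oa_y))
      if (identical(cy, ea_x) && identical(co, oa_x)) {
        harm <- list(b = b_out, f = eaf_out, act = "aligned")
      } else if (identical(cy, oa_x) && identical(co, ea_x)) {
        harm <- list(b = -b_out, f = 1 - eaf_out, act = "flipped")
      }
    }
    if (is.null(harm)) {
      res$action[i] <- "removed_mismatch"
    } else {
      res$beta_out[i] <- harm$b
      res$eaf_out[i] <- harm$f
      res$action[i] <- harm$act
    }
  }
  new("HarmonizedSet", instruments = res,
      exposure = exposure_name, outcome = outcome_name)
}

#' Variance explained implied by a p-value and sample size
#'
#' Inverts a 1-df association test: with \eqn{t^2} the \eqn{F(1, n-2)}
#' quantile at \eqn{1 - p}, returns \eqn{r^2 = t^2 / (t^2 + n - 2)}. Summing
#' over an instrument set gives the set's total variance explained, the
#' \eqn{R^2} that enters the instrument-strength F statistic.
#'
#' @param pvalue P-value(s) in (0, 1].
#' @param n Sample size(s), > 2.
#' @return Squared correlation(s) in [0, 1).
#' @export
r2FromPN <- function(pvalue, n) {
  stopifnot(all(pvalue > 0), all(pvalue <= 1))
  if (any(n <= 2)) stop("sample size must exceed 2")
  t2 <- qf(pvalue, 1, n - 2, lower.tail = FALSE)
  t2[pvalue == 1] <- 0
  t2 / (t2 + n - 2)
}

#' Instrument-strength F statistic
#'
#' \deqn{F = R^2 (N - k - 1) / ((1 - R^2) k)} where \eqn{R^2} is the total
#' exposure variance explained by the \eqn{k} instruments and \eqn{N} the
#' exposure sample size. Values above 10 conventionally indicate adequately
#' strong instruments.
#'
#' @param r2_total Fraction of variance explained, in [0, 1).
#' @param k Number of instruments.
#' @param n Sample size (must exceed \code{k + 1}).
#' @return The F statistic.
#' @examples
#' fStatistic(0.0242, 38, 123665)  # ~80.7
#' @export
fStatistic <- function(r2_total, k, n) {
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must lie in [0, 1)")
  stopifnot(k >= 1, n > k + 1)
  r2_total * (n - k - 1) / ((1 - r2_total) * k)
}

#' Instrument strength summary for a selected set
#'
#' Computes per-SNP variance explained via [r2FromPN()], sums it, and applies
#' [fStatistic()].
#'
#' @param x Instrument set ([GwasSumstats-class] or data.frame).
#' @param n Exposure sample size; defaults to the maximum per-SNP N.
#' @return List with \code{r2_total}, \code{k}, \code{n}, \code{f_stat}.
#' @export
instrumentStrength <- function(x, n = NULL) {
  df <- .variant_df(x)
  if (is.null(n)) n <- max(df$N)
  r2 <- sum(r2FromPN(df$P, df$N))
  list(r2_total = r2, k = nrow(df), n = n,
       f_stat = fStatistic(r2, nrow(df), n))
}

#' Subset instruments by functional annotation
#'
#' Used, e.g., to restrict HbA1c instruments to those acting through
#' glycaemic (rather than erythrocytic) pathways.
#'
#' @param x Instrument set ([GwasSumstats-class] or data.frame).
#' @param annotation_map Named character vector (SNP ID -> label) or
#'   two-column data.frame (snp_id, label).
#' @param keep_label Label to retain.
#' @param default_label Label assumed for SNPs absent from the map.
#' @return data.frame of instruments carrying \code{keep_label}.
#' @export
subsetByAnnotation <- function(x, annotation_map, keep_label,
                               default_label = "unannotated") {
  df <- .variant_df(x)
  if (is.data.frame(annotation_map))
    annotation_map <- setNames(as.character(annotation_map[[2]]),
                               as.character(annotation_map[[1]]))
  lab <- annotation_map[df$SNP]
  lab[is.na(lab)] <- default_label
  df[lab == keep_label, , drop = FALSE]
}

#' Covariate-stable instruments across two versions of an exposure GWAS
#'
#' Partitions the union of instruments from a covariate-adjusted and an
#' unadjusted scan of the same exposure into those significant in both
#' (the stable set), only in the adjusted scan, or only in the unadjusted
#' scan.
#'
#' @param ivs_adjusted,ivs_unadjusted Variant tables ([GwasSumstats-class]
#'   or data.frame) over a shared SNP universe.
#' @param p_threshold Significance level (default 5e-8).
#' @return List with data.frames \code{stable} (adjusted-scan rows),
#'   \code{adjusted_only}, \code{unadjusted_only}.
#' @export
stableInstruments <- function(ivs_adjusted, ivs_unadjusted,
                              p_threshold = 5e-8) {
  a <- .variant_df(ivs_adjusted)
  u <- .variant_df(ivs_unadjusted)
  if (!length(intersect(a$SNP, u$SNP)))
    stop("the two instrument sets share no SNP IDs")
  sig_a <- a$SNP[a$P < p_threshold]
  sig_u <- u$SNP[u$P < p_threshold]
  list(
    stable = a[a$SNP %in% intersect(sig_a, sig_u), , drop = FALSE],
    adjusted_only = a[a$SNP %in% setdiff(sig_a, sig_u), , drop = FALSE],
    unadjusted_only = u[u$SNP %in% setdiff(sig_u, sig_a), , drop = FALSE]
  )
}

#' Remove instruments shared with a potential confounder GWAS
#'
#' Drops instruments whose association p-value in the confounder GWAS (e.g.
#' BMI) is below \code{p_threshold}; instruments absent from the confounder
#' file are retained.
#'
#' @param x Instrument set ([GwasSumstats-class] or data.frame).
#' @param confounder Confounder GWAS ([GwasSumstats-class] or data.frame).
#' @param p_threshold Significance level (default 5e-8).
#' @return List with \code{kept} (data.frame) and \code{dropped} (SNP IDs).
#' @export
removeSharedHits <- function(x, confounder, p_threshold = 5e-8) {
  df <- .variant_df(x)
  cf <- .variant_df(confounder)
  p_cf <- cf$P[match(df$SNP, cf$SNP)]
  hit <- !is.na(p_cf) & p_cf < p_threshold
  if (all(hit))
    warning("every instrument is associated with the confounder at the threshold")
  list(kept = df[!hit, , drop = FALSE], dropped = df$SNP[hit])
}
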