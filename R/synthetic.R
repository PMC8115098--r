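## Synthetic GWAS summary statistics with known causal truth.
##
## The instrument-level generator mirrors the design of the study that
## motivates the package: a handful of genome-wide-significant instruments
## for a continuous glycaemic-like exposure (the defaults copy the fasting
## insulin instrument set: 14 IVs explaining 0.64% of variance at
## n = 108,557) tested against a large case-control outcome
## (n = 72,515), with configurable causal effect and pleiotropy.

#' Construct the generating truth of a synthetic two-sample MR dataset
#'
#' Defaults mirror the motivating study design: 14 instruments explaining
#' 0.64\% of exposure variance at n_exp = 108,557, outcome n = 72,515, true
#' causal effect -0.72 (log-odds per exposure unit), no pleiotropy.
#'
#' @param beta_causal True causal effect (default -0.72).
#' @param pleiotropy_model \code{"none"} (default), \code{"balanced"},
#'   \code{"directional"} or \code{"correlated"} (InSIDE-violating).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-instrument
#'   direct effects on the outcome (per-allele outcome scale).
#' @param pleiotropy_cor Coefficient on the exposure effect in the
#'   \code{correlated} model.
#' @param frac_invalid Fraction of instruments receiving a pleiotropic
#'   effect (default 1 when a pleiotropy model is active).
#' @param n_iv Number of true instruments (default 14).
#' @param n_null Background null SNPs included in both tables (default 100).
#' @param n_exp,n_out GWAS sample sizes (defaults 108,557 and 72,515).
#' @param case_prop_out Case proportion of the binary outcome GWAS (default
#'   0.234, i.e. 16,992 cases of 72,515); outcome standard errors follow
#'   the log-odds sampling variance \eqn{1/(2f(1-f) n P(1-P))}.
#' @param maf_range Allele-frequency range (default [0.05, 0.5]).
#' @param r2_total Total exposure variance explained by the instruments
#'   (default 0.0064).
#' @param prop_palindromic Fraction of SNPs assigned palindromic allele
#'   pairs (default 0.1), exercising the harmonization paths.
#' @param ld_blocks Integer vector of LD block sizes; each block pads one
#'   instrument with correlated partner SNPs. Empty (default) for
#'   independent instruments.
#' @param ld_r Within-block LD correlation (default 0.8).
#' @param seed RNG seed; identical truth objects regenerate bit-identical
#'   datasets.
#' @return A [SimTruth-class].
#' @export
simTruth <- function(beta_causal = -0.72, pleiotropy_model = "none",
                     pleiotropy_mean = 0, pleiotropy_sd = 0,
                     pleiotropy_cor = 0, frac_invalid = 1,
                     n_iv = 14, n_null = 100,
                     n_exp = 108557, n_out = 72515, case_prop_out = 0.234,
                     maf_range = c(0.05, 0.5), r2_total = 0.0064,
                     prop_palindromic = 0.1,
                     ld_blocks = integer(), ld_r = 0.8, seed = 1) {
  new("SimTruth", beta_causal = beta_causal,
      pleiotropy_model = pleiotropy_model,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      pleiotropy_cor = pleiotropy_cor, frac_invalid = frac_invalid,
      n_iv = as.integer(n_iv), n_null = as.integer(n_null),
      n_exp = n_exp, n_out = n_out, case_prop_out = case_prop_out,
      maf_range = maf_range,
      r2_total = r2_total, prop_palindromic = prop_palindromic,
      ld_blocks = as.integer(ld_blocks), ld_r = ld_r,
      seed = as.integer(seed))
}

.draw_alleles <- function(m, prop_palindromic) {
  pal_pairs <- list(c("A", "T"), c("C", "G"))
  oth_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  is_pal <- runif(m) < prop_palindromic
  t(vapply(seq_len(m), function(i) {
    p <- if (is_pal[i]) sample(pal_pairs, 1)[[1]] else sample(oth_pairs, 1)[[1]]
    if (runif(1) < 0.5) p else rev(p)
  }, character(2)))
}

.sumstats_frame <- function(snp, chr, pos, al, eaf, beta, se, n) {
  p <- 2 * pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin
  data.frame(SNP = snp, CHR = as.character(chr), POS = as.integer(pos),
             A1 = al[, 1], A2 = al[, 2], EAF = eaf, BETA = beta, SE = se,
             P = p, N = n, stringsAsFactors = FALSE)
}

## Per-instrument variance shares: near-equal with mild jitter, normalized.
.r2_shares <- function(n_iv, r2_total) {
  sh <- runif(n_iv, 0.8, 1.2)
  r2_total * sh / sum(sh)
}

#' Simulate an exposure/outcome summary-statistic pair with known truth
#'
#' Draws per-instrument standardized exposure effects whose variance shares
#' sum to the configured \code{r2_total}, converts them to the per-allele
#' scale at simulated allele frequencies, and adds sampling noise with
#' \eqn{se = 1/\sqrt{2 f (1-f) n}}. Outcome effects are
#' \eqn{\beta_{causal}\beta_{exp} + \alpha_j} plus noise, where the direct
#' effects \eqn{\alpha_j} follow the configured pleiotropy model (the
#' \code{correlated} model makes them depend on the exposure effect,
#' violating InSIDE). Background null SNPs are appended, and a fraction of
#' outcome rows is re-coded with swapped alleles or on the opposite strand
#' to exercise harmonization. Generated p-values are exactly consistent with
#' beta/se, so read-time validation always passes.
#'
#' @param truth A [SimTruth-class].
#' @param flip_rate Fraction of outcome rows stored with effect/other
#'   alleles swapped (default 0.2).
#' @param strand_rate Fraction of non-palindromic outcome rows stored on the
#'   opposite strand (default 0.1).
#' @return List with [GwasSumstats-class] elements \code{exposure} and
#'   \code{outcome}, the \code{ld} r-squared matrix over all SNPs, the
#'   \code{truth} object, and \code{iv_ids}, the IDs of the true
#'   instruments.
#' @export
simulateIVDataset <- function(truth, flip_rate = 0.2, strand_rate = 0.1) {
  stopifnot(is(truth, "SimTruth"))
  old <- .Random.seed_exists()
  set.seed(truth@seed)
  on.exit(.restore_seed(old))

  k <- truth@n_iv
  r2 <- .r2_shares(k, truth@r2_total)
  z_gw <- qnorm(2.5e-8, lower.tail = FALSE)  # two-sided 5e-8
  exp_z <- sqrt(truth@n_exp * r2)
  if (any(exp_z < z_gw)) {
    need <- z_gw^2 / truth@n_exp
    stop("infeasible configuration: instrument expected chi-square below the ",
         "genome-wide threshold at n_exp = ", truth@n_exp,
         "; minimal feasible per-instrument r2 is ", signif(need, 3))
  }

  n_blk_extra <- if (length(truth@ld_blocks)) sum(truth@ld_blocks - 1L) else 0L
  m <- k + truth@n_null + n_blk_extra
  snp <- sprintf("rs%06d", seq_len(m))
  chr <- rep(rep(1:22, length.out = k + truth@n_null),
             times = c(rep(1, k + truth@n_null)))
  chr <- as.character(chr)
  pos <- seq_len(k + truth@n_null) * 1000000L
  f <- runif(m, truth@maf_range[1], truth@maf_range[2])
  al <- .draw_alleles(m, truth@prop_palindromic)

  ## true standardized exposure effects for instruments; null SNPs are zero
  b_std <- c(sqrt(r2) * sample(c(-1, 1), k, replace = TRUE),
             rep(0, truth@n_null))
  chr_all <- c(chr, rep(NA_character_, n_blk_extra))
  pos_all <- c(pos, rep(NA_integer_, n_blk_extra))

  ## LD-block partners: correlated neighbours of the first instruments
  ld <- diag(m)
  if (length(truth@ld_blocks)) {
    nxt <- k + truth@n_null
    for (bi in seq_along(truth@ld_blocks)) {
      size <- truth@ld_blocks[bi]
      anchor <- bi  # block around instrument bi
      partners <- nxt + seq_len(size - 1L)
      nxt <- nxt + size - 1L
      chr_all[partners] <- chr_all[anchor]
      pos_all[partners] <- pos_all[anchor] + seq_len(size - 1L) * 5000L
      b_std <- c(b_std, rep(truth@ld_r * b_std[anchor], size - 1L))
      idx <- c(anchor, partners)
      ld[idx, idx] <- truth@ld_r^2
      diag(ld)[idx] <- 1
    }
  } else if (n_blk_extra == 0L && length(b_std) < m) {
    b_std <- c(b_std, rep(0, m - length(b_std)))
  }
  dimnames(ld) <- list(snp, snp)

  scale_allele <- 1 / sqrt(2 * f * (1 - f))
  b_exp_true <- b_std * scale_allele
  se_exp <- scale_allele / sqrt(truth@n_exp)
  b_exp_hat <- b_exp_true + rnorm(m, 0, se_exp)

  ## pleiotropic direct effects on the outcome (per-allele scale)
  alpha <- rep(0, m)
  if (truth@pleiotropy_model != "none") {
    n_inv <- round(truth@frac_invalid * k)
    inv <- seq_len(k) %in% sample(seq_len(k), n_inv)
    ## balanced/directional effects are defined relative to the
    ## exposure-increasing allele, the frame in which the Egger intercept
    ## estimates their mean; correlated effects carry the sign naturally
    sgn <- sign(b_exp_true[seq_len(k)])
    sgn[sgn == 0] <- 1
    a <- switch(truth@pleiotropy_model,
      balanced = sgn * rnorm(k, 0, truth@pleiotropy_sd),
      directional = sgn * rnorm(k, truth@pleiotropy_mean, truth@pleiotropy_sd),
      correlated = truth@pleiotropy_cor * b_exp_true[seq_len(k)] +
        rnorm(k, 0, truth@pleiotropy_sd))
    alpha[seq_len(k)] <- a * inv
  }
  b_out_true <- truth@beta_causal * b_exp_true + alpha
  cp <- truth@case_prop_out
  se_out <- scale_allele / sqrt(truth@n_out * cp * (1 - cp))
  b_out_hat <- b_out_true + rnorm(m, 0, se_out)

  exp_df <- .sumstats_frame(snp, chr_all, pos_all, al, f,
                            b_exp_hat, se_exp, truth@n_exp)

  ## outcome table, with harmonization corruptions
  al_out <- al
  f_out <- f
  b_out_rec <- b_out_hat
  do_flip <- runif(m) < flip_rate
  al_out[do_flip, ] <- al_out[do_flip, c(2, 1), drop = FALSE]
  b_out_rec[do_flip] <- -b_out_rec[do_flip]
  f_out[do_flip] <- 1 - f_out[do_flip]
  pal <- isPalindromic(al_out[, 1], al_out[, 2])
  do_strand <- runif(m) < strand_rate & !pal
  al_out[do_strand, ] <- cbind(.complement(al_out[do_strand, 1]),
                               .complement(al_out[do_strand, 2]))
  out_df <- .sumstats_frame(snp, chr_all, pos_all, al_out, f_out,
                            b_out_rec, se_out, truth@n_out)

  meta_exp <- studyMeta("sim_exposure", "continuous", unit = "SD",
                        n = truth@n_exp)
  meta_out <- studyMeta("sim_outcome", "binary", unit = "log-odds",
                        n = truth@n_out,
                        n_cases = round(truth@n_out * truth@case_prop_out),
                        prevalence = 0.009)
  zero <- setNames(integer(0), character(0))
  list(
    exposure = new("GwasSumstats", variants = exp_df, meta = meta_exp,
                   dropCounts = zero),
    outcome = new("GwasSumstats", variants = out_df, meta = meta_out,
                  dropCounts = zero),
    ld = ld,
    truth = truth,
    iv_ids = snp[seq_len(k)]
  )
}

#' Simulate covariate-adjusted and unadjusted exposure scans
#'
#' Produces two exposure summary tables over the same instruments from the
#' same underlying effects, where a chosen fraction of instruments loses
#' genome-wide significance in the unadjusted scan (their unadjusted
#' expected z-score is set to 3, far below the significance threshold).
#' The design-level stable set — instruments whose expected association is
#' genome-wide significant in both scans — is recorded in the result.
#'
#' @param truth A [SimTruth-class].
#' @param covariate_shift_fraction Fraction of instruments that are only
#'   significant in the adjusted scan.
#' @return List with [GwasSumstats-class] elements \code{adjusted} and
#'   \code{unadjusted}, and \code{stable_ids}, the design-level stable SNP
#'   IDs.
#' @export
simulateBMIPair <- function(truth, covariate_shift_fraction = 6 / 14) {
  stopifnot(is(truth, "SimTruth"),
            covariate_shift_fraction >= 0, covariate_shift_fraction <= 1)
  old <- .Random.seed_exists()
  set.seed(truth@seed)
  on.exit(.restore_seed(old))

  k <- truth@n_iv
  r2 <- .r2_shares(k, truth@r2_total)
  z_gw <- qnorm(2.5e-8, lower.tail = FALSE)
  if (any(sqrt(truth@n_exp * r2) < z_gw))
    stop("infeasible configuration: instruments not significant at n_exp")

  snp <- sprintf("rs%06d", seq_len(k))
  chr <- as.character(rep(1:22, length.out = k))
  pos <- seq_len(k) * 1000000L
  f <- runif(k, truth@maf_range[1], truth@maf_range[2])
  al <- .draw_alleles(k, truth@prop_palindromic)
  b_std <- sqrt(r2) * sample(c(-1, 1), k, replace = TRUE)
  scale_allele <- 1 / sqrt(2 * f * (1 - f))
  se <- scale_allele / sqrt(truth@n_exp)

  n_shift <- round(covariate_shift_fraction * k)
  shifted <- sample(seq_len(k), n_shift)
  shrink <- rep(1, k)
  ## unadjusted expected z of shifted instruments pinned at 2: associated,
  ## but comfortably below genome-wide significance
  shrink[shifted] <- 2 / sqrt(truth@n_exp * r2[shifted])

  b_adj <- b_std * scale_allele + rnorm(k, 0, se)
  b_unadj <- b_std * shrink * scale_allele + rnorm(k, 0, se)

  meta <- studyMeta("sim_exposure", "continuous", unit = "SD", n = truth@n_exp)
  zero <- setNames(integer(0), character(0))
  list(
    adjusted = new("GwasSumstats",
                   variants = .sumstats_frame(snp, chr, pos, al, f, b_adj,
                                              se, truth@n_exp),
                   meta = meta, dropCounts = zero),
    unadjusted = new("GwasSumstats",
                     variants = .sumstats_frame(snp, chr, pos, al, f,
                                                b_unadj, se, truth@n_exp),
                     meta = meta, dropCounts = zero),
    stable_ids = snp[setdiff(seq_len(k), shifted)]
  )
}

#' Simulate genome-wide summary statistics under a latent causal model
#'
#' Draws per-SNP standardized effects for two traits from a shared latent
#' factor plus trait-specific polygenic backgrounds. The latent loadings
#' realize a target genetic causality proportion: with per-SNP genetic
#' variances \eqn{v_t \propto h_t^2 \ell_j} (so LD-score regression holds),
#' the latent components have standard deviations
#' \eqn{\sqrt{v_1}|\rho|^{(1-g)/2}} and \eqn{\sqrt{v_2}|\rho|^{(1+g)/2}}
#' (signed by \eqn{\rho}), giving genetic correlation \eqn{\rho} at every
#' \eqn{g} and full causality of trait 1 on trait 2 at \eqn{g = 1}. The
#' latent factor is sparse (point-normal), hence strongly kurtotic, which is
#' what identifies the causality proportion from mixed fourth moments.
#'
#' @param m Number of SNPs (default 20000).
#' @param h2 Length-2 vector of SNP-heritabilities in (0,1).
#' @param rho_g Genetic correlation in (-1, 1).
#' @param gcp_truth Genetic causality proportion in [-1, 1].
#' @param n1,n2 GWAS sample sizes.
#' @param pi_latent Fraction of SNPs loading on the latent factor
#'   (default 0.01; smaller is more kurtotic).
#' @param pi_background Fraction of SNPs with trait-specific effects
#'   (default 0.1).
#' @param seed RNG seed.
#' @return List with [GwasSumstats-class] elements \code{trait1},
#'   \code{trait2}, and \code{ld_scores} (named vector).
#' @export
simulateGenomewide <- function(m = 20000, h2 = c(0.25, 0.25), rho_g = 0.35,
                               gcp_truth = 0, n1 = 1e5, n2 = 1e5,
                               pi_latent = 0.01, pi_background = 0.1,
                               seed = 1) {
  if (any(h2 <= 0) || any(h2 >= 1))
    stop("infeasible configuration: heritabilities must lie in (0,1)")
  if (abs(rho_g) >= 1)
    stop("infeasible configuration: rho_g must lie in (-1,1)")
  if (abs(gcp_truth) > 1) stop("gcp_truth must lie in [-1, 1]")
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old))

  ell <- 1 + rexp(m)
  v1 <- h2[1] * ell / sum(ell)
  v2 <- h2[2] * ell / sum(ell)
  ar <- abs(rho_g)
  if (ar == 0) {
    q1 <- q2 <- rep(0, m)
  } else {
    q1 <- sqrt(v1) * ar^((1 - gcp_truth) / 2)
    q2 <- sign(rho_g) * sqrt(v2) * ar^((1 + gcp_truth) / 2)
  }
  d1 <- sqrt(pmax(0, v1 - q1^2))
  d2 <- sqrt(pmax(0, v2 - q2^2))

  point_normal <- function(m, pi) {
    ind <- rbinom(m, 1, pi)
    ind * rnorm(m, 0, 1 / sqrt(pi))
  }
  gam <- point_normal(m, pi_latent)
  a1 <- q1 * gam + d1 * point_normal(m, pi_background)
  a2 <- q2 * gam + d2 * point_normal(m, pi_background)

  z1 <- sqrt(n1) * a1 + rnorm(m)
  z2 <- sqrt(n2) * a2 + rnorm(m)

  snp <- sprintf("rs%07d", seq_len(m))
  chr <- as.character(rep(1:22, length.out = m))
  pos <- as.integer(seq_len(m) * 10000L)
  f <- runif(m, 0.05, 0.5)
  oth_pairs <- matrix(c("A", "G"), m, 2, byrow = TRUE)
  mk <- function(z, n, trait) {
    se <- 1 / sqrt(2 * f * (1 - f) * n)
    new("GwasSumstats",
        variants = .sumstats_frame(snp, chr, pos, oth_pairs, f, z * se, se, n),
        meta = studyMeta(trait, "continuous", unit = "SD", n = n),
        dropCounts = setNames(integer(0), character(0)))
  }
  list(trait1 = mk(z1, n1, "sim_trait1"),
       trait2 = mk(z2, n2, "sim_trait2"),
       ld_scores = setNames(ell, snp))
}
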