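## Latent causal variable model: genetic causality proportion from
## genome-wide summary statistics.
##
## The model: a latent factor L mediates the genetic correlation rho between
## two traits; trait t's standardized per-SNP effects are
## alpha_t = q_t gamma + delta_t with a kurtotic latent loading gamma. Under
## the parametrization q1 = |rho|^{(1-g)/2}, q2 = sign(rho) |rho|^{(1+g)/2}
## (standardized scale), g is the genetic causality proportion: g = 1 means
## trait 1 IS the latent factor (full genetic causality 1 -> 2), g = -1 the
## reverse. The excess mixed fourth moments
##   k41 = E[a1^3 a2] - 3 E[a1^2] E[a1 a2] = sign(rho) |rho|^{2-g} kappa
##   k14 = E[a1 a2^3] - 3 E[a2^2] E[a1 a2] = sign(rho) |rho|^{2+g} kappa
## (kappa the latent excess kurtosis) identify g: the statistic
##   D(g0) = |rho|^{g0} k41' - |rho|^{-g0} k14'   (k' = sign(rho) k)
## has expectation zero iff g0 equals the true g. The estimator computes
## D(g0) over a grid, converts block-jackknife t-statistics to an
## approximate likelihood, and reports the posterior-mean g under a flat
## prior; hypothesis tests of g = 0 and g = +/-1 are jackknife t-tests of
## D(0), D(1), D(-1).

## Align trait2 effects to trait1's effect allele by SNP ID.
## Returns merged data.frame with z1, z2 columns; mismatches dropped.
.align_pair <- function(t1, t2) {
  d1 <- if (is(t1, "GwasSumstats")) t1@variants else as.data.frame(t1)
  d2 <- if (is(t2, "GwasSumstats")) t2@variants else as.data.frame(t2)
  j <- match(d1$SNP, d2$SNP)
  ok <- !is.na(j)
  d1 <- d1[ok, ]; d2 <- d2[j[ok], ]
  same <- d1$A1 == d2$A1 & d1$A2 == d2$A2
  swap <- d1$A1 == d2$A2 & d1$A2 == d2$A1
  comp <- .complement(d2$A1) == d1$A1 & .complement(d2$A2) == d1$A2
  comp_swap <- .complement(d2$A1) == d1$A2 & .complement(d2$A2) == d1$A1
  keep <- same | swap | comp | comp_swap
  sgn <- ifelse(swap | comp_swap, -1, 1)
  data.frame(SNP = d1$SNP[keep],
             z1 = (d1$BETA / d1$SE)[keep],
             z2 = (sgn * d2$BETA / d2$SE)[keep],
             n1 = d1$N[keep], n2 = d2$N[keep],
             stringsAsFactors = FALSE)
}

## Weighted LD-score regression of y on ell. intercept_free = FALSE pins the
## intercept at `intercept`.
.ldsc_slope <- function(y, ell, w, intercept_free = TRUE, intercept = 0) {
  if (intercept_free) {
    fit <- lm(y ~ ell, weights = w)
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  } else {
    y0 <- y - intercept
    c(slope = sum(w * ell * y0) / sum(w * ell^2), intercept = intercept)
  }
}

## Statistics from weighted moment aggregates.
## agg: named list of sums S_w, S11, S22, S12, S31, S13 (weighted sums of
## a1^2, a2^2, a1 a2, a1^3 a2, a1 a2^3), plus n1, n2.
.lcv_stats <- function(agg, grid) {
  v1 <- agg$S11 / agg$S_w - 1 / agg$n1
  v2 <- agg$S22 / agg$S_w - 1 / agg$n2
  if (v1 <= 0 || v2 <= 0) return(NULL)
  c12 <- agg$S12 / agg$S_w - agg$off12   # off12: sample-overlap intercept
  rho <- c12 / sqrt(v1 * v2)
  ## noise-corrected standardized excess mixed kurtosis
  m31 <- (agg$S31 / agg$S_w - 3 * c12 / agg$n1) / (v1^1.5 * sqrt(v2))
  m13 <- (agg$S13 / agg$S_w - 3 * c12 / agg$n2) / (sqrt(v1) * v2^1.5)
  k41 <- m31 - 3 * rho
  k14 <- m13 - 3 * rho
  s <- if (rho < 0) -1 else 1
  ar <- min(max(abs(rho), 1e-2), 1 - 1e-4)
  list(rho = rho, k41 = k41, k14 = k14,
       D = ar^grid * (s * k41) - ar^(-grid) * (s * k14))
}

.jackknife_se <- function(theta_blocks, n_blocks) {
  tb <- colMeans(theta_blocks)
  sqrt((n_blocks - 1) / n_blocks *
         colSums(sweep(theta_blocks, 2, tb)^2))
}

#' Estimate the genetic causality proportion (latent causal variable model)
#'
#' Takes two munged, allele-alignable genome-wide summary-statistic sets and
#' per-SNP LD scores, estimates heritabilities and the genetic correlation
#' by weighted LD-score regression, and identifies the genetic causality
#' proportion (GCP) from the imbalance of the standardized excess mixed
#' fourth moments of the bivariate effect-size distribution. The point
#' estimate is the posterior mean of the GCP over a flat prior on
#' \eqn{[-1, 1]}, using an approximate likelihood built from block-jackknife
#' t-statistics of the grid moment condition; its standard error is the
#' block jackknife SE of that posterior mean. Tests of GCP = 0 (no partial
#' causality) and GCP = \eqn{\pm 1} (full genetic causality in either
#' direction) are jackknife t-tests with \code{n_blocks - 1} degrees of
#' freedom. Positive GCP means trait 1 is partially genetically causal for
#' trait 2. SNP weights are \eqn{1/\max(1, \ell_j)} throughout, discounting
#' high-LD SNPs that tag many others.
#'
#' @param trait1,trait2 Munged [GwasSumstats-class] objects (or canonical
#'   data.frames); SNPs are intersected and trait 2 allele-aligned to
#'   trait 1.
#' @param ld_scores Named numeric vector of per-SNP LD scores.
#' @param n_blocks Number of contiguous jackknife blocks (default 100).
#' @param overlap If \code{TRUE}, estimates a sample-overlap intercept from
#'   the cross-trait LD-score regression and subtracts it from the cross
#'   moments; off by default (non-overlapping GWAS).
#' @param seed Unused; the estimator is deterministic. Retained for
#'   interface stability.
#' @return An [LCVResult-class].
#' @export
estimateLCV <- function(trait1, trait2, ld_scores, n_blocks = 100,
                        overlap = FALSE, seed = NULL) {
  d <- .align_pair(trait1, trait2)
  d <- d[d$SNP %in% names(ld_scores), , drop = FALSE]
  m <- nrow(d)
  if (m < 10 * n_blocks)
    stop("insufficient SNPs: need at least ", 10 * n_blocks,
         " intersected SNPs for ", n_blocks, " jackknife blocks")
  ell <- unname(ld_scores[d$SNP])
  w <- 1 / pmax(1, ell)
  n1 <- mean(d$n1); n2 <- mean(d$n2)

  ## LD-score regressions: heritabilities and genetic correlation.
  ## E[z^2] = 1 + n h2 l_j / sum(l), so h2 = slope * sum(l) / n.
  L <- sum(ell)
  f1 <- .ldsc_slope(d$z1^2, ell, w)
  f2 <- .ldsc_slope(d$z2^2, ell, w)
  h2_1 <- f1["slope"] * L / n1
  h2_2 <- f2["slope"] * L / n2
  if (h2_1 <= 0) stop("degenerate heritability estimate (<= 0) for trait 1")
  if (h2_2 <= 0) stop("degenerate heritability estimate (<= 0) for trait 2")
  ## sample overlap shows up as a constant term in E[z1 z2]; estimate it
  ## from the cross regression only when requested
  off12 <- if (overlap) {
    fx <- .ldsc_slope(d$z1 * d$z2, ell, w)
    unname(fx["intercept"]) / sqrt(n1 * n2)
  } else 0

  ## per-block weighted moment sums
  a1 <- d$z1 / sqrt(n1)
  a2 <- d$z2 / sqrt(n2)
  blk <- cut(seq_len(m), n_blocks, labels = FALSE)
  bs <- function(x) as.numeric(rowsum(x, blk))
  S <- list(S_w = bs(w), S11 = bs(w * a1^2), S22 = bs(w * a2^2),
            S12 = bs(w * a1 * a2), S31 = bs(w * a1^3 * a2),
            S13 = bs(w * a1 * a2^3))
  tot <- lapply(S, sum)

  grid <- seq(-1, 1, by = 0.01)
  agg_full <- c(tot, n1 = n1, n2 = n2, off12 = off12)
  full <- .lcv_stats(agg_full, grid)
  if (is.null(full))
    stop("degenerate heritability estimate (<= 0) in the moment step")

  ## delete-one-block statistics
  D_blocks <- matrix(NA_real_, n_blocks, length(grid))
  for (b in seq_len(n_blocks)) {
    agg_b <- lapply(names(S), function(nm) tot[[nm]] - S[[nm]][b])
    names(agg_b) <- names(S)
    st <- .lcv_stats(c(agg_b, n1 = n1, n2 = n2, off12 = off12), grid)
    D_blocks[b, ] <- if (is.null(st)) full$D else st$D
  }
  se_D <- .jackknife_se(D_blocks, n_blocks)
  se_D[se_D == 0] <- .Machine$double.eps
  tstat <- full$D / se_D
  df <- n_blocks - 1

  ## approximate likelihood over the grid -> posterior mean under flat prior
  post_mean <- function(tvec) {
    lw <- dt(tvec, df, log = TRUE)
    wgt <- exp(lw - max(lw))
    sum(grid * wgt) / sum(wgt)
  }
  gcp_hat <- post_mean(tstat)
  pm_blocks <- vapply(seq_len(n_blocks), function(b)
    post_mean(D_blocks[b, ] / se_D), numeric(1))
  gcp_se <- .jackknife_se(matrix(pm_blocks, ncol = 1), n_blocks)

  pval_at <- function(g) {
    i <- which.min(abs(grid - g))
    max(2 * pt(-abs(tstat[i]), df), .Machine$double.xmin)
  }
  new("LCVResult",
      gcp = min(max(gcp_hat, -1), 1),
      gcp_se = as.numeric(gcp_se),
      p_gcp_zero = pval_at(0),
      p_full_causal_fwd = pval_at(1),
      p_full_causal_rev = pval_at(-1),
      rho_g = min(max(full$rho, -1), 1),
      h2 = c(unname(h2_1), unname(h2_2)))
}
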