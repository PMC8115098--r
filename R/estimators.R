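## Causal-effect estimators for harmonized two-sample MR instrument sets.
##
## All estimators take a HarmonizedSet (or a data.frame with columns
## beta_exp, se_exp, beta_out, se_out) and return an MRFit. P-values are
## two-sided from the normal distribution (summary-data asymptotics).

.h_df <- function(h, min_k, method) {
  df <- if (is(h, "HarmonizedSet")) usable(h) else as.data.frame(h)
  if (!is.null(df$action))
    df <- df[!startsWith(df$action, "removed"), , drop = FALSE]
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("harmonized set lacks columns: ", paste(miss, collapse = ", "))
  if (!"SNP" %in% names(df)) df$SNP <- paste0("iv", seq_len(nrow(df)))
  if (nrow(df) < min_k)
    stop(method, " requires at least ", min_k, " usable instruments (got ",
         nrow(df), ")")
  df
}

.mrfit <- function(method, beta, se, k, extra = list(), level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  new("MRFit", method = method, beta = beta, se = se,
      ci_low = beta - z * se, ci_high = beta + z * se,
      pvalue = max(p, .Machine$double.xmin), k_used = as.integer(k),
      extra = extra)
}

#' Per-instrument Wald ratio estimates
#'
#' For each usable instrument, the ratio \eqn{\beta_{out}/\beta_{exp}} and
#' its delta-method standard error including the second-order exposure term:
#' \deqn{se^2 = se_{out}^2/\beta_{exp}^2 +
#'   \beta_{out}^2 se_{exp}^2/\beta_{exp}^4.}
#' Instruments with \eqn{\beta_{exp} = 0} are excluded with a warning.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @return data.frame with columns \code{SNP}, \code{ratio}, \code{ratio_se}.
#' @export
ratioEstimates <- function(h) {
  df <- .h_df(h, 1L, "ratio_estimates")
  zero <- df$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect excluded")
    df <- df[!zero, , drop = FALSE]
  }
  ratio <- df$beta_out / df$beta_exp
  ratio_se <- sqrt(df$se_out^2 / df$beta_exp^2 +
                   df$beta_out^2 * df$se_exp^2 / df$beta_exp^4)
  data.frame(SNP = df$SNP, ratio = ratio, ratio_se = ratio_se,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' Weighted mean of the Wald ratios with first-order weights
#' \eqn{w_j = \beta_{exp,j}^2 / se_{out,j}^2}. The default multiplicative
#' random-effects model inflates the fixed-effects standard error by
#' \eqn{\max(1, \sqrt{Q/(k-1)})} where Q is Cochran's heterogeneity
#' statistic; the inflation never deflates below the fixed-effects SE.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @param random_effects \code{"multiplicative"} (default) or \code{"fixed"}.
#' @return An [MRFit-class]; \code{extra} carries \code{Q} and the
#'   \code{se_inflation} applied.
#' @export
mrIVW <- function(h, random_effects = c("multiplicative", "fixed")) {
  random_effects <- match.arg(random_effects)
  df <- .h_df(h, 2L, "IVW")
  w <- df$beta_exp^2 / df$se_out^2
  r <- df$beta_out / df$beta_exp
  beta <- sum(w * r) / sum(w)
  k <- nrow(df)
  q <- sum(w * (r - beta)^2)
  se <- sqrt(1 / sum(w))
  infl <- 1
  if (random_effects == "multiplicative" && k > 1) {
    infl <- max(1, sqrt(q / (k - 1)))
    se <- se * infl
  }
  .mrfit(paste0("ivw_", random_effects), beta, se, k,
         extra = list(Q = q, se_inflation = infl))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept representing the average directional pleiotropic effect.
#' Instruments are first oriented so every exposure effect is non-negative
#' (the intercept is only interpretable in that orientation). Weights are
#' \eqn{1/se_{out}^2}; standard errors use the multiplicative
#' random-effects inflation with floor 1 on \eqn{k - 2} degrees of freedom.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @return An [MRFit-class] for the slope; \code{extra} carries
#'   \code{intercept}, \code{intercept_se}, \code{intercept_p}, \code{i2_gx}.
#' @export
mrEgger <- function(h) {
  df <- .h_df(h, 3L, "MR-Egger")
  flip <- sign(df$beta_exp)
  flip[flip == 0] <- 1
  bx <- df$beta_exp * flip
  by <- df$beta_out * flip
  w <- 1 / df$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- if (is.finite(sigma) && sigma > 0) min(1, sigma) else 1
  est <- coef(sm)
  b <- est["bx", "Estimate"]
  b_se <- est["bx", "Std. Error"] / scale
  a <- est["(Intercept)", "Estimate"]
  a_se <- est["(Intercept)", "Std. Error"] / scale
  a_p <- if (a_se > 0) 2 * pnorm(-abs(a / a_se)) else as.numeric(a == 0)
  .mrfit("egger", b, b_se, nrow(df),
         extra = list(intercept = a, intercept_se = a_se, intercept_p = a_p,
                      i2_gx = i2GX(df), sigma = sigma))
}

#' I-squared of the instrument-exposure effects
#'
#' Quantifies the relative strength of the no-measurement-error (NOME)
#' assumption for MR-Egger: \eqn{Q_{GX} = \sum (\beta_{exp,j} - \mu_w)^2 /
#' se_{exp,j}^2} over oriented (non-negative) exposure effects, with
#' \eqn{\mu_w} their inverse-variance-weighted mean, and
#' \eqn{I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX})}. Values above 0.9
#' conventionally deem the instruments appropriate for MR-Egger.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @return A fraction in [0, 1).
#' @export
i2GX <- function(h) {
  df <- .h_df(h, 2L, "I2_GX")
  bx <- abs(df$beta_exp)
  w <- 1 / df$se_exp^2
  mu <- sum(w * bx) / sum(w)
  q <- sum((bx - mu)^2 * w)
  if (q <= 0) return(0)
  max(0, (q - (nrow(df) - 1)) / q)
}

## Weighted 50th percentile by linear interpolation of cumulative
## normalized weights (the weighted-median MR interpolation rule).
.weighted_percentile <- function(x, w, prob = 0.5) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cum <- cumsum(w) / sum(w) - w / (2 * sum(w))
  if (prob <= cum[1]) return(x[1])
  n <- length(x)
  if (prob >= cum[n]) return(x[n])
  j <- max(which(cum < prob))
  x[j] + (x[j + 1] - x[j]) * (prob - cum[j]) / (cum[j + 1] - cum[j])
}

.boot_se <- function(df, estimator, n_boot, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bs <- df
    bs$beta_exp <- rnorm(nrow(df), df$beta_exp, df$se_exp)
    bs$beta_out <- rnorm(nrow(df), df$beta_out, df$se_out)
    est[b] <- estimator(bs)
  }
  .restore_seed(old)
  sd(est)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.median_point <- function(df) {
  r <- df$beta_out / df$beta_exp
  rse2 <- df$se_out^2 / df$beta_exp^2 +
    df$beta_out^2 * df$se_exp^2 / df$beta_exp^4
  .weighted_percentile(r, 1 / rse2)
}

#' Weighted median estimator
#'
#' The weighted 50th percentile of the Wald ratio estimates, with
#' second-order delta-method inverse-variance weights (see
#' [ratioEstimates()]). Consistent when at least half the total weight comes
#' from valid instruments ("majority valid"). The standard error is obtained
#' by seeded parametric bootstrap: exposure and outcome effects are
#' resampled from their normal sampling distributions and the estimate
#' recomputed.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MRFit-class]; \code{extra} carries \code{n_boot}.
#' @export
mrMedian <- function(h, n_boot = 1000, seed = 1) {
  df <- .h_df(h, 3L, "weighted median")
  beta <- .median_point(df)
  se <- .boot_se(df, .median_point, n_boot, seed)
  .mrfit("weighted_median", beta, se, nrow(df),
         extra = list(n_boot = n_boot))
}

.mode_point <- function(df, bandwidth_factor = 1) {
  r <- df$beta_out / df$beta_exp
  rse2 <- df$se_out^2 / df$beta_exp^2 +
    df$beta_out^2 * df$se_exp^2 / df$beta_exp^4
  w <- 1 / rse2
  s <- mad(r)
  if (s <= 0) s <- sd(r)
  h_bw <- bandwidth_factor * 0.9 * min(sd(r), s) * length(r)^(-1 / 5)
  if (!is.finite(h_bw) || h_bw <= 0)
    return(.weighted_percentile(r, w))  # degenerate spread: all ratios equal
  d <- density(r, weights = w / sum(w), bw = h_bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Weighted mode estimator
#'
#' The maximiser of a Gaussian-kernel weighted density over the Wald ratio
#' estimates, with inverse-variance (second-order) weights and bandwidth
#' \code{bandwidth_factor} times the modified Silverman rule
#' \eqn{0.9 \min(sd, mad) k^{-1/5}}. Consistent when the largest group of
#' instruments sharing a causal ratio is valid ("plurality valid"). Standard
#' error by seeded parametric bootstrap.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MRFit-class].
#' @export
mrMode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  df <- .h_df(h, 3L, "weighted mode")
  beta <- .mode_point(df, bandwidth_factor)
  se <- .boot_se(df, function(d) .mode_point(d, bandwidth_factor),
                 n_boot, seed)
  .mrfit("weighted_mode", beta, se, nrow(df),
         extra = list(bandwidth_factor = bandwidth_factor, n_boot = n_boot))
}

## Leave-one-out IVW point estimates, vectorized.
.loo_beta <- function(w, r) {
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The observed global residual sum of squares is
#' \eqn{RSS = \sum_j w_j (r_j - \hat\beta_{(-j)})^2} with IVW weights
#' \eqn{w_j} and leave-one-out IVW estimates \eqn{\hat\beta_{(-j)}}. Its
#' null distribution is simulated by drawing, \code{n_sim} times, outcome
#' effects from \eqn{N(\beta_{exp,j}\hat\beta_{(-j)}, se_{out,j}^2)} and
#' exposure effects from \eqn{N(\beta_{exp,j}, se_{exp,j}^2)} and recomputing
#' the RSS (with fresh leave-one-out estimates). The global p is the
#' empirical exceedance fraction. Each instrument's observed residual is
#' compared with its simulated distribution for a per-instrument outlier p,
#' Bonferroni-corrected over k; flagged outliers are removed and the IVW
#' re-estimated. The outlier-corrected fit is returned (the distortion test
#' is not implemented).
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame (>= 4 usable
#'   instruments).
#' @param n_sim Number of null simulations (>= 100 and >= k/outlier_alpha).
#' @param outlier_alpha Significance level for the Bonferroni-corrected
#'   per-instrument outlier test (default 0.05).
#' @param seed RNG seed.
#' @return An [MRFit-class]; \code{extra} carries \code{global_p},
#'   \code{outlier_indices}, \code{outlier_snps}, \code{n_sim} and the
#'   uncorrected \code{raw_fit}.
#' @export
mrPresso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  df <- .h_df(h, 4L, "MR-PRESSO")
  k <- nrow(df)
  if (n_sim < max(100, ceiling(k / outlier_alpha)))
    stop("n_sim too small to resolve the Bonferroni-corrected outlier test; ",
         "need at least ", max(100, ceiling(k / outlier_alpha)))
  w <- df$beta_exp^2 / df$se_out^2
  r <- df$beta_out / df$beta_exp
  b_loo <- .loo_beta(w, r)
  res_obs <- w * (r - b_loo)^2
  rss_obs <- sum(res_obs)

  old <- .Random.seed_exists()
  set.seed(seed)
  res_sim <- matrix(0, n_sim, k)
  for (s in seq_len(n_sim)) {
    bx <- rnorm(k, df$beta_exp, df$se_exp)
    by <- rnorm(k, df$beta_exp * b_loo, df$se_out)
    ws <- bx^2 / df$se_out^2
    rs <- by / bx
    bl <- .loo_beta(ws, rs)
    res_sim[s, ] <- ws * (rs - bl)^2
  }
  .restore_seed(old)

  global_p <- (1 + sum(rowSums(res_sim) >= rss_obs)) / (1 + n_sim)
  p_iv <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (1 + n_sim)
  p_iv_bonf <- pmin(1, p_iv * k)
  out_idx <- which(p_iv_bonf < outlier_alpha)

  raw_fit <- mrIVW(df)
  keep <- if (length(out_idx) && k - length(out_idx) >= 2)
    df[-out_idx, , drop = FALSE] else df
  fit <- mrIVW(keep)
  .mrfit("mr_presso", fit@beta, fit@se, nrow(keep),
         extra = list(global_p = global_p,
                      outlier_indices = out_idx,
                      outlier_snps = df$SNP[out_idx],
                      outlier_p = p_iv_bonf,
                      n_sim = n_sim, raw_fit = raw_fit))
}

#' IVW with correlated instruments (generalised least squares)
#'
#' The generalised least squares analogue of [mrIVW()] for instruments in
#' linkage disequilibrium: with \eqn{\Sigma = D \rho D} (\eqn{D} the diagonal
#' of outcome SEs, \eqn{\rho} the signed LD correlation matrix),
#' \deqn{\hat\beta = (x'\Sigma^{-1}x)^{-1} x'\Sigma^{-1}y,} where \eqn{x}
#' are exposure and \eqn{y} outcome effects. With an identity correlation
#' matrix this reduces exactly to the fixed-effects IVW.
#'
#' @param h A [HarmonizedSet-class] or compatible data.frame.
#' @param ld Signed LD correlation matrix over the usable instruments
#'   (SNP-ID dimnames; must be positive-definite).
#' @param random_effects \code{"fixed"} (default; the GSMR-style reference)
#'   or \code{"multiplicative"} for heterogeneity-inflated SEs.
#' @return An [MRFit-class].
#' @export
mrIVWCorrelated <- function(h, ld, random_effects = c("fixed", "multiplicative")) {
  random_effects <- match.arg(random_effects)
  df <- .h_df(h, 2L, "correlated-IV IVW")
  if (!is.null(rownames(ld)) && all(df$SNP %in% rownames(ld)))
    ld <- ld[df$SNP, df$SNP, drop = FALSE]
  if (nrow(ld) != nrow(df))
    stop("LD matrix does not cover the usable instruments")
  sigma <- diag(df$se_out) %*% ld %*% diag(df$se_out)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) stop("LD correlation matrix is not positive-definite")
  x <- df$beta_exp
  y <- df$beta_out
  xi <- backsolve(ch, forwardsolve(t(ch), x))
  yi <- backsolve(ch, forwardsolve(t(ch), y))
  xtx <- sum(x * xi)
  beta <- sum(x * yi) / xtx
  se <- sqrt(1 / xtx)
  k <- nrow(df)
  resid <- y - x * beta
  q <- sum(resid * backsolve(ch, forwardsolve(t(ch), resid)))
  if (random_effects == "multiplicative" && k > 2)
    se <- se * max(1, sqrt(q / (k - 1)))
  .mrfit(paste0("ivw_correlated_", random_effects), beta, se, k,
         extra = list(Q_gls = q))
}
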