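test_that("ratio estimates use the second-order delta method", {
  h <- data.frame(beta_exp = c(1, 2, 1), se_exp = c(0, 0, 0.1),
                  beta_out = c(2, 4, 2), se_out = c(1, 1, 0.3))
  r <- ratioEstimates(h)
  expect_equal(r$ratio, c(2, 2, 2))
  expect_equal(r$ratio_se, c(1, 0.5, sqrt(0.13)))
  # a zero exposure effect is excluded with a warning
  h$beta_exp[1] <- 0
  expect_warning(r2 <- ratioEstimates(h), "zero exposure")
  expect_equal(nrow(r2), 2)
})

test_that("IVW reproduces the hand-computed weighted mean", {
  f <- mrIVW(oracle3())
  expect_equal(mrBeta(f), 7 / 6, tolerance = 1e-12)
  expect_equal(mrExtra(f)$Q, 5 / 6, tolerance = 1e-12)
  expect_error(mrIVW(oracle3()[1, ]), "at least 2")
})

test_that("homogeneous ratios collapse all estimators to the common ratio", {
  h <- data.frame(beta_exp = c(1, 2, 4, 0.5), se_exp = 1e-8,
                  beta_out = 3 * c(1, 2, 4, 0.5), se_out = c(1, 1, 2, 1))
  ivw_m <- mrIVW(h, "multiplicative")
  ivw_f <- mrIVW(h, "fixed")
  expect_equal(mrBeta(ivw_m), 3, tolerance = 1e-12)
  expect_equal(mrSE(ivw_m), mrSE(ivw_f))  # Q = 0: no inflation
  expect_equal(mrBeta(mrMedian(h, n_boot = 10, seed = 1)), 3, tolerance = 1e-9)
  expect_equal(mrBeta(mrMode(h, n_boot = 10, seed = 1)), 3, tolerance = 1e-9)
  eg <- suppressWarnings(mrEgger(h))
  expect_equal(mrBeta(eg), 3, tolerance = 1e-9)
  expect_equal(mrExtra(eg)$intercept, 0, tolerance = 1e-9)
})

test_that("MR-Egger recovers slope and intercept of exact linear data", {
  h <- data.frame(beta_exp = c(1, 2, 3), se_exp = 0.01,
                  beta_out = c(1, 3, 5), se_out = 1)
  f <- suppressWarnings(mrEgger(h))
  expect_equal(mrBeta(f), 2, tolerance = 1e-10)
  expect_equal(mrExtra(f)$intercept, -1, tolerance = 1e-10)
  expect_error(mrEgger(h[1:2, ]), "at least 3")
})

test_that("Egger orientation makes the intercept estimate directional pleiotropy", {
  ints <- vapply(1:60, function(s) {
    h <- sim_harmonized(simTruth(beta_causal = 0.5,
                                 pleiotropy_model = "directional",
                                 pleiotropy_mean = 0.1, pleiotropy_sd = 0.02,
                                 seed = s, n_null = 0))
    mrExtra(mrEgger(h))$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.1), 0.05)
})

test_that("Egger intercept test controls type-I error under balanced pleiotropy", {
  ps <- vapply(1:100, function(s) {
    h <- sim_harmonized(simTruth(beta_causal = 0.5,
                                 pleiotropy_model = "balanced",
                                 pleiotropy_sd = 0.02, seed = s, n_null = 0))
    mrExtra(mrEgger(h))$intercept_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("I2 of exposure effects separates NOME-safe from NOME-weak sets", {
  h0 <- data.frame(beta_exp = rep(0.1, 5), se_exp = 0.01,
                   beta_out = 0.1, se_out = 1)
  expect_equal(i2GX(h0), 0)
  h1 <- data.frame(beta_exp = c(0.1, 0.2, 0.4, 0.8), se_exp = 1e-6,
                   beta_out = 0.1, se_out = 1)
  expect_gt(i2GX(h1), 0.999)
  # dispersed instruments all stronger than |z| = 5.45 pass the threshold
  for (s in 1:5) {
    set.seed(s)
    bx <- seq(0.02, 0.10, length.out = 14)
    h <- data.frame(beta_exp = bx + rnorm(14, 0, 0.003),
                    se_exp = 0.003, beta_out = 0, se_out = 1)
    expect_true(all(abs(h$beta_exp / h$se_exp) > 5.45))
    expect_gt(i2GX(h), 0.9)
  }
})

test_that("the weighted median interpolates cumulative normalized weights", {
  h3 <- data.frame(beta_exp = 1, se_exp = 1e-9,
                   beta_out = c(1, 2, 9), se_out = 1)
  expect_equal(mrBeta(mrMedian(h3, n_boot = 10, seed = 1)), 2)
  # two ratios {1, 2} with weights {3, 1}: interpolated value 1.25
  h2 <- data.frame(beta_exp = 1, se_exp = 0,
                   beta_out = c(1, 2), se_out = c(1 / sqrt(3), 1))
  expect_equal(ivmr:::.weighted_percentile(c(1, 2), c(3, 1)), 1.25)
  expect_error(mrMedian(h3[1:2, ]), "at least 3")
})

test_that("the weighted median is robust when 60% of instruments are valid", {
  # strong instruments so the ratio clusters are separated
  res <- sapply(1:50, function(s) {
    h <- sim_harmonized(simTruth(beta_causal = 0.5,
                                 pleiotropy_model = "correlated",
                                 pleiotropy_cor = 1.5, pleiotropy_sd = 0,
                                 frac_invalid = 0.4, r2_total = 0.3,
                                 seed = s, n_null = 0))
    c(mrBeta(mrIVW(h)), mrBeta(mrMedian(h, n_boot = 10, seed = s)))
  })
  expect_equal(mean(res[2, ]), 0.5, tolerance = 0.1)   # median near truth
  expect_gt(mean(res[1, ]) - 0.5, 0.3)                 # IVW biased upward
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h <- data.frame(beta_exp = 1, se_exp = 1e-9,
                  beta_out = c(1, 1, 1, 5), se_out = 1)
  expect_equal(mrBeta(mrMode(h, n_boot = 10, seed = 1)), 1, tolerance = 0.05)
  h1 <- data.frame(beta_exp = 1, se_exp = 1e-9,
                   beta_out = rep(2.5, 4), se_out = 1)
  expect_equal(mrBeta(mrMode(h1, n_boot = 10, seed = 1)), 2.5, tolerance = 1e-6)
})

test_that("the weighted mode is robust under the plurality-valid assumption", {
  res <- vapply(1:50, function(s) {
    set.seed(s)
    k <- 20
    bx <- runif(k, 0.1, 0.2)
    ratio <- c(rep(0.5, 8), rep(2, 6), rep(-1, 6))
    h <- data.frame(beta_exp = bx, se_exp = 0.002,
                    beta_out = ratio * bx + rnorm(k, 0, 0.004),
                    se_out = 0.004)
    mrBeta(mrMode(h, n_boot = 10, seed = s))
  }, numeric(1))
  expect_equal(mean(res), 0.5, tolerance = 0.1)
})

test_that("MR-PRESSO flags a planted outlier and nothing in clean data", {
  h <- instruments(sim_harmonized(simTruth(seed = 7, n_iv = 20,
                                           r2_total = 0.0064 / 14 * 20,
                                           n_null = 0)))
  fit <- mrPresso(h, n_sim = 1000, seed = 1)
  expect_length(mrExtra(fit)$outlier_indices, 0)
  expect_gt(mrExtra(fit)$global_p, 0.05)
  # outlier-free data: corrected estimate equals the plain IVW exactly
  expect_equal(mrBeta(fit), mrBeta(mrIVW(h)))
  # shift one outcome effect by 10 SE: exactly that instrument is flagged
  h2 <- h
  h2$beta_out[3] <- h2$beta_out[3] + 10 * h2$se_out[3]
  fit2 <- mrPresso(h2, n_sim = 1000, seed = 1)
  expect_identical(as.integer(mrExtra(fit2)$outlier_indices), 3L)
  expect_lt(mrExtra(fit2)$global_p, 0.05)
  expect_equal(mrBeta(fit2), mrBeta(mrIVW(h2[-3, ])))
  # preconditions
  expect_error(mrPresso(h[1:3, ]), "at least 4")
  expect_error(mrPresso(h, n_sim = 50), "n_sim too small")
})

test_that("GLS IVW reduces to fixed-effects IVW under identity LD", {
  h <- oracle3()
  ld <- diag(3); dimnames(ld) <- list(h$SNP, h$SNP)
  g <- mrIVWCorrelated(h, ld)
  f <- mrIVW(h, "fixed")
  expect_equal(mrBeta(g), mrBeta(f), tolerance = 1e-12)
  expect_equal(mrSE(g), mrSE(f), tolerance = 1e-12)
})

test_that("GLS IVW collapses duplicated instruments in the high-LD limit", {
  h1 <- data.frame(SNP = "a", beta_exp = 1, se_exp = 0.01,
                   beta_out = 2, se_out = 1)
  h2 <- rbind(h1, transform(h1, SNP = "b"))
  r <- 1 - 1e-6
  ld <- matrix(c(1, r, r, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- mrIVWCorrelated(h2, ld)
  expect_equal(mrBeta(g), 2, tolerance = 1e-6)
  # exactly singular correlation is rejected
  ld1 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mrIVWCorrelated(h2, ld1), "positive-definite")
})

test_that("GLS IVW covers the truth with correlated instruments", {
  # strong instruments (per-IV F ~ 170) so coverage reflects the GLS model
  covered <- vapply(1:500, function(s) {
    tr <- simTruth(seed = s, n_iv = 6, r2_total = 0.01, n_null = 0,
                   ld_blocks = rep(2L, 6), ld_r = 0.6)
    sim <- simulateIVDataset(tr, flip_rate = 0, strand_rate = 0)
    v <- variants(sim$exposure)
    h <- instruments(harmonizeInstruments(v, sim$outcome))
    h <- h[!startsWith(h$action, "removed"), ]
    ldr <- sqrt(sim$ld[h$SNP, h$SNP])
    fit <- mrIVWCorrelated(h, ldr)
    fit@ci_low <= -0.72 && fit@ci_high >= -0.72
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("estimators are scale- and sign-equivariant", {
  h <- instruments(sim_harmonized(simTruth(seed = 5, n_null = 0)))
  h <- h[!startsWith(h$action, "removed"), ]
  fits <- function(d) c(
    ivw = mrBeta(mrIVW(d)),
    egger = mrBeta(mrEgger(d)),
    med = mrBeta(mrMedian(d, n_boot = 10, seed = 1)),
    mode = mrBeta(mrMode(d, n_boot = 10, seed = 1)))
  base <- fits(h)
  hs <- h; hs$beta_exp <- 3 * h$beta_exp; hs$se_exp <- 3 * h$se_exp
  expect_equal(fits(hs), base / 3, tolerance = 1e-6)
  hn <- h; hn$beta_out <- -h$beta_out
  expect_equal(fits(hn), -base, tolerance = 1e-6)
})

test_that("PRESSO global test holds its size under the null", {
  ps <- vapply(1:200, function(s) {
    h <- sim_harmonized(simTruth(seed = s + 3000, n_null = 0))
    mrExtra(mrPresso(h, n_sim = 300, seed = s))$global_p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
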