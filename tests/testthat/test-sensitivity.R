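test_that("Cochran's Q matches hand computation and the brute-force oracle", {
  q <- cochranQ(oracle3())
  expect_equal(q$Q, 5 / 6, tolerance = 1e-12)
  expect_equal(q$df, 2L)
  # homogeneous ratios: Q = 0, p = 1
  h0 <- data.frame(beta_exp = c(1, 2, 3), se_exp = 1e-9,
                   beta_out = c(2, 4, 6), se_out = 1)
  expect_equal(cochranQ(h0)$Q, 0, tolerance = 1e-12)
  expect_equal(cochranQ(h0)$p, 1)
  # brute-force oracle on a random instance
  set.seed(9)
  h <- data.frame(beta_exp = runif(8, 0.5, 2), se_exp = 0.01,
                  beta_out = rnorm(8), se_out = runif(8, 0.5, 2))
  w <- h$beta_exp^2 / h$se_out^2
  r <- h$beta_out / h$beta_exp
  b <- sum(w * r) / sum(w)
  q_brute <- 0
  for (j in 1:8) q_brute <- q_brute + w[j] * (r[j] - b)^2
  expect_equal(cochranQ(h)$Q, q_brute, tolerance = 1e-12)
})

test_that("Q/(k-1) is centred on one under homogeneity", {
  qs <- vapply(1:100, function(s)
    cochranQ(sim_harmonized(simTruth(seed = s, n_null = 0)))$Q, numeric(1))
  ks <- vapply(1:100, function(s)
    nrow(usable(sim_harmonized(simTruth(seed = s, n_null = 0)))), numeric(1))
  expect_equal(mean(qs / (ks - 1)), 1, tolerance = 0.1)
})

test_that("leave-one-out flags exactly a planted influential instrument", {
  h <- instruments(sim_harmonized(simTruth(seed = 11, n_iv = 10,
                                           r2_total = 0.0064 / 14 * 10,
                                           n_null = 0)))
  h <- h[!startsWith(h$action, "removed"), ]
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), nrow(h))
  expect_false(any(loo$flagged))
  h2 <- h
  h2$beta_out[4] <- h2$beta_out[4] + 25 * h2$se_out[4]
  loo2 <- leaveOneOut(h2)
  expect_true(loo2$flagged[4])
  expect_equal(sum(loo2$flagged), 1)
  # homogeneous set: every omission reproduces the full estimate
  hh <- data.frame(beta_exp = c(1, 2, 4), se_exp = 1e-9,
                   beta_out = 3 * c(1, 2, 4), se_out = 1)
  lh <- leaveOneOut(hh)
  expect_equal(nrow(lh), 3)
  expect_equal(lh$beta, rep(3, 3), tolerance = 1e-9)
})

test_that("liability-scale r2 conversion matches a direct threshold-model simulation", {
  set.seed(11)
  K <- 0.1; f <- 0.3; b <- 0.05
  ratios <- vapply(1:3, function(s) {
    set.seed(s)
    N <- 300000
    g <- rbinom(N, 2, f)
    l <- b * (g - 2 * f) + rnorm(N, 0, sqrt(1 - b^2 * 2 * f * (1 - f)))
    y <- as.integer(l > qnorm(1 - K))
    r2_obs <- summary(lm(y ~ g))$r.squared
    liabilityR2(r2_obs, K, mean(y)) / (b^2 * 2 * f * (1 - f))
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("liability conversions are linear and guarded", {
  expect_equal(liabilityR2(0, 0.01, 0.3), 0)
  expect_equal(liabilityR2(0.02, 0.01, 0.3), 2 * liabilityR2(0.01, 0.01, 0.3))
  expect_gt(liabilityR2(0.02, 0.01, 0.3), liabilityR2(0.01, 0.01, 0.3))
  expect_error(liabilityR2(0.1, 1.5, 0.3), "prevalence")
  expect_equal(liabilityBeta(0, 0.007), 0)
  expect_equal(liabilityBeta(0.02, 0.01), 2 * liabilityBeta(0.01, 0.01))
  expect_error(liabilityBeta(0.1, 0), "prevalence")
})

test_that("Steiger compares variance explained across sides with liability conversion", {
  h <- data.frame(beta_exp = 0.1, se_exp = 0.01, beta_out = 0.05, se_out = 0.05,
                  p_exp = c(1e-10, 1e-12), n_exp = 1e5,
                  p_out = c(0.1, 0.2), n_out = 5e4)
  st <- mrSteiger(h)
  expect_true(st@correct_direction)
  expect_lt(st@p_direction, 0.05)
  expect_equal(st@r2_exposure, sum(r2FromPN(h$p_exp, h$n_exp)))
  # exchanging sides reverses the decision symmetrically
  h_swap <- transform(h, p_exp = p_out, n_exp = n_out,
                      p_out = p_exp, n_out = n_exp)
  st2 <- mrSteiger(h_swap)
  expect_false(st2@correct_direction)
  expect_equal(st2@p_direction, st@p_direction)
  # equal evidence both sides: direction undetermined
  h_eq <- transform(h, p_out = p_exp, n_out = n_exp)
  expect_equal(mrSteiger(h_eq)@p_direction, 1)
  # binary outcome requires a prevalence
  meta_bin <- studyMeta("d", "binary", n = 5e4, n_cases = 1e4)
  expect_error(mrSteiger(h, meta_bin), "prevalence")
  st3 <- mrSteiger(h, meta_bin, prevalence = 0.009)
  expect_equal(st3@prevalence_used, 0.009)
  expect_lt(st3@r2_outcome, sum(r2FromPN(h$p_out, h$n_out)))
})

test_that("odds-ratio intervals exponentiate the log-odds interval", {
  v <- orCI(-0.72, 0.20)
  expect_equal(unname(v["or"]), exp(-0.72), tolerance = 1e-12)
  expect_equal(round(unname(v["ci_low"]), 2), 0.33)
  expect_equal(round(unname(v["ci_high"]), 2), 0.72)
  v0 <- orCI(0, 0.5)
  expect_equal(unname(v0["or"]), 1)
  expect_equal(unname(v0["ci_low"] * v0["ci_high"]), 1, tolerance = 1e-12)
  expect_equal(unname(v["ci_low"] * v["ci_high"]), unname(v["or"])^2,
               tolerance = 1e-12)
})

test_that("one ln-unit of concentration multiplies by e", {
  expect_equal(unitContext(30.97), 30.97 * exp(1))
  expect_equal(unitContext(1), exp(1))
  x <- c(0.5, 3, 100)
  expect_equal(unitContext(x) / x, rep(exp(1), 3))
  expect_error(unitContext(-1), "positive")
})

test_that("multiple-testing flags agree with Bonferroni arithmetic and BH dominates", {
  p <- c(2.27e-4, 0.01, 0.2, rep(0.9, 29))
  mt <- multipleTesting(p, "bonferroni")
  expect_equal(mt$threshold, 0.05 / 32)
  expect_true(mt$significant[1])
  expect_false(any(mt$significant[-1]))
  bh <- multipleTesting(p, "bh")
  expect_true(all(bh$significant[mt$significant]))  # BH superset of Bonferroni
  expect_equal(bh$adjusted, p.adjust(p, "BH"))
  none <- multipleTesting(rep(1, 5), "bonferroni")
  expect_false(any(none$significant))
  expect_false(any(multipleTesting(rep(1, 5), "bh")$significant))
  expect_error(multipleTesting(numeric(0)), "no p-values")
})

test_that("the sensitivity report bundles diagnostics and serializes", {
  hs <- sim_harmonized(simTruth(seed = 21, n_null = 0))
  meta_out <- studyMeta("disorder", "binary", n = 72515, n_cases = 16992,
                        prevalence = 0.009)
  rep <- sensitivityReport(hs, outcome_meta = meta_out,
                           prevalence_bounds = c(0.009, 0.04),
                           n_sim = 300, seed = 4)
  expect_s4_class(rep, "SensitivityReport")
  expect_equal(rep@q_df, nrow(usable(hs)) - 1L)
  expect_length(rep@steiger, 2)
  expect_true(all(vapply(rep@steiger, function(s) s@correct_direction,
                         logical(1))))
  tdir <- withr::local_tempdir()
  paths <- writeSensitivityReport(rep, file.path(tdir, "pair1"))
  expect_true(all(file.exists(paths)))
  tab <- data.table::fread(paths[1])
  expect_true("cochran_q" %in% tab$statistic)
  expect_equal(tab$value[tab$statistic == "cochran_q"], rep@q_stat,
               tolerance = 1e-9)
})
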