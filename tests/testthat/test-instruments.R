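test_that("instrument selection applies a strict threshold and sorts by p", {
  df <- toy_sumstats(3)
  df$P <- c(6e-8, 1e-9, 4.9e-8)
  sel <- selectInstruments(df, 5e-8)
  expect_equal(sel$P, c(1e-9, 4.9e-8))
  expect_equal(nrow(selectInstruments(df, 1e-10)), 0)
})

test_that("greedy clumping keeps the most significant SNP per LD cluster", {
  df <- toy_sumstats(3)
  df$SNP <- c("s1", "s2", "s3"); df$CHR <- "1"
  df$POS <- c(1e6L, 2e6L, 3e6L)
  df$P <- c(1e-10, 1e-9, 1e-8)
  ld <- matrix(0, 3, 3, dimnames = list(df$SNP, df$SNP)); diag(ld) <- 1
  ld["s1", "s2"] <- ld["s2", "s1"] <- 0.5
  kept <- clumpInstruments(df, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(kept$SNP, c("s1", "s3"))

  # all pairs independent: input returned unchanged
  ld0 <- diag(3); dimnames(ld0) <- list(df$SNP, df$SNP)
  expect_setequal(clumpInstruments(df, ld0)$SNP, df$SNP)

  # perfect LD: only the more significant survives
  ld1 <- matrix(1, 2, 2, dimnames = list(df$SNP[1:2], df$SNP[1:2]))
  expect_equal(clumpInstruments(df[1:2, ], ld1)$SNP, "s1")

  # LD entries missing for an in-window pair is a hard error
  ldm <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  expect_error(clumpInstruments(df[1:2, ], ldm), "missing entries")

  # absent LD matrix: warn and treat as independent
  expect_warning(k2 <- clumpInstruments(df, NULL), "independent")
  expect_equal(nrow(k2), 3)
})

test_that("no kept pair within the window exceeds the clump threshold", {
  for (s in 1:10) {
    set.seed(s)
    n <- 12
    df <- toy_sumstats(n, seed = s)
    df$CHR <- "1"
    df$POS <- as.integer(sort(sample.int(5e6, n)))
    r <- matrix(runif(n * n), n)
    ld <- (r + t(r)) / 2; diag(ld) <- 1
    dimnames(ld) <- list(df$SNP, df$SNP)
    kept <- clumpInstruments(df, ld, r2_threshold = 0.3, window_kb = 10000)
    ids <- kept$SNP
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      inwin <- abs(kept$POS[i] - kept$POS[j]) <= 1e7
      if (inwin) expect_lt(ld[ids[i], ids[j]], 0.3)
    }
  }
})

test_that("palindromic allele pairs are recognized", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("g", "c"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("T", "C"))
})

test_that("harmonization aligns, flips, complements, and infers or removes palindromes", {
  ex <- toy_sumstats(6)
  ex$A1 <- c("A", "A", "A", "A", "A", "T")
  ex$A2 <- c("G", "G", "T", "T", "C", "C")
  ex$EAF <- c(0.3, 0.3, 0.10, 0.50, 0.3, 0.2)
  ex$BETA <- abs(ex$BETA) + 0.01
  ou <- ex
  ou$BETA <- 0.05
  ou$A1[2] <- "G"; ou$A2[2] <- "A"; ou$EAF[2] <- 0.7   # swapped alleles
  ou$EAF[3] <- 0.11                                     # palindrome, concordant
  ou$A1[5] <- "T"; ou$A2[5] <- "G"                      # strand complement
  ou$SNP[6] <- "absent"                                 # missing from outcome
  h <- instruments(harmonizeInstruments(ex, ou, eaf_ambiguity = 0.08))
  expect_equal(h$action,
               c("aligned", "flipped", "palindromic_inferred",
                 "removed_palindromic", "aligned", "removed_missing"))
  expect_equal(h$beta_out[1], 0.05)
  expect_equal(h$beta_out[2], -0.05)   # allele swap forces a sign flip
  expect_equal(h$eaf_out[2], 0.3)
  expect_equal(h$beta_out[3], 0.05)
  expect_equal(h$beta_out[5], 0.05)
  # non-complementary mismatch is marked, not dropped
  ou2 <- ex[1, ]; ou2$A2 <- "C"
  h2 <- instruments(harmonizeInstruments(ex[1, ], ou2))
  expect_equal(h2$action, "removed_mismatch")
})

test_that("harmonization never alters exposure effects or outcome magnitudes", {
  for (s in 1:5) {
    sim <- simulateIVDataset(simTruth(seed = s, n_null = 20))
    ex <- variants(sim$exposure)
    h <- instruments(harmonizeInstruments(ex, sim$outcome))
    expect_equal(h$beta_exp, ex$BETA)
    expect_equal(h$se_exp, ex$SE)
    ou <- variants(sim$outcome)
    matched <- !is.na(h$beta_out)
    expect_equal(abs(h$beta_out[matched]),
                 abs(ou$BETA[match(h$SNP[matched], ou$SNP)]))
  }
})

test_that("variance explained inverts the 1-df association test", {
  p_z2 <- 2 * pnorm(-2)
  expect_equal(r2FromPN(p_z2, 1002), 4 / 1004, tolerance = 1e-2)
  expect_equal(r2FromPN(1, 1000), 0)
  expect_error(r2FromPN(0.5, 2), "exceed 2")
  # additivity: the set total is the sum of per-SNP values
  df <- toy_sumstats(5)
  st <- instrumentStrength(df)
  expect_equal(st$r2_total, sum(r2FromPN(df$P, df$N)))
  expect_equal(st$f_stat, fStatistic(st$r2_total, 5, st$n))
})

test_that("the F statistic matches its closed form and printed exemplar", {
  expect_equal(fStatistic(0.0242, 38, 123665), 80.68, tolerance = 1e-4)
  expect_equal(fStatistic(0, 5, 1000), 0)
  expect_equal(fStatistic(0.5, 1, 103), 101)
  expect_error(fStatistic(1, 1, 100), "lie in")
})

test_that("F is increasing in r2 and n, decreasing in k", {
  set.seed(42)
  for (i in 1:20) {
    r2 <- runif(1, 0.001, 0.2); k <- sample(2:50, 1); n <- sample(1000:1e5, 1)
    f0 <- fStatistic(r2, k, n)
    expect_gt(fStatistic(r2 * 1.1, k, n), f0)
    expect_gt(fStatistic(r2, k, n + 1000), f0)
    expect_lt(fStatistic(r2, k + 1, n), f0)
  }
})

test_that("generator instrument sets are strong (F > 10) by construction", {
  for (s in 1:5) {
    sim <- simulateIVDataset(simTruth(seed = s, n_null = 0))
    st <- instrumentStrength(variants(sim$exposure))
    expect_gt(st$f_stat, 10)
  }
})

test_that("annotation subsetting restricts to the requested label", {
  df <- toy_sumstats(10)
  amap <- setNames(rep(c("glycaemic", "erythrocytic"), c(4, 6)), df$SNP)
  expect_equal(nrow(subsetByAnnotation(df, amap, "glycaemic")), 4)
  expect_equal(nrow(subsetByAnnotation(df, amap, "absent_label")), 0)
  expect_equal(nrow(subsetByAnnotation(df, setNames(rep("x", 10), df$SNP), "x")), 10)
})

test_that("stable-instrument partition is exhaustive and recovers the construction", {
  bp <- simulateBMIPair(simTruth(seed = 3, r2_total = 0.013), 6 / 14)
  st <- stableInstruments(bp$adjusted, bp$unadjusted)
  expect_setequal(st$stable$SNP, bp$stable_ids)
  expect_equal(nrow(st$stable), 8)
  # shifted instruments land in the adjusted-only set
  expect_setequal(st$adjusted_only$SNP,
                  setdiff(variants(bp$adjusted)$SNP, bp$stable_ids))
  # identical inputs: everything significant is stable
  st2 <- stableInstruments(bp$adjusted, bp$adjusted)
  v <- variants(bp$adjusted)
  expect_setequal(st2$stable$SNP, v$SNP[v$P < 5e-8])
  expect_equal(nrow(st2$adjusted_only), 0)
  # disjoint SNP universes are an error
  other <- variants(bp$unadjusted)
  other$SNP <- paste0("x", other$SNP)
  expect_error(stableInstruments(bp$adjusted, other), "share no SNP")
})

test_that("confounder-shared instruments are removed, absent ones retained", {
  df <- toy_sumstats(14)
  conf <- df
  conf$P <- 1e-3
  conf$P[1:5] <- 1e-9
  rs <- removeSharedHits(df, conf)
  expect_equal(nrow(rs$kept), 9)
  expect_equal(length(rs$dropped), 5)
  # instrument absent from the confounder file is retained
  conf2 <- conf[-1, ]
  expect_true(df$SNP[1] %in% removeSharedHits(df, conf2)$kept$SNP)
  # none crosses: identity
  conf$P <- 0.5
  expect_equal(nrow(removeSharedHits(df, conf)$kept), 14)
  # all cross: empty plus warning
  conf$P <- 1e-10
  expect_warning(rs3 <- removeSharedHits(df, conf), "every instrument")
  expect_equal(nrow(rs3$kept), 0)
})
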