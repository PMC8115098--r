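# Shared fixtures, all built in code.

# The 3-instrument set whose IVW/Q values are hand-computable:
# weights {1,1,4}, ratios {2,1,1}, IVW beta 7/6, Q = 5/6.
oracle3 <- function() {
  data.frame(SNP = c("s1", "s2", "s3"),
             beta_exp = c(1, 1, 2), se_exp = 0.01,
             beta_out = c(2, 1, 2), se_out = 1)
}

# Harmonize a simulated dataset using its known true instruments (no
# re-selection, no allele corruptions) — isolates estimator behaviour.
sim_harmonized <- function(truth) {
  sim <- simulateIVDataset(truth, flip_rate = 0, strand_rate = 0)
  v <- variants(sim$exposure)
  harmonizeInstruments(v[v$SNP %in% sim$iv_ids, ], sim$outcome)
}

# A small valid canonical sumstats data.frame with self-consistent p-values.
toy_sumstats <- function(n = 10, seed = 1) {
  set.seed(seed)
  f <- runif(n, 0.05, 0.45)
  se <- 1 / sqrt(2 * f * (1 - f) * 50000)
  beta <- rnorm(n, 0, 2 * se)
  data.frame(SNP = sprintf("rs%03d", seq_len(n)), CHR = "1",
             POS = as.integer(seq_len(n) * 1e5),
             A1 = rep(c("A", "C"), length.out = n),
             A2 = rep(c("G", "T"), length.out = n),
             EAF = f, BETA = beta, SE = se,
             P = 2 * pnorm(-abs(beta / se)), N = 50000,
             stringsAsFactors = FALSE)
}
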