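# ivmr — two-sample Mendelian randomisation with a pleiotropy-robust estimator suite

`ivmr` is an R package for causal inference from GWAS summary statistics by
two-sample Mendelian randomisation (MR). It was built around the analysis
design used to ask whether glycaemic traits (fasting insulin, fasting
glucose, glycated haemoglobin) causally affect the risk of psychiatric
disorders: a grid of exposures and outcomes, analysed bidirectionally, with
genetic instruments selected at genome-wide significance, a primary
inverse-variance weighted (IVW) estimate, and a suite of sensitivity
analyses probing the instrumental-variable assumptions. Everything is
exercised end-to-end on synthetic summary statistics with known causal
truth, so the statistical guarantees of each stage are testable without any
external download.

## What it implements

**Instruments.** Genetic variants associated with an exposure at
*P* < 5 × 10⁻⁸ are selected, LD-clumped (greedy, *r*² < 0.001 within a
10 Mb window against a user-supplied LD matrix) and harmonized against the
outcome GWAS: allele codes are aligned, swapped or strand-complemented;
palindromic (A/T, C/G) SNPs are kept only when both allele frequencies lie
outside [0.42, 0.58] and agree in orientation. Instrument strength is
quantified by

> *F* = *R*²(*N* − *k* − 1) / ((1 − *R*²)*k*),

with *R*² the summed per-SNP variance explained recovered from each SNP's
p-value and sample size (*F* > 10 is the conventional adequacy bar).

**Estimators.** Wald ratios β_out/β_exp are combined by: IVW with
multiplicative random effects (the primary model), MR-Egger (free intercept
estimating mean directional pleiotropy, gated by the I²_GX > 0.9
no-measurement-error diagnostic), the weighted median (robust when ≥ 50% of
weight is valid), the weighted mode (plurality valid), MR-PRESSO (simulated
residual-sum-of-squares global test and Bonferroni-corrected per-SNP
outlier removal), and a generalised-least-squares IVW for correlated
instruments.

**Sensitivity.** Cochran's Q, the Egger intercept test, the PRESSO global
test, leave-one-out refits, and the Steiger directionality test (variance
explained in exposure vs outcome, converted to the liability scale for
binary traits). Binary-exposure estimates are rescaled to a per-SD-of-
liability unit via β·z/(K(1−K)), with z the standard-normal density at the
liability threshold for prevalence K.

**Latent causal variable model.** For genetically correlated trait pairs,
`estimateLCV()` estimates the genetic causality proportion (GCP ∈ [−1, 1])
from the imbalance of standardized mixed fourth moments of the bivariate
SNP-effect distribution, with block-jackknife tests of GCP = 0 and full
causality (GCP = ±1).

**Synthetic data.** `simulateIVDataset()`, `simulateBMIPair()` and
`simulateGenomewide()` generate summary statistics with configurable causal
effects, pleiotropy (balanced, directional, or InSIDE-violating), LD,
palindromic/flipped allele corruptions, and latent-factor architectures
realizing a chosen GCP — each seeded and bit-reproducible.

## Worked example

Simulate the design the package mirrors — 14 instruments explaining 0.64%
of a fasting-insulin-like exposure at n = 108,557, a case-control outcome
of n = 72,515 with a protective causal effect of −0.72 log-odds per
exposure unit — then run the analysis:

```r
library(ivmr)
sim <- simulateIVDataset(simTruth(seed = 42))
sel <- selectInstruments(sim$exposure)          # P < 5e-8
h   <- harmonizeInstruments(sel, sim$outcome)
h
#> HarmonizedSet: exposure -> sim_outcome (12 instruments, 11 usable)
#>   actions: aligned=9, flipped=2, removed_palindromic=1

fit <- mrIVW(h)
fit
#> MRFit [ivw_multiplicative]: beta = -0.6872 (SE 0.124),
#>   95% CI [-0.9301, -0.4442], p = 2.96e-08, k = 11
orCI(mrBeta(fit), mrSE(fit))
#>        or    ci_low   ci_high
#> 0.5029844 0.3944976 0.6413051
```

Twelve of the 14 planted instruments reached significance in this draw; one
palindromic SNP was unresolvable and removed. The IVW estimate recovers the
planted −0.72 (OR ≈ 0.50, i.e. halved odds per unit of exposure). The
sensitivity suite finds no pleiotropy — as it should, none was simulated —
and Steiger confirms the generating direction:

```r
rep <- sensitivityReport(h, outcome_meta = studyMetaOf(sim$outcome),
                         prevalence_bounds = c(0.009, 0.04),
                         n_sim = 1000, seed = 1)
rep
#> SensitivityReport: Q = 7.789 (df 10, p = 0.649); Egger intercept = -0.0196
#>   (p = 0.378); PRESSO global p = 0.71
#>   leave-one-out flags: 0 of 11
rep@steiger[[1]]
#> Steiger: r2_exposure = 0.005006, r2_outcome = 0.0003991
#>   -> direction supported (p = 2.64e-26)
```

`runGrid()` orchestrates a whole exposure × outcome grid from a YAML
configuration (Bonferroni-corrected over all pairs, full estimator suite on
corrected-significant pairs, liability conversion for binary exposures) and
`renderReport()` serializes the results, sensitivity table, run log, and
the per-pair harmonized sets from which every reported number is
reproducible.

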