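---
title: "Methods: two-sample Mendelian randomisation in ivmr"
author: "ivmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation in ivmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmr)
```

# The model

Two-sample Mendelian randomisation treats genetic variants as instrumental
variables for an exposure. For instrument $j$ we observe the marginal
association estimates $(\hat\beta_{Xj}, se_{Xj})$ with the exposure from one
GWAS and $(\hat\beta_{Yj}, se_{Yj})$ with the outcome from a second,
non-overlapping GWAS. Under the three IV assumptions — association with the
exposure, independence from confounders, and no effect on the outcome except
through the exposure — each Wald ratio $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
estimates the causal effect $\beta$, and the inverse-variance weighted (IVW)
estimator combines them with first-order weights
$w_j = \hat\beta_{Xj}^2/se_{Yj}^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j r_j}{\sum_j w_j},
\qquad
se_{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$

The primary model uses *multiplicative random effects*: the fixed-effects
standard error is inflated by $\max\!\big(1, \sqrt{Q/(k-1)}\big)$, where
$Q = \sum_j w_j (r_j - \hat\beta)^2$ is Cochran's heterogeneity statistic.
The floor at 1 means heterogeneity can only widen, never narrow, the
interval. P-values are two-sided normal throughout: these are summary-data
asymptotics, and a single consistent reference avoids mixing normal and $t$
conventions across estimators.

Exclusion-restriction violations (horizontal pleiotropy) motivate the rest
of the suite:

* **MR-Egger** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights
  $1/se_{Yj}^2$ and a free intercept estimating the mean directional
  pleiotropic effect. Instruments are first oriented so that every
  $\hat\beta_{Xj} \ge 0$; without that orientation the intercept is not
  interpretable as a mean direct effect. The slope's validity rests on the
  InSIDE assumption and on negligible measurement error in the exposure
  effects, summarised by $I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX})$ over
  oriented exposure effects; the conventional gate is $I^2_{GX} > 0.9$.
  Note that $I^2_{GX}$ measures the *spread* of true instrument effects
  relative to their standard errors: a set of uniformly strong but
  similar-sized instruments can fail the gate even at large per-SNP $F$.
* **Weighted median**: the weighted 50th percentile (linear interpolation of
  cumulative normalized weights) of the ratio estimates with second-order
  delta-method weights
  $se_{r_j}^2 = se_{Yj}^2/\hat\beta_{Xj}^2 +
  \hat\beta_{Yj}^2 se_{Xj}^2/\hat\beta_{Xj}^4$. Consistent while at least
  half the weight comes from valid instruments. Its finite-sample bias
  scales with the ratio-estimate noise: when invalid instruments shift
  ratios upward, the median sits at the $0.5/p_{valid}$ quantile of the
  valid cluster, a displacement proportional to $se_{r}$.
* **Weighted mode**: the maximiser of a Gaussian-kernel weighted density of
  the ratios, bandwidth = `bandwidth_factor` × the modified Silverman rule
  $0.9\min(sd, mad)k^{-1/5}$. Consistent when the largest group of
  instruments sharing a ratio is valid.
* **MR-PRESSO**: the observed residual sum of squares
  $\sum_j w_j (r_j - \hat\beta_{(-j)})^2$ (leave-one-out IVW predictions) is
  compared with a parametric simulation of its null distribution; per-SNP
  residuals give Bonferroni-corrected outlier p-values, flagged outliers are
  removed, and the IVW is refit. The distortion test is not implemented.
* **Correlated-instrument IVW**: generalised least squares with covariance
  $\Sigma = D\rho D$ ($D$ = outcome SEs, $\rho$ = signed LD correlations).
  With identity $\rho$ it reduces exactly to fixed-effects IVW. Exactly
  singular correlation matrices are rejected: the estimator's precondition
  is positive-definiteness, and duplicate instruments should be collapsed by
  clumping, not by the GLS.

Median and mode standard errors come from a seeded parametric bootstrap
(default `n_boot = 1000`): effect estimates are resampled from their normal
sampling distributions and the estimator recomputed.

# Harmonization and instrument processing

Exposure and outcome records are matched on variant ID only. Allele codes
that agree are used as-is; swapped effect/other alleles flip the sign of the
outcome effect (and reflect its allele frequency); strand complements are
complemented first. Palindromic SNPs (A/T, C/G) carry no strand information
in their codes, so orientation is inferred from allele frequencies: the SNP
is kept only when both frequencies fall outside the ambiguity window
$[0.5 - w, 0.5 + w]$ (default half-width $w = 0.08$, the conventional
choice) *and* lie on the same side of 0.5. Everything else is retained in
the harmonized table with an explicit `removed_*` action — no record is
silently dropped, and exposure-side effects are never modified.

Clumping is greedy: the most significant remaining SNP is kept and all
remaining SNPs within 10,000 kb with $r^2 \ge 0.001$ to it are discarded
(ties in $p$ broken lexicographically by SNP ID). The LD matrix is an
explicit input; with none supplied all pairs are treated as independent,
with a warning, because silent assumptions about LD are worse than loud
ones.

Instrument strength uses $F = R^2(N-k-1)/((1-R^2)k)$ with $R^2$ the sum of
per-SNP variances explained, each recovered from the SNP's p-value by
inverting the 1-df association test: $t^2 = F^{-1}_{1,n-2}(1-p)$,
$r^2 = t^2/(t^2+n-2)$.

# Scale conversions

For a binary exposure, the IVW estimate is per log-odds unit — one unit is
an $e \approx 2.72$-fold multiplicative change in odds, which is hard to
interpret. `liabilityBeta()` rescales to the change in outcome per standard
deviation of liability, multiplying by $z/(K(1-K))$ with $z$ the
standard-normal density at the liability threshold $\Phi^{-1}(1-K)$ and $K$
the population prevalence. For Steiger's directionality test on a binary
outcome, observed-scale variance explained is converted with the Lee
transformation $r^2_{liab} = r^2_{obs} K^2(1-K)^2 / (z^2 P(1-P))$, where
$P$ is the sample case proportion; the test is run at both bounds of the
prevalence estimate when a range is supplied (default 0.9% and 4% for an
anorexia-like outcome). The Steiger p-value compares the implied
correlations by Fisher-z with variance $1/(n-3)$ per side — appropriate
because the two GWAS do not share samples.

# The latent causal variable model

For genome-wide trait pairs, the package estimates the genetic causality
proportion (GCP). Standardized per-SNP effects are modelled as
$\alpha_t = q_t\gamma + \delta_t$ with a shared kurtotic latent factor
$\gamma$; under $q_1 = |\rho|^{(1-g)/2}$,
$q_2 = \mathrm{sign}(\rho)|\rho|^{(1+g)/2}$ the genetic correlation is
$\rho$ for every $g$, and $g = \pm 1$ is full causality. The excess mixed
fourth moments satisfy $k_{41} = \mathrm{sign}(\rho)|\rho|^{2-g}\kappa$ and
$k_{14} = \mathrm{sign}(\rho)|\rho|^{2+g}\kappa$ ($\kappa$ = latent excess
kurtosis), so

$$D(g_0) = |\rho|^{g_0} k_{41}' - |\rho|^{-g_0} k_{14}'$$

has mean zero exactly at $g_0 = g$. The estimator computes noise-corrected,
$1/\max(1,\ell_j)$-weighted sample moments (the weighting discounts
high-LD-score SNPs, which tag many neighbours), converts block-jackknife
$t$-statistics of $D(g_0)$ over a grid ($g_0 \in \{-1, -0.99, \dots, 1\}$)
into an approximate likelihood, and reports the posterior mean under a flat
prior; its SE is the block-jackknife SE of that posterior mean, and the
tests of $GCP = 0, \pm 1$ are jackknife $t$-tests of $D(0)$, $D(1)$,
$D(-1)$ with `n_blocks - 1` degrees of freedom (default 100 contiguous
blocks). Heritabilities come from weighted LD-score regressions
($E[z^2] = 1 + n h^2 \ell_j / \sum\ell$) and gate the computation: a
non-positive estimate is a hard error. The genetic correlation is reported
from the same weighted second moments the fourth-moment step standardizes
with; in simulation this moment estimator is markedly more stable (SD ≈
0.03 at $\rho = 0.35$, 20,000 SNPs) than the cross-trait regression slope
(SD ≈ 0.05). The construction is exactly antisymmetric: exchanging the
traits negates the GCP and swaps the two full-causality tests. Sample
overlap is assumed absent by default; `overlap = TRUE` estimates a
cross-trait intercept and subtracts it from the cross moments.

# What the synthetic data emulate — and what they do not

`simulateIVDataset()` mirrors the motivating design: 14 instruments jointly
explaining 0.64% of a continuous exposure at $n = 108{,}557$ (per-SNP
variance shares jittered ±20% around equal, giving expected $|z| \approx 7$,
comfortably genome-wide significant), tested against a case-control outcome
of $n = 72{,}515$ with case fraction 0.234. Standard errors follow
$1/\sqrt{2f(1-f)n}$ for the continuous trait and
$1/\sqrt{2f(1-f)nP(1-P)}$ for the binary one — with these the simulated IVW
standard error (~0.12) approaches the scale reported for real
glycaemic-psychiatric analyses. Allele frequencies are uniform on
[0.05, 0.5]; 10% of SNPs are palindromic, and configurable fractions of
outcome rows are stored with swapped alleles or on the opposite strand so
the harmonization paths are exercised constantly. Pleiotropy models:
`balanced` and `directional` draw direct effects relative to the
exposure-increasing allele (the frame in which the Egger intercept
estimates their mean); `correlated` makes them proportional to the
instrument's exposure effect, violating InSIDE. P-values are computed
exactly from $z = \hat\beta/se$, so read-time validation never rejects
generated data. All generators restore the caller's RNG state and are
bit-reproducible from the seed.

What is *not* emulated: realistic human LD maps (LD is block-uniform by
construction), allele-frequency/effect-size coupling from selection,
population stratification, sample overlap, and winner's curse in the
discovery of the instruments (tests that measure estimator recovery use the
designed instrument set directly). Passing calibration here therefore
demonstrates correctness of the estimators under their stated assumptions,
not robustness to every artefact of real GWAS.

Two calibration facts worth knowing when reading the tests. First, IVW
carries a regression-dilution bias of roughly $1/(1 + 1/\bar F)$ from noise
in the exposure effects: at the design's per-SNP $F \approx 50$ that is
about 2%, and the measured bias (~1.9% over 500 seeds) is essentially all
attenuation, not implementation error. Second, the leave-one-out flag uses
the *fixed-effects* interval of the full set as its reference: an
influential outlier inflates the multiplicative random-effects interval in
proportion to its own displacement, which would make a flag against that
interval unattainable by construction.

`simulateBMIPair()` builds covariate-adjusted/unadjusted exposure scans in
which a chosen fraction of instruments loses genome-wide significance
without adjustment (their unadjusted expected $z$ is pinned at 2 —
associated but clearly sub-significant, so the designed stable set is
recovered deterministically). `simulateGenomewide()` draws latent-factor
architectures for the LCV model: a sparse point-normal latent factor
(1% of SNPs, excess kurtosis ≈ 300) with per-SNP variance proportional to a
simulated LD score, trait-specific backgrounds on 10% of SNPs, defaults
$h^2 = 0.25$, $\rho_g = 0.35$, $n = 10^5$, 20,000 SNPs.

# Pipeline policy

`runGrid()` analyses every ordered exposure → outcome pair of the declared
studies. The multiple-testing family is the *whole grid* (including pairs
that turn out not assessable), matching how a Bonferroni threshold of
$0.05/32$ arises from an 8 × 4 design; pairs with fewer than three usable
instruments are reported "not assessable" with an explicit reason. The full
sensitivity suite runs for corrected-significant pairs (a config flag can
force it everywhere); pairs at uncorrected $p < 0.05$ get the lighter
Egger/median/mode follow-up. MR-Egger results are flagged — not suppressed —
when $I^2_{GX} \le 0.9$. Per-pair stochastic components (bootstrap, PRESSO)
are seeded from a hash of the pair label and the configuration seed, making
the whole grid invariant to the order studies are listed. Every rendered
number is recomputable from the harmonized per-pair tables the report
writes alongside.

The package deliberately exposes its functionality as R functions plus this
vignette rather than a shell program: that is how the surrounding ecosystem
of MR tooling is used in practice.

# Numerical and testing choices

Test problem sizes were chosen to make each check decisive yet quick: 1,000
null replicates for the IVW size check (binomial SE ≈ 0.7%), 500 seeds for
bias/coverage at the mirrored design, 60 seeds × 1,000 simulations for
MR-PRESSO detection (the Bonferroni-corrected outlier test needs
$n_{sim} \gg k/\alpha$ to resolve; at equality a single exceedance already
blocks a flag), 100 seeds for Steiger, and 20,000-SNP architectures with
100 jackknife blocks for the LCV suites. Property tests that isolate an
estimator's identifying assumption (majority-valid median, plurality-valid
mode, GLS coverage) use stronger instruments than the mirrored design so
the property is not confounded with weak-instrument attenuation; the
rationale is stated inline where it applies.

Degenerate inputs are handled explicitly: perfect-fit Egger regressions
yield zero standard errors rather than NaN; a zero-spread ratio vector
short-circuits the mode's bandwidth rule; p-values of exactly zero are
replaced by the smallest positive double and flagged at read time (top hits
must remain usable as instruments); and $|\rho|$ is clamped to
$[10^{-2}, 1-10^{-4}]$ inside the LCV grid exponentials.

# Known limitations

No proxy-SNP lookup for instruments missing from the outcome; no multivariable
MR; no SIMEX correction for Egger under weak instruments; no PRESSO
distortion test; the LCV weighting scheme is the package's own (external
implementations differ in their weighting and posterior machinery, so GCP
values are comparable in sign and approximate magnitude, not digit-for-digit);
and clumping distances are positional only (no recombination-map awareness).
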