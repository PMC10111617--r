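---
title: "Two-step Mendelian randomization with a mediated binary outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization with a mediated binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

`mrmediate` estimates how much of the causal effect of an exposure X on a
binary outcome Y flows through a mediator M, using only GWAS summary
statistics from three (non-overlapping) cohorts. The causal diagram is

    G  →  X  →  M  →  Y
           └────────↗
              c′ (direct)

with per-unit effects a (X→M), b (M→Y, log odds ratio) and a direct effect
c′ (log-OR). On the log-OR scale the total effect decomposes exactly:

    c = a·b + c′,   mediated = a·b,   proportion mediated = a·b / c.

Each arrow into a trait is estimated by two-sample Mendelian randomization
(MR): genetic variants robustly associated with the upstream trait serve as
instrumental variables, assumed to affect the downstream trait only through
it. The package implements the whole chain — instrument quality control,
four estimators, heterogeneity/pleiotropy diagnostics, and the mediation
arithmetic — plus a summary-level simulator so that every stage can be
exercised and calibrated without downloading any cohort data.

## Instrument quality control

1. **Significance threshold.** Instruments are SNPs with association
   p-value strictly below a threshold: 5×10⁻⁸ by default, conventionally
   relaxed to 1×10⁻⁵ for instrument-poor traits (a per-trait override in
   `pipeline_config()`).
2. **LD clumping.** Greedy pruning at r² < 0.001 within a 10,000 kb
   window: SNPs are visited in order of ascending p-value (ties broken by
   identifier, so the result is independent of row order) and accepted
   unless correlated with an already-accepted SNP. The LD matrix is a
   user- or simulator-supplied input; SNPs absent from it are treated as
   independent. The 10 Mb window is the conventional clumping default; the
   r² threshold is the tight value standard for MR instrument selection.
3. **Instrument strength.** The per-SNP approximation F = (β/se)² is
   applied as a hard filter at F > 10, the conventional weak-instrument
   boundary. The variance-explained form (n−2)·R²/(1−R²) is available via
   `f_from_r2()` when allele frequencies and sample sizes are preferred.
4. **Steiger directionality.** A SNP explaining more variance in the
   outcome than in the exposure (r² = t²/(t² + n − 2) per side) is a
   reverse-causation suspect. We retain a SNP only when r²_exposure >
   r²_outcome *and* the one-sided test on the Fisher-transformed
   correlations is significant at α = 0.05 — a deliberately conservative
   reading: an instrument whose direction cannot be established is not a
   defensible instrument. Filtering runs after harmonization (so both
   sides are allele-aligned); running clumping before or after
   harmonization does not change the instrument set because clumping uses
   exposure statistics only.

Harmonization aligns outcome to exposure effect alleles, flipping signs
for swapped alleles and complementing strand flips. Palindromic (A/T, C/G)
SNPs cannot be oriented from allele labels alone and are removed
unconditionally — allele-frequency-based rescue is deliberately not
implemented, matching the stricter convention; the `palindrome_policy`
argument is an extensible enum with the single implemented value `"drop"`.

## Estimators

All estimators work on the harmonized per-SNP effect pairs
(β̂_exp, β̂_out) and report the causal effect as a log-OR with OR and 95%
CI (normal multiplier fixed at 1.959964 so serialized output is stable).

* **Wald ratio** (single instrument): β̂_out/β̂_exp with the first-order
  delta-method se, se_out/|β̂_exp|. The neglected second-order term is
  below 5% whenever the instrument t-statistic exceeds 10, which the F
  filter guarantees.
* **IVW**: inverse-variance-weighted mean of the per-SNP Wald ratios with
  weights β̂²_exp/se²_out — identically the zero-intercept weighted
  regression of β̂_out on β̂_exp. The default error model is
  multiplicative random effects (se inflated by √max(1, Q/(n−1))), the
  convention of the standard two-sample MR tooling; fixed effects is a
  flag. p-values are Gaussian.
* **MR-Egger**: the same regression with a free intercept, exposure
  effects oriented non-negative. The slope is a pleiotropy-adjusted
  effect; the intercept estimates average directional pleiotropy.
  Standard errors use √max(1, Q′/(n−2)) and p-values the t distribution
  with n−2 df. The truncation at 1 makes null p-values mildly
  conservative rather than exactly uniform; with 45 instruments the
  effect is small (the calibration tests bound it), and we keep the
  truncated form because it is what the field's tooling reports.
* **Weighted median**: the per-SNP ratio at which the cumulative
  normalized weight crosses ½, using the cumulative-weight midpoint
  convention with linear interpolation; consistent when instruments
  carrying ≥ 50% of the weight are valid. Its se comes from a parametric
  bootstrap (default 1000 resamples, explicit seed).

All four are exactly equivariant under rescaling of the exposure, and the
weighted median always lies within the per-SNP ratio range.

## Diagnostics

* **Cochran's Q** for the IVW fit (ratio scale, df n−1) and Rücker's Q′
  for the Egger fit (regression scale, df n−2), with upper chi-square
  p-values.
* **Egger intercept test**: two-sided t-test on the intercept; a two-SNP
  exact fit is reported with df 0 and no p-value rather than refused.
* **MR-PRESSO**: the observed global statistic is the weighted residual
  sum of squares around leave-one-out IVW slopes; its null distribution
  is built by redrawing both effect vectors from Gaussians centered on
  the observed exposure effects and the leave-one-out fitted outcome
  values (default 1000 simulations, explicit seed, bit-for-bit
  reproducible). Per-SNP outlier p-values are Bonferroni-adjusted; when
  outliers are flagged, a distortion p-value compares the slope shift
  from removing them against the shift from removing equally many random
  SNPs. Defaults: 1000 simulations, outlier α = 0.05.

## Mediation

`mediate_decompose()` combines the three MR estimates on the log scale:
mediated = a·b, direct = c − a·b, proportion = a·b/c, carried at full
precision. Feeding the published two-decimal odds ratios 1.27 (total),
1.06 (step 1) and 1.25 (step 2) gives mediated 0.0130, direct 0.2260 and
proportion 5.44% — consistent with the published 0.014 / 0.221 / 5.91% up
to the input rounding. Note the published values are not jointly exact at
two decimals (0.221 + 0.014 = 0.235, while ln 1.27 = 0.239): a total
log-OR of 0.235 corresponds to OR 1.265, which prints as 1.27. We
therefore treat agreement at the rounding level as the best achievable
desk reproduction.

Uncertainty for the mediated effect comes from the delta method
(√(b²se²_a + a²se²_b)) or a parametric bootstrap; both converge for
strong signals.

Two pipeline rules govern which decompositions are reported:

* **Mediator screening**: only candidates whose mediator→outcome MR is
  significant at α = 0.05 (strict inequality, so a p-value of exactly
  0.05 is excluded) proceed — a mediator with no detectable outcome
  effect cannot carry a mediated path.
* **Total-effect gate** (`require_significant_total`, default on): the
  decomposition is computed only when the total effect is itself
  significant at the same α. The proportion mediated divides by the
  total effect; when that denominator is statistically indistinguishable
  from zero the ratio is numerically meaningless and its sampling
  distribution is heavy-tailed. This mirrors the sequential logic of
  mediation practice: establish the total effect first, then ask how it
  decomposes.

Step-2 (mediator→outcome) instrument sets additionally exclude SNPs that
are genome-wide significant for the exposure
(`step2_exclude_exposure_instruments`, default on). Such SNPs reach the
outcome through the direct exposure path as well, so their
mediator→outcome ratios estimate b + c′/a rather than b; keeping them
would bias the decomposition whenever the exposure→mediator effect is
large enough to make exposure loci significant for the mediator.

## The synthetic-data generator

`simulate_gwas()` emulates the three-cohort two-sample structure at
summary level; no individual-level genotypes are simulated, because
two-sample MR consumes only summary statistics and summary-level
generation keeps a full study in milliseconds.

Per locus with minor-allele frequency maf (uniform on [0.05, 0.5]), the
true effect on its *primary* trait is drawn Normal(0, h²/(2·maf·(1−maf)))
so the expected variance explained equals the per-SNP heritability
(default 0.1%), and the observed beta adds noise with the analytic
standard error 1/√(2·maf·(1−maf)·n). For the binary outcome the standard
error uses the effective sample size n_case·n_control/n — the standard
log-OR approximation, which at the default 6,303 cases / 325,717 controls
inflates outcome standard errors about 7-fold relative to a quantitative
trait of the same size.

Default study conditions: 45 exposure-instrument loci at n = 496,946; 50
mediator-instrument loci at n = 194,453 (mediator-specific instruments
are required for the step-2 MR — exposure loci alone cannot instrument
the mediator, since their mediator associations sit far below genome-wide
significance); 50 null loci; a = 0.06, b = ln 1.25, c′ = 0.22, hence a
true proportion mediated of 5.7%. Configurable extras: balanced or
directional horizontal pleiotropy on the outcome side of the exposure
loci; outlier loci with offsets in units of the outcome se; a fraction of
palindromic allele pairs; LD blocks of proxies tagging exposure loci
(proxy effects attenuated by r, constant-correlation blocks in the LD
matrix — a deliberate simplification of real LD); and reverse-causal loci
whose primary effect is on the outcome with a configurable fraction
(default 0.3) leaking back into the exposure.

Two conventions worth knowing:

* Effect alleles are labelled so the primary-trait effect is
  non-negative. This is a pure labelling choice (any GWAS can be
  re-oriented this way), but it makes "directional pleiotropy" in the
  generator mean what MR-Egger estimates: a constant outcome offset
  against randomly-signed exposure effects would be balanced, not
  directional, after Egger's orientation step.
* All randomness flows from the single config seed through an isolated
  RNG scope; repeated calls are byte-identical and the session RNG is
  untouched.

What the generator does *not* emulate: sample overlap between cohorts,
population stratification, realistic LD beyond constant-correlation
blocks, allele-frequency differences between cohorts, and non-Gaussian
effect-size distributions. Passing tests therefore demonstrate internal
statistical correctness under idealized two-sample conditions, not
robustness to the failure modes of real cohort data.

## Calibration results and problem sizes

The test suite and the acceptance script recompute, among others: IVW
type-I error at the 5% level under the simulated null (500–1000 seeds;
the multiplicative random-effects model makes it mildly conservative, and
it stays within 0.05 ± 0.02); Cochran's Q/df mean within 5% of 1 (1000
seeds); recovery of an injected directional pleiotropy intercept of 0.01
(mean over 100 seeds within [0.005, 0.015]); MR-PRESSO detection of a
10·se outlier present in the instrument set (≥ 95% of 100 seeds at 1000
simulations); Steiger removal of ≥ 90% of reverse-causal loci at
n = 100,000; and full-pipeline recovery of configured mediation
proportions (200 seeds per setting, with weighted-median and MR-PRESSO
simulation counts reduced to 200 inside these loops — they do not affect
the recovered proportion). These sizes were chosen to make the Monte-Carlo
error of each check small relative to its tolerance.

## Known limitations

* **The proportion mediated is an upward-biased ratio.** Even with the
  total-effect gate, E[1/ĉ] > 1/c by roughly half the squared coefficient
  of variation of ĉ. At the default outcome precision (total-effect
  z ≈ 3.9, matching a FinnGen-scale binary outcome) this leaves a bias of
  about +5–6% *relative* (e.g. a true 25% proportion is recovered as
  ≈ 26.5% on average, as the acceptance recovery computation shows), with
  conditioning on mediator screening contributing a further point or so.
  The bias shrinks quadratically with the total-effect precision and is a
  property of the estimator the field uses, not of this implementation;
  single-study proportions at modest outcome power should be read with
  this in mind.
* The Egger intercept test is mildly conservative under the null because
  of the max(1, ·) truncation of the residual scale.
* Per-instrument F statistics are the (β/se)² approximation; no
  first-stage regression is available from summary data.
* The Steiger variance-explained formula treats the outcome GWAS sample
  size at face value; for case-control outcomes this is an approximation
  on the observed scale.
* One mediator at a time: multivariable MR, simultaneous mediators and
  exposure–mediator interactions are out of scope.
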