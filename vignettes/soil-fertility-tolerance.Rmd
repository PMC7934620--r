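---
title: "Screening genotypes for low soil fertility tolerance with the SFSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genotypes for low soil fertility tolerance with the SFSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsi)
```

## The screening problem

Breeding programmes for staple crops in low-input farming systems need
genotypes that hold their yield when soil nutrients are scarce, and
genotypes that convert added fertilizer into yield. A standard screen grows
a panel of genotypes under two contrasting fertility treatments — a
nutrient-depleted low-fertility (LF) main plot and an NPK-fertilized
high-fertility (HF) main plot — in a split-plot design over several years,
and summarises each genotype's response with a susceptibility index.

`sfsi` implements this analysis end to end for plot-level trial data: trait
means per genotype and treatment, percent reduction, stress intensity, the
soil fertility susceptibility index, tolerance classification against a
check variety, the supporting trial statistics, and a calibrated simulator
with known truth for validating the whole pipeline. As a worked reference
it packages the genotype means of a two-year white Guinea yam
(*Dioscorea rotundata*) trial of 20 advanced breeding lines plus the
landrace check "Amula" grown at Ibadan, Nigeria
(`yam_trial_means()`).

## The index

For one trait, let $\bar{x}_{lf}$ and $\bar{x}_{hf}$ be a genotype's mean
value (g plant$^{-1}$) under LF and HF, and $\bar{Y}_{lf}$, $\bar{Y}_{hf}$
the corresponding grand means over genotypes. The package computes

* **percent reduction** $\mathrm{PR} = (1 - \bar{x}_{lf}/\bar{x}_{hf}) \times 100$,
  the genotype's own relative loss under stress (negative if it performs
  better under LF; never clipped);
* **stress intensity** $\mathrm{SI} = 1 - \bar{Y}_{lf}/\bar{Y}_{hf}$, the
  population-level severity of the stress, which must be strictly positive
  for the index to be defined;
* the **soil fertility susceptibility index**, a Fischer–Maurer-type
  stress-susceptibility index,
  $$\mathrm{SFSI} = \frac{1 - \bar{x}_{lf}/\bar{x}_{hf}}{1 - \bar{Y}_{lf}/\bar{Y}_{hf}}
                  = \frac{\mathrm{PR}/100}{\mathrm{SI}}.$$

SFSI $< 1$ marks a genotype that loses proportionally less than the
population average; SFSI $> 1$ proportionally more. Two exact algebraic
properties follow and are enforced by property tests: $\mathrm{SFSI}
\times \mathrm{SI} \times 100 = \mathrm{PR}$ for every row, and complete
invariance of PR, SI, SFSI and the classification under any common
rescaling of the trait.

Two design choices deserve note:

* **Grand means are unweighted means of the genotype means**, not means
  over raw plots. With a balanced trial the two coincide; with missing data
  they do not, and the genotype-mean convention is what reproduces the Mean
  row of a published genotype-mean table. (On the packaged shoot trait this
  choice exposes a handful of internally inconsistent printed index cells —
  see "Reproducing the reference trial".)
* **Pooling**: genotype means pool all non-missing observations across
  years, replicates and plants. Missing values are excluded pairwise, never
  imputed, and every exclusion is reported (`excluded_genotypes()`,
  `validation_report()`).

## Classification against the check

`classify_tolerance()` labels each genotype relative to the check variety.
The default rule calls a genotype **tolerant** when its SFSI is strictly
below the check's *and* its PR is below the table-mean PR (a low relative
susceptibility paired with a low absolute loss), and **susceptible** when
its SFSI is at least `susceptible_sfsi_min`. The susceptibility threshold
defaults to 1.25; on the packaged trial this separates the three genotypes
the screen flags as fertilizer-responsive but stress-susceptible (SFSI
1.32–1.34 for tuber yield, next genotype at 1.17) and is configurable
because it is a screening convention, not an estimated quantity. Everything
else is *intermediate*; the check itself is labelled *check*.

## Supporting statistics

* `fit_split_plot()` fits the standard split-plot linear mixed model with
  `lme4`: fixed effects year × treatment × genotype, random intercepts for
  the block (year × replicate) and the main plot (block × treatment), the
  two error strata of the design; terms are summarised by Type II Wald
  chi-square tests (`car::Anova`). Reps are treated as nested within years,
  the usual layout when a trial is re-randomised each season. A singular
  fit triggers a flagged refit with the block intercept only. Wald
  chi-square tests ignore denominator degrees of freedom, so with only
  eight main plots the whole-plot terms (year, treatment, their
  interaction) are anti-conservative under the null; the package's
  calibration tests therefore assert null uniformity for the
  subplot-stratum interaction terms, and whole-plot p-values should be read
  qualitatively.
* `genotype_treatment_tests()` runs a two-sided Welch t-test of LF against
  HF observations per genotype, with no correction across genotypes and a
  strict `p < alpha` significance rule, so a p-value exactly at alpha does
  not count as significant.
* `dunnett_vs_check()` compares every genotype with the check within one
  treatment level using the multivariate-t Dunnett adjustment
  (`multcomp::glht`), two-sided by default, with the usual significance
  bands (`***`, `**`, `*`, `+` for $p<0.1$). The quasi-Monte-Carlo
  integration behind the adjusted p-values is pinned to an internal RNG
  state, so results are deterministic and the pipeline's report bundles are
  byte-identical across runs.
* `trait_correlation()` gives Pearson's $r$ with the exact
  $t_{n-2}$ p-value for paired per-genotype summaries. Cross-trait
  correlations are computed on genotype means ($n$ = number of genotypes),
  the resolution at which such trials report them.

## The simulator

`simulate_trial()` generates plant-level observations from an additive
Gaussian model on the trait scale: genotype × treatment expectation plus
year, year × treatment, block, main-plot and residual effects. Effects are
additive (no log link) precisely so that the implied truth stays analytic:
`sim_truth()` computes the true PR, SI and SFSI from the configuration
alone, never from a sample, and a noise-free simulation reproduces it
exactly through the estimation pipeline.

Default parameters emulate the packaged reference trial: 21 genotypes whose
HF means and reduction fractions are read from the packaged tuber-yield
table, 2 years × 2 replicates × 3 plants per subplot (n = 12 per genotype
and treatment), and noise standard deviations of 500 (residual), 150 (main
plot) and 100 (block) g plant$^{-1}$ with year effects of ±150 and
year × treatment effects of ±50. The residual scale was chosen once so
that per-genotype Welch tests at n = 12 produce p-values in the range such
trials report (roughly 0.00–0.2 for treatment gaps of 450–900 g
plant$^{-1}$); the trial itself publishes no residual diagnostics, so this
is a calibration judgement, documented here rather than tuned.

Known limitations of the generator, which bound what passing tests say
about real data:

* Negative simulated masses are clipped at zero (with a reported count).
  At the calibrated noise this truncates the lowest-yielding genotypes'
  LF distributions and biases their sample means slightly upward — about a
  2–3% inflation of the LF grand mean. Real trials achieve non-negativity
  through skewness, not truncation; the law-of-large-numbers test
  therefore runs at means far from zero.
* Noise is homoscedastic on the trait scale, while the reference trial's
  printed p-values suggest genotype-specific variances.
* No spatial layout, sprouting-time variation, virus load or weather
  covariates; year effects are additive constants.

Seeding is hierarchical: one root seed, with deterministic sub-streams per
stratum and per genotype, so appending genotypes to a configuration does
not reshuffle the noise of existing ones.

`recovery_experiment()` repeatedly simulates, runs the estimation pipeline
and reports per-genotype bias and RMSE of the estimated SFSI. RMSE shrinks
with more replicates or years. One structural fact it exposes: on the
reference truth the tolerant/check boundary (SFSI 0.859 vs 0.87) is
narrower than any realistic sampling error at n = 12, so *exact* recovery
of the published tolerant set is rare at any plausible noise level even
though the susceptible set (well separated at $\ge$ 1.32) is recovered
essentially always once noise is moderate. Screening calls near the check
boundary should be treated as provisional.

## Reproducing the reference trial

`reproduce_reference()` recomputes both trait index tables, the tolerance
classification and the three cross-trait correlations from the packaged
genotype means, and compares every quantity against the published value at
fixed tolerances (±0.1 on g-plant$^{-1}$ means and PR, matching their
1-dp printing; ±0.01 on SFSI, 2-dp printing; ±0.03 on correlations, whose
source-data granularity is unknown). Comparison failures are reported in
the run log, never raised: the tuber table reproduces cell-for-cell, while
four printed shoot SFSI cells disagree with their own printed PR and SI
column — most prominently the check variety's cell, printed 0.08 where
recomputation gives 0.89 and the source's own text says 0.88. Back-solving
the remaining three suggests the published shoot index column was computed
with a slightly different stress intensity (≈0.353, consistent with
plot-level grand means) than its printed Mean row (0.347). The recomputed
values are taken as authoritative and the discrepancies are always logged.

## Numerical conventions

* Report rounding is half-away-from-zero (`round_half_up()`): means and PR
  to 1 dp, SFSI to 2 dp. Internal computation always keeps full precision.
* Index tables are sorted by ascending SFSI with ties broken by genotype
  ID.
* Degenerate inputs fail loudly with typed conditions: `SI <= 0`
  (population not stressed) is a stress-orientation error; a zero HF mean
  is an undefined-rate error; rows with non-positive HF means are flagged
  and excluded from grand means with a warning.
* Problem sizes used by the validation suite are chosen to keep it quick
  while retaining power: 150 null fits for mixed-model calibration on a
  6-genotype design, 250 null simulations with 10 comparators for the
  Dunnett family-wise error (checked against a 3-standard-error binomial
  band around $\alpha$), 1,000 random tables for the index algebra, and
  exhaustive permutation oracles at 6 + 6 observations for the Welch test.
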