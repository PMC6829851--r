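---
title: "Methods: left-truncated Cox versus logistic regression for genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left-truncated Cox versus logistic regression for genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxscan)
```

## The problem

Cohorts assembled from electronic health records observe each individual
over a window `[entry_age, exit_age]`: people enter the record system at
different ages (left truncation) and most leave it without developing the
disease of interest (right censoring). Genome-wide association studies on
such cohorts usually dichotomise this into case/control status and fit
logistic regression per variant, adjusting for age with flexible terms.
That discards the time dimension: a person diagnosed at 45 and one
diagnosed at 85 are the same "case", and a person censored at 30 is the
same "control" as one disease-free at 90.

`coxscan` implements both analyses over the same cohort so they can be
compared directly:

* a Cox proportional-hazards scan whose partial likelihood correctly
  handles delayed entry, and
* a logistic scan adjusting for age via restricted cubic splines,

plus a simulator for cohorts with truncation and censoring, quality
control, power/type-I evaluators, and a sequential strategy that screens
with the cheap logistic test and refits promising variants with Cox.

## The Cox model with delayed entry

For individual $i$ with covariates $x_i$ the hazard is
$\lambda_i(t) = \lambda_0(t)\exp(x_i^\top\beta)$. With entry age $L_i$,
exit age $R_i$ and event indicator $\delta_i$, the risk set at event time
$t$ is $\{i : L_i < t \le R_i\}$, and the log partial likelihood sums
$x_i^\top\beta - \log\sum_{j \in \text{risk}(t)} e^{x_j^\top\beta}$
over events. Ties are handled by Efron's method (default) or Breslow's.

`fit_cox()` maximises this by Newton-Raphson with analytic gradient and
Hessian. Two implementation points matter for genome-scan throughput:

* **Counting-process risk sums in $O(n\log n)$.** Because
  $L_i < R_i$ always, $\{i: L_i \ge t\} \subseteq \{i: R_i \ge t\}$, so a
  sum over the risk set decomposes into a difference of two cumulative
  sums, one over entry-ordered and one over exit-ordered individuals. No
  per-event loop over subjects is needed; each Newton iteration is a few
  vectorised passes.
* **A univariate fast path.** Genome scans fit one genotype column at a
  time (covariate-free Cox scan); `fit_cox` dispatches to a scalar Newton
  update in that case and reuses the sorted risk-set structure across all
  SNPs of a scan.

Numerical safeguards: the linear predictor is centred before
exponentiation (the partial likelihood is shift-invariant); step-halving
(up to 20 halvings) enforces monotone likelihood ascent; convergence is
declared when the log-likelihood change falls below
$10^{-9}(|\ell| + 0.1)$; and fits drifting past $|\beta| > 15$ are flagged
as divergent (monotone-likelihood / separation behaviour), since a hazard
ratio of $e^{15}$ is never a real signal. Standard errors come from the
inverse observed information; per-coefficient tests are Wald.
`fit_logistic()` is an IRLS implementation with the same contract
(deviance-monotone trace, complete-separation flag, Wald tests).

Both fitters are validated in the test suite against independent
references (`survival::coxph`, `stats::glm`) and against brute-force
risk-set enumeration; the references are used only as test oracles, never
at runtime.

## The logistic comparator

`run_scan(..., method = "logistic")` regresses the event indicator on the
genotype plus `logistic_age_design()`: 5-knot restricted cubic splines
(Harrell's truncated-power basis, quantile knots) in the exit age and,
when entry ages vary, in the follow-up time `exit - entry`. This mirrors
the standard GWAS practice of flexible age adjustment while ignoring the
time-to-event structure.

## The simulator

`simulate_cox_cohort()` draws, per individual:

* genotypes: haploid 0/1 by default (one Bernoulli(MAF) draw; `ploidy = 2`
  gives 0/1/2), with MAFs from `maf_spectrum()` — default Unif(0.01, 0.40);
* event age $T = -\log(U)\,s / \exp(x^\top\beta)$, i.e. exponential with
  baseline scale $s$ (`baseline_scale`, default 10,000) modulated by the
  true log hazard ratios, which are Unif(0.3, 0.5) on the causal variants;
* censoring age $C = \min(\mathrm{Gamma}(1,1),\,2)$ and truncation
  (entry) age $L \sim \mathrm{Unif}(0, 0.1)$; individuals with
  $\min(T, C) \le L$ never enter the cohort and are removed.

Ages are on an abstract scale; what matters is the induced structure. At
the defaults with 100 causal variants the cohort shows roughly a 32%
event rate and 10% truncation removal — the regime the comparison targets
(common diseases in biobank-scale EHR cohorts). With few or no causal
variants the baseline scale 10,000 makes events essentially impossible
(rate $\approx (1-e^{-2})/10^4$), which the test suite exploits as a
closed-form check; null-calibration cohorts therefore use
`baseline_scale = 2`, which restores a ~30% event rate with all genetic
effects exactly zero.

`simulate_logistic_cohort()` generates from the logistic model instead
(risk depends on age at a fixed rate, `age_coef`, with the intercept
calibrated by bisection to a target prevalence): data where logistic
regression is correctly specified, used to verify that log hazard ratios
and log odds ratios agree when both models are near-correct (rare-event
regime).

All randomness flows from one `seed` through `substream_seed()`, so MAFs,
genotypes, coefficients and event times are independently reproducible.

## Scan pipeline and evaluation

`qc_filter_snps()` applies, in order: MAF $\ge$ 0.01, call rate $\ge$
0.95, and (diploid only) the exact Hardy-Weinberg test at $p \ge 10^{-3}$.
`run_scan()` aligns individuals by id, handles missing genotypes per-SNP
complete-case, and reports Bonferroni-adjusted p-values for a declared
number of tests `m_tests` (set it to the genome-wide test count, e.g.
800,000, even when only a subset of SNPs is simulated).
`sequential_scan()` runs logistic everywhere and refits with Cox only
where logistic $p \le 10^{-4}$, reporting the Cox p-value for refitted
SNPs.

`evaluate_power()` computes per-replicate true/false positive rates at
adjusted-p cutoffs, excluding flagged SNPs, and summarises the
Cox-minus-logistic TPR difference with its Monte Carlo standard error.
`genomic_inflation()` computes $\lambda_{GC}$ as the median association
$\chi^2_1$ over `qchisq(0.5, 1)` $= 0.4549$. `catalog_sensitivity()`
scores detection of known loci grouped into LD blocks (a block counts as
detected when its best adjusted p passes the cutoff).

## Problem sizes and expected behaviour

At the package's reference scale — 50,000 haploid individuals, 100 causal
variants, Bonferroni over 800,000 tests at $\alpha = 0.05$ — the Cox scan
detects on the order of 3-9 more true variants per 100 than the logistic
scan when the data are generated from the Cox model, while both methods
keep calibrated type-I error ($\lambda_{GC}$ within [0.95, 1.05] on null
SNPs; no null SNP passes the genome-wide threshold in $10^5$ attempts).
When the data are generated from the logistic model at low prevalence,
per-SNP log hazard ratios and log odds ratios correlate above 0.99, so
little is lost by the Cox analysis even when it is the misspecified one.
One full-scale replicate (both scans) takes roughly 10 seconds on one
CPU.

## Limitations

* The simulator draws independent SNPs; there is no linkage
  disequilibrium, population structure, or relatedness, so mixed-model
  adjustments are out of scope.
* The Cox fitter targets a single baseline hazard (no strata) and dense
  covariates.
* The divergence flag (|log HR| > 15) is a pragmatic monotone-likelihood
  detector, not a Firth-type correction; flagged SNPs are excluded rather
  than penalised.
* P-values are Wald-based; for very rare variants score or likelihood
  ratio tests would be preferable.
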