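# coxscan

Genome-wide association scans on EHR-style cohorts: left-truncated Cox
proportional-hazards regression versus age-adjusted logistic regression,
with a cohort simulator and evaluation tools to compare them.

## The problem

Cohorts linked to electronic health records observe each person over an
age window `[entry, exit]`: people enter the record system at different
ages (left truncation) and most are censored before any diagnosis. The
common GWAS practice is to collapse this to case/control status and fit
per-SNP logistic regressions with spline age adjustment. That throws away
the time axis. The alternative is a Cox model whose partial likelihood
uses the correct delayed-entry risk sets

    risk(t) = { i : entry_i < t <= exit_i },

with hazard `lambda_i(t) = lambda_0(t) exp(x_i' beta)`. This package
implements both analyses from scratch (Newton-Raphson on the
counting-process partial likelihood with Efron/Breslow ties; IRLS for the
logistic model), a simulator for truncated/censored cohorts, SNP quality
control, delayed-entry Kaplan-Meier curves, power and type-I-error
evaluation, genomic-control inflation, and a sequential strategy that
screens with the cheap logistic test and refits promising SNPs with Cox.

## Worked example

Simulate a cohort from the Cox generative model (50,000 haploid
individuals would be the study scale; a small cohort keeps this quick),
then scan it with both methods:

```r
library(coxscan)

cfg <- sim_cox_config(n_individuals = 5000, n_snps = 110, n_true = 100,
                      seed = 42)
cohort <- simulate_cox_cohort(cfg)
cohort
#> Simulated cox-model cohort: 4545 individuals x 110 SNPs (100 true)
#>   event rate 0.310; 455 individuals removed by truncation

fit <- fit_cox(cohort$genotypes[, 1], cohort$pheno)
summary(fit)
#> Left-truncated Cox model (efron ties)
#> n = 4545, events = 1409; log partial likelihood -10826.6051 (null -10830.3909)
#> Likelihood ratio statistic 7.572 on 1 df
#>     coef exp(coef)     se      z      p
#> x 0.2552    1.2907 0.0896 2.8469 0.0044

scan_cox <- run_scan(cohort$genotypes, cohort$pheno, method = "cox",
                     m_tests = 800000)
scan_log <- run_scan(cohort$genotypes, cohort$pheno, method = "logistic",
                     m_tests = 800000)

pw <- evaluate_power(list(rbind(scan_cox, scan_log)), list(cohort$truth),
                     cutoffs = 0.05)
pw
#> Power / type-I error across simulation replicates
#>    method cutoff  tpr fpr tpr_se fpr_se n_replicates
#>       cox   0.05 0.08   0     NA     NA            1
#>  logistic   0.05 0.02   0     NA     NA            1
#>
#> TPR difference (Cox - logistic):
#>  cutoff mean_diff se lo95 hi95
#>    0.05      0.06 NA   NA   NA
```

(Exact numbers depend on the seed; at the full study scale of 50,000
individuals the Cox scan finds roughly 3-9 more true SNPs per 100 than
the logistic scan at the Bonferroni 0.05 threshold.)

Other entry points: `sequential_scan()` (logistic screen at p <= 1e-4,
Cox refit), `km_delayed_entry()` (truncation-aware Kaplan-Meier),
`qc_filter_snps()` (MAF / call-rate / exact-HWE filters),
`genomic_inflation()` (lambda_GC), `catalog_sensitivity()` (LD-block
detection), `read_plink()` / `write_plink()` (PLINK 1 .bed/.bim/.fam),
`build_survival_phenotype()` (entry/exit/event construction from visit
records using the two-distinct-code-dates rule). A thin command-line
front end lives at `inst/cli/coxscan.R`; a methods write-up is in
`vignettes/methods.Rmd`.

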