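#' Minor-allele-frequency spectrum
#'
#' Describes the distribution minor allele frequencies are drawn from when
#' simulating genotypes: either a uniform interval or an explicit list of
#' frequencies to resample with replacement (e.g. an empirical spectrum).
#' All frequencies must lie in (0, 0.5].
#'
#' @param kind `"uniform"` or `"empirical"`.
#' @param lower,upper bounds of the uniform interval (ignored for
#'   `"empirical"`).
#' @param values explicit frequencies to resample from (for `"empirical"`).
#' @return An object of class `maf_spectrum`.
#' @examples
#' maf_spectrum("uniform", 0.01, 0.4)
#' maf_spectrum("empirical", values = c(0.1, 0.25, 0.4))
#' @export
maf_spectrum <- function(kind = c("uniform", "empirical"),
                         lower = 0.01, upper = 0.4, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (!(lower > 0 && upper <= 0.5 && lower <= upper))
      stop_coxscan("uniform MAF bounds must satisfy 0 < lower <= upper <= 0.5",
                   "coxscan_config_error")
  } else {
    if (is.null(values) || !length(values) ||
        any(values <= 0 | values > 0.5))
      stop_coxscan("empirical MAF values must lie in (0, 0.5]",
                   "coxscan_config_error")
  }
  structure(list(kind = kind, lower = lower, upper = upper, values = values),
            class = "maf_spectrum")
}

#' Sample minor allele frequencies from a spectrum
#'
#' @param spectrum a [maf_spectrum].
#' @param n_snps number of frequencies to draw.
#' @param seed integer seed (the draw is reproducible).
#' @return numeric vector of length `n_snps`, each value in (0, 0.5].
#' @examples
#' sample_mafs(maf_spectrum("uniform", 0.3, 0.3), 5, seed = 1)
#' @export
sample_mafs <- function(spectrum, n_snps, seed) {
  stopifnot(inherits(spectrum, "maf_spectrum"), n_snps >= 1)
  with_seed(seed, {
    if (spectrum$kind == "uniform")
      stats::runif(n_snps, spectrum$lower, spectrum$upper)
    else
      sample(spectrum$values, n_snps, replace = TRUE)
  })
}

#' Simulate a genotype matrix
#'
#' Allele counts are independent Binomial(ploidy, f) draws per SNP; a haploid
#' genome (ploidy 1) gives 0/1 counts, a diploid genome 0/1/2.
#'
#' @param mafs vector of per-SNP minor allele frequencies in (0, 0.5].
#' @param n_individuals number of rows.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param seed integer seed.
#' @return integer matrix (individuals x SNPs) with SNP ids as column names.
#' @export
simulate_genotypes <- function(mafs, n_individuals, ploidy = 1L, seed = 1L) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop_coxscan("allele frequencies must lie in (0, 0.5]",
                 "coxscan_config_error")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  m <- length(mafs)
  G <- with_seed(seed, matrix(
    stats::rbinom(n_individuals * m, ploidy, rep(mafs, each = n_individuals)),
    nrow = n_individuals, ncol = m))
  storage.mode(G) <- "integer"
  colnames(G) <- sprintf("snp%0*d", nchar(m), seq_len(m))
  rownames(G) <- sprintf("ind%0*d", nchar(n_individuals), seq_len(n_individuals))
  G
}

#' Configuration for the Cox generative model
#'
#' Event times follow a proportional-hazards model with an Exponential
#' baseline: for linear predictor eta, T = -log(U) * baseline_scale /
#' exp(eta). Censoring is min(Gamma(shape, rate), censor_cap) and truncation
#' (study entry) Unif(trunc_low, trunc_high); individuals whose event or
#' censoring time precedes their truncation time never enter the cohort and
#' are removed.
#'
#' Defaults mirror a large EHR-linked biobank scan: 50,000 haploid
#' individuals, 100 true risk alleles with log hazard ratios Unif(0.3, 0.5),
#' baseline scale 10,000, Gamma(1,1) censoring capped at 2, truncation
#' Unif(0, 0.1). Under the default MAF spectrum (Unif(0.01, 0.40)) the mean
#' event rate is close to 30% and about 9% of individuals are removed by
#' truncation.
#'
#' @param n_individuals,n_snps,n_true cohort and panel sizes.
#' @param coef_low,coef_high bounds of the true log hazard ratios.
#' @param baseline_scale scale (mean) of the Exponential baseline event time.
#' @param censor_shape,censor_rate,censor_cap Gamma censoring parameters and
#'   administrative cap.
#' @param trunc_low,trunc_high uniform truncation-time bounds.
#' @param ploidy 1 or 2.
#' @param maf_spectrum a [maf_spectrum].
#' @param seed master integer seed; all substreams derive from it.
#' @return a `sim_cox_config` list.
#' @export
sim_cox_config <- function(n_individuals = 50000L, n_snps = 100L,
                           n_true = 100L, coef_low = 0.3, coef_high = 0.5,
                           baseline_scale = 10000, censor_shape = 1,
                           censor_rate = 1, censor_cap = 2,
                           trunc_low = 0, trunc_high = 0.1, ploidy = 1L,
                           maf_spectrum = coxscan::maf_spectrum(),
                           seed = 1L) {
  stopifnot(n_true <= n_snps, coef_low <= coef_high, baseline_scale > 0,
            censor_cap > trunc_high, trunc_high >= trunc_low, trunc_low >= 0)
  structure(as.list(environment()), class = "sim_cox_config")
}

#' Simulate a cohort from the Cox generative model
#'
#' @param config a [sim_cox_config].
#' @return a list of class `simulated_cohort` with elements `genotypes`
#'   (retained individuals x SNPs), `truth` (logical mask of true risk
#'   alleles), `coefficients` (true log hazard ratios), `mafs`, `pheno`
#'   (a [survival_phenotype] for retained individuals), `n_removed`, and
#'   `event_rate`.
#' @export
simulate_cox_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cox_config"))
  cf <- config
  mafs <- sample_mafs(cf$maf_spectrum, cf$n_snps,
                      substream_seed(cf$seed, "mafs"))
  G <- simulate_genotypes(mafs, cf$n_individuals, cf$ploidy,
                          substream_seed(cf$seed, "genotypes"))
  beta <- numeric(cf$n_snps)
  truth <- rep(FALSE, cf$n_snps)
  truth[seq_len(cf$n_true)] <- TRUE
  beta[truth] <- with_seed(substream_seed(cf$seed, "coefficients"),
                           stats::runif(cf$n_true, cf$coef_low, cf$coef_high))
  eta <- drop(G %*% beta)
  tim <- with_seed(substream_seed(cf$seed, "times"), {
    u <- stats::runif(cf$n_individuals)
    tt <- -log(u) * cf$baseline_scale / exp(eta)
    cc <- pmin(stats::rgamma(cf$n_individuals, cf$censor_shape,
                             cf$censor_rate), cf$censor_cap)
    ll <- stats::runif(cf$n_individuals, cf$trunc_low, cf$trunc_high)
    list(t = tt, c = cc, l = ll)
  })
  exit <- pmin(tim$t, tim$c)
  keep <- exit > tim$l  # removed if min(T, C) < L (ties have probability 0)
  if (!any(keep))
    stop_coxscan("no individuals survive truncation", "coxscan_sim_error")
  pheno <- survival_phenotype(tim$l[keep], exit[keep],
                              as.integer(tim$t[keep] <= tim$c[keep]),
                              id = rownames(G)[keep])
  structure(list(
    genotypes = G[keep, , drop = FALSE],
    truth = stats::setNames(truth, colnames(G)),
    coefficients = stats::setNames(beta, colnames(G)),
    mafs = stats::setNames(mafs, colnames(G)),
    pheno = pheno,
    n_removed = sum(!keep),
    event_rate = mean(pheno$event_status),
    model = "cox", config = cf
  ), class = "simulated_cohort")
}

#' Configuration for the logistic generative model
#'
#' Age (a surrogate of the event time) is Normal(age_mean, age_sd); case
#' status is Bernoulli with log-odds `intercept + age_coef * age + x'beta`.
#' A censoring age Unif(censor_low, censor_high) converts case status into a
#' right-censored observation for the Cox comparator: observed time =
#' min(age, censor), with the event zeroed when `age > censor`. No left
#' truncation.
#'
#' The intercept may be the string `"auto"`, in which case it is calibrated
#' by bisection so that the mean simulated event probability equals
#' `target_rate` (default 0.30, near the ~32% rate of the motivating EHR
#' cohort simulations).
#'
#' @inheritParams sim_cox_config
#' @param coef_low,coef_high bounds of the true log odds ratios.
#' @param age_mean,age_sd Normal age parameters (years).
#' @param age_coef log-odds per year of age.
#' @param intercept numeric log-odds intercept, or `"auto"`.
#' @param target_rate marginal event rate targeted when `intercept = "auto"`.
#' @param censor_low,censor_high uniform censoring-age bounds (years).
#' @return a `sim_logistic_config` list.
#' @export
sim_logistic_config <- function(n_individuals = 50000L, n_snps = 100L,
                                n_true = 100L, coef_low = 0.3,
                                coef_high = 0.7, age_mean = 60, age_sd = 5,
                                age_coef = 0.001, intercept = "auto",
                                target_rate = 0.30, censor_low = 50,
                                censor_high = 85, ploidy = 1L,
                                maf_spectrum = coxscan::maf_spectrum(
                                  "uniform", 0.01, 0.5),
                                seed = 1L) {
  stopifnot(n_true <= n_snps, censor_low < censor_high, age_sd > 0)
  structure(as.list(environment()), class = "sim_logistic_config")
}

#' Simulate a cohort from the logistic generative model
#'
#' @param config a [sim_logistic_config].
#' @return a `simulated_cohort` list as in [simulate_cox_cohort], with extra
#'   elements `age`, `censor_age`, `status_raw` (pre-censoring case status)
#'   and `intercept` (the value actually used). `pheno` encodes the censored
#'   observation with entry age 0 shifted to just below the minimum observed
#'   time (no truncation).
#' @export
simulate_logistic_cohort <- function(config) {
  stopifnot(inherits(config, "sim_logistic_config"))
  cf <- config
  mafs <- sample_mafs(cf$maf_spectrum, cf$n_snps,
                      substream_seed(cf$seed, "mafs"))
  G <- simulate_genotypes(mafs, cf$n_individuals, cf$ploidy,
                          substream_seed(cf$seed, "genotypes"))
  beta <- numeric(cf$n_snps)
  truth <- rep(FALSE, cf$n_snps)
  truth[seq_len(cf$n_true)] <- TRUE
  beta[truth] <- with_seed(substream_seed(cf$seed, "coefficients"),
                           stats::runif(cf$n_true, cf$coef_low, cf$coef_high))
  eta0 <- drop(G %*% beta)
  age <- with_seed(substream_seed(cf$seed, "age"),
                   stats::rnorm(cf$n_individuals, cf$age_mean, cf$age_sd))
  b0 <- if (identical(cf$intercept, "auto"))
    calibrate_intercept(eta0 + cf$age_coef * age, cf$target_rate)
  else cf$intercept
  p <- stats::plogis(b0 + cf$age_coef * age + eta0)
  out <- with_seed(substream_seed(cf$seed, "outcome"), {
    status <- stats::rbinom(cf$n_individuals, 1L, p)
    cens <- stats::runif(cf$n_individuals, cf$censor_low, cf$censor_high)
    list(status = status, cens = cens)
  })
  obs_time <- pmin(age, out$cens)
  obs_status <- as.integer(out$status == 1L & age <= out$cens)
  # no truncation: every individual observable from age 0
  pheno <- survival_phenotype(rep(0, cf$n_individuals), obs_time, obs_status,
                              id = rownames(G))
  structure(list(
    genotypes = G,
    truth = stats::setNames(truth, colnames(G)),
    coefficients = stats::setNames(beta, colnames(G)),
    mafs = stats::setNames(mafs, colnames(G)),
    pheno = pheno,
    age = age, censor_age = out$cens, status_raw = out$status,
    intercept = b0,
    n_removed = 0L,
    event_rate = mean(obs_status),
    model = "logistic", config = cf
  ), class = "simulated_cohort")
}

# Bisection on the marginal mean of plogis(b0 + offset): monotone in b0.
calibrate_intercept <- function(offset, target, tol = 1e-10) {
  f <- function(b0) mean(stats::plogis(b0 + offset)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop_coxscan("cannot bracket target event rate for intercept calibration",
                 "coxscan_calibration_error")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated %s-model cohort: %d individuals x %d SNPs (%d true)\n",
    x$model, nrow(x$genotypes), ncol(x$genotypes), sum(x$truth)))
  cat(sprintf("  event rate %.3f; %d individuals removed by truncation\n",
              x$event_rate, x$n_removed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the genotype TSV, phenotype TSV and a truth TSV
#' (`snp_id`, `is_true`, `coefficient`) in the dialects consumed by the scan
#' functions.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  pp <- file.path(dir, paste0(prefix, "_phenotype.tsv"))
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_genotypes_tsv(cohort$genotypes, gp)
  write_phenotype(cohort$pheno, pp)
  utils::write.table(
    data.frame(snp_id = names(cohort$truth),
               is_true = as.integer(cohort$truth),
               coefficient = cohort$coefficients),
    tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = gp, phenotype = pp, truth = tp))
}
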