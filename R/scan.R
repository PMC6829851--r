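# Per-SNP association scans, QC and evaluation.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the minor-allele
#' count, computed by the standard stable recurrence over all heterozygote
#' counts of matching parity. The p-value is the total probability of
#' configurations no more likely than the observed one (two-sided).
#'
#' @param n_aa,n_ab,n_bb genotype counts (minor-allele homozygote,
#'   heterozygote, major-allele homozygote).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab          # minor allele count
  if (n_a > n) return(Recall(n_bb, n_ab, n_aa))
  hets <- seq.int(n_a %% 2L, n_a, by = 2L)
  probs <- numeric(length(hets))
  # start from mid-range het count, recur outward (Wigginton-style)
  mid <- hets[which.min(abs(hets - n_a * (2 * n - n_a) / (2 * n)))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1L) for (i in (i_mid - 1L):1L) {
    h <- hets[i + 1L]  # going down: het h -> h - 2
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * ((n_a - h) / 2 + 1) * ((2 * n - n_a - h) / 2 + 1))
  }
  if (i_mid < length(hets)) for (i in (i_mid + 1L):length(hets)) {
    h <- hets[i - 1L]  # going up: het h -> h + 2
    probs[i] <- probs[i - 1L] * 4 * ((n_a - h) / 2) * ((2 * n - n_a - h) / 2) /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("impossible heterozygote count for given alleles")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Quality-control filter for a genotype matrix
#'
#' Removes SNPs failing any of: minor allele frequency below `maf_min`,
#' call rate below `call_rate_min`, or exact Hardy-Weinberg p-value below
#' `hwe_p_min` (diploid genotypes only; haploid input skips the HWE test).
#' The first failing criterion, in that order, is recorded per excluded SNP.
#'
#' @param G genotype matrix (individuals x SNPs), allele counts with `NA`
#'   for missing.
#' @param maf_min,call_rate_min,hwe_p_min thresholds.
#' @param ploidy 1, 2 or `"auto"` (2 when any count equals 2).
#' @return list with `genotypes` (filtered matrix), `snp_stats` (data frame
#'   of per-SNP maf, call_rate, hwe_p), and `exclusions` (snp_id, reason).
#' @export
qc_filter_snps <- function(G, maf_min = 0.01, call_rate_min = 0.95,
                           hwe_p_min = 0.001, ploidy = "auto") {
  G <- as.matrix(G)
  if (identical(ploidy, "auto"))
    ploidy <- if (any(G == 2L, na.rm = TRUE)) 2L else 1L
  m <- ncol(G)
  call_rate <- colMeans(!is.na(G))
  af <- colMeans(G, na.rm = TRUE) / ploidy
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hwe_p <- rep(NA_real_, m)
  if (ploidy == 2L) {
    for (j in seq_len(m)) {
      g <- G[, j]
      hwe_p[j] <- hwe_exact_test(sum(g == 2L, na.rm = TRUE),
                                 sum(g == 1L, na.rm = TRUE),
                                 sum(g == 0L, na.rm = TRUE))
    }
  }
  reason <- rep(NA_character_, m)
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & call_rate < call_rate_min] <- "call_rate"
  if (ploidy == 2L)
    reason[is.na(reason) & hwe_p < hwe_p_min] <- "hwe"
  keep <- is.na(reason)
  if (!any(keep))
    stop_coxscan("all SNPs removed by QC", "coxscan_qc_error")
  list(genotypes = G[, keep, drop = FALSE],
       snp_stats = data.frame(snp_id = colnames(G), maf = maf,
                              call_rate = call_rate, hwe_p = hwe_p,
                              kept = keep, row.names = NULL),
       exclusions = data.frame(snp_id = colnames(G)[!keep],
                               reason = reason[!keep], row.names = NULL))
}

scan_one_method <- function(G, pheno, covariates, method, m_tests, ties) {
  m <- ncol(G)
  n_all <- nrow(G)
  if (nrow(pheno) != n_all)
    stop_coxscan("genotype and phenotype dimensions disagree",
                 "coxscan_alignment_error")
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0L
  if (has_cov) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_all)
      stop_coxscan("covariates must have one row per individual",
                   "coxscan_alignment_error")
  }
  ploidy <- if (any(G == 2L, na.rm = TRUE)) 2L else 1L
  full_prep <- if (method == "cox") coxlt_prepare(pheno) else NULL
  # warm start for the logistic scans: covariate-only coefficients with the
  # genotype slot at zero
  lg_start <- NULL
  if (method == "logistic") {
    base <- tryCatch({
      if (has_cov) fit_logistic(covariates, pheno$event_status)
      else NULL
    }, coxscan_error = function(e) NULL)
    if (!is.null(base) && base$converged)
      lg_start <- c(base$coefficients[1L], 0, base$coefficients[-1L])
  }
  out <- data.frame(snp_id = colnames(G), af = NA_real_, n_used = NA_integer_,
                    method = method, beta = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_, p_bonf = NA_real_,
                    converged = FALSE, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g)
    n_used <- sum(ok)
    out$n_used[j] <- n_used
    out$af[j] <- if (n_used) mean(g[ok]) / ploidy else NA_real_
    design <- if (has_cov) cbind(g = as.numeric(g[ok]),
                                 covariates[ok, , drop = FALSE])
              else matrix(as.numeric(g[ok]), ncol = 1L,
                          dimnames = list(NULL, "g"))
    fit <- tryCatch({
      if (method == "cox") {
        prep <- if (all(ok)) full_prep else
          coxlt_prepare(survival_phenotype(pheno$entry_age[ok],
                                           pheno$exit_age[ok],
                                           pheno$event_status[ok],
                                           id = pheno$id[ok]))
        fit_cox(design, pheno, ties = ties, prep = prep)
      } else {
        fit_logistic(design, pheno$event_status[ok], start = lg_start)
      }
    }, coxscan_error = function(e) NULL)
    if (is.null(fit)) { out$flagged[j] <- TRUE; next }
    idx <- if (method == "cox") 1L else 2L  # genotype coefficient
    flag <- if (method == "cox") fit$diverged else
      (fit$separated || abs(fit$coefficients[idx]) > 15)
    out$beta[j] <- fit$coefficients[idx]
    out$se[j] <- fit$se[idx]
    out$stat[j] <- fit$z[idx]
    out$converged[j] <- fit$converged
    out$flagged[j] <- flag || !fit$converged
    if (fit$converged && !flag) out$p[j] <- fit$p[idx]
  }
  out$p_bonf <- pmin(1, m_tests * out$p)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "m_tests") <- m_tests
  out
}

#' Per-SNP association scan
#'
#' Fits one model per SNP: Cox proportional hazards with left truncation
#' (genotype + optional covariates such as ancestry PCs) or logistic
#' regression (genotype + covariates; when `covariates` is `NULL` the
#' logistic model defaults to the restricted-cubic-spline age design of
#' [logistic_age_design], mirroring age/follow-up adjustment). The genotype
#' effect is additive (untransformed allele count). SNPs with missing
#' genotypes are handled per-SNP complete-case; non-converged, diverged or
#' separated fits are flagged and their p-value left missing.
#'
#' @param G genotype matrix with individual ids as row names.
#' @param pheno a [survival_phenotype] (ids must match `rownames(G)`; rows
#'   are realigned by id).
#' @param covariates optional matrix of extra covariates (ids in rownames
#'   realigned likewise).
#' @param method `"cox"` or `"logistic"`.
#' @param m_tests Bonferroni denominator; defaults to `ncol(G)` but may be
#'   overridden (e.g. 800000) so scaled-down panels reproduce genome-wide
#'   thresholds.
#' @param ties ties method for the Cox fits.
#' @return a `scan_result` data frame: `snp_id`, `af`, `n_used`, `method`,
#'   `beta`, `se`, `stat`, `p`, `p_bonf`, `converged`, `flagged`.
#' @export
run_scan <- function(G, pheno, covariates = NULL,
                     method = c("cox", "logistic"), m_tests = NULL,
                     ties = "efron") {
  method <- match.arg(method)
  aligned <- align_by_id(G, pheno, covariates)
  if (method == "logistic" && is.null(aligned$covariates))
    aligned$covariates <- logistic_age_design(aligned$pheno)
  scan_one_method(aligned$G, aligned$pheno, aligned$covariates, method,
                  m_tests %||% ncol(G), ties)
}

# realign phenotype (and covariates) rows to genotype rows by individual id
align_by_id <- function(G, pheno, covariates = NULL) {
  stopifnot(inherits(pheno, "survival_phenotype"))
  ids <- rownames(G)
  if (!is.null(ids)) {
    idx <- match(ids, pheno$id)
    if (anyNA(idx))
      stop_coxscan("individual ids in genotypes missing from phenotype",
                   "coxscan_alignment_error")
    pheno <- survival_phenotype(pheno$entry_age[idx], pheno$exit_age[idx],
                                pheno$event_status[idx], id = pheno$id[idx])
    if (!is.null(covariates) && !is.null(rownames(covariates))) {
      cidx <- match(ids, rownames(covariates))
      if (anyNA(cidx))
        stop_coxscan("individual ids in genotypes missing from covariates",
                     "coxscan_alignment_error")
      covariates <- covariates[cidx, , drop = FALSE]
    }
  } else if (nrow(G) != nrow(pheno)) {
    stop_coxscan("genotype and phenotype dimensions disagree",
                 "coxscan_alignment_error")
  }
  list(G = G, pheno = pheno, covariates = covariates)
}

#' Sequential logistic-then-Cox scan
#'
#' Runs the fast logistic scan on every SNP, then refits with left-truncated
#' Cox regression only those SNPs whose unadjusted logistic p-value is at or
#' below `filter_p` (default 1e-4). The reported p-value is the Cox p-value
#' for refitted SNPs and the logistic p-value otherwise; the `stage` column
#' records which model produced each row. The Bonferroni denominator is
#' unchanged by the filtering.
#'
#' @inheritParams run_scan
#' @param covariates_logistic,covariates_cox covariate matrices for the two
#'   stages (logistic defaults to the spline age design; Cox to none).
#' @param filter_p logistic p-value threshold for Cox refitting.
#' @return a `scan_result` data frame with an extra `stage` column
#'   (`"logistic"` or `"cox"`).
#' @export
sequential_scan <- function(G, pheno, covariates_logistic = NULL,
                            covariates_cox = NULL, filter_p = 1e-4,
                            m_tests = NULL, ties = "efron") {
  m_tests <- m_tests %||% ncol(G)
  lg <- run_scan(G, pheno, covariates_logistic, "logistic", m_tests)
  pass <- which(!is.na(lg$p) & lg$p <= filter_p)
  out <- lg
  out$stage <- "logistic"
  out$method <- "sequential"
  if (length(pass)) {
    cx <- run_scan(G[, pass, drop = FALSE], pheno, covariates_cox, "cox",
                   m_tests, ties)
    for (col in c("beta", "se", "stat", "p", "p_bonf", "converged", "flagged"))
      out[[col]][pass] <- cx[[col]]
    out$stage[pass] <- "cox"
  }
  out$p_bonf <- pmin(1, m_tests * out$p)
  attr(out, "m_tests") <- m_tests
  attr(out, "filter_p") <- filter_p
  out
}

#' Power and type-I error across simulation replicates
#'
#' For each Bonferroni-adjusted cutoff and each method, the true positive
#' rate is the fraction of true risk alleles with adjusted p below the
#' cutoff and the false positive rate the corresponding fraction of null
#' alleles; both are averaged over replicates with Monte-Carlo standard
#' errors. Flagged (non-converged/separated) SNPs are excluded from both
#' numerator and denominator. When both a Cox and a logistic scan are
#' present, 95% confidence intervals of the per-replicate TPR difference
#' (Cox minus logistic) are attached.
#'
#' @param results list over replicates; each element a `scan_result` or an
#'   rbind of several (distinguished by their `method` column).
#' @param truths list over replicates of logical truth masks named by
#'   `snp_id` (or a single mask recycled across replicates).
#' @param cutoffs adjusted-p cutoffs (each in (0, 1)).
#' @param m_tests optional Bonferroni denominator overriding the one stored
#'   in the scans.
#' @return a `power_report` data frame: `method`, `cutoff`, `tpr`, `fpr`,
#'   `tpr_se`, `fpr_se`, `n_replicates`; attribute `"tpr_diff"` holds the
#'   Cox-minus-logistic summary when applicable.
#' @export
evaluate_power <- function(results, truths, cutoffs = c(0.01, 0.05, 0.1),
                           m_tests = NULL) {
  if (any(cutoffs <= 0 | cutoffs >= 1))
    stop("cutoffs must lie in (0, 1)")
  if (inherits(results, "scan_result")) results <- list(results)
  if (is.logical(truths)) truths <- list(truths)
  if (length(truths) == 1L) truths <- rep(truths, length(results))
  stopifnot(length(truths) == length(results))
  per_rep <- list()
  for (r in seq_along(results)) {
    res <- results[[r]]
    truth <- truths[[r]]
    for (meth in unique(res$method)) {
      rr <- res[res$method == meth & !res$flagged & !is.na(res$p), ,
                drop = FALSE]
      mt <- m_tests %||% attr(res, "m_tests") %||% nrow(res)
      padj <- pmin(1, mt * rr$p)
      is_true <- truth[rr$snp_id]
      for (a in cutoffs) {
        sig <- padj < a
        per_rep[[length(per_rep) + 1L]] <- data.frame(
          rep = r, method = meth, cutoff = a,
          tpr = if (any(is_true)) mean(sig[is_true]) else NA_real_,
          fpr = if (any(!is_true)) mean(sig[!is_true]) else NA_real_)
      }
    }
  }
  per_rep <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(per_rep,
                                     per_rep[c("method", "cutoff")],
                                     drop = TRUE), function(d) {
    data.frame(method = d$method[1], cutoff = d$cutoff[1],
               tpr = mean(d$tpr), fpr = mean(d$fpr),
               tpr_se = stats::sd(d$tpr) / sqrt(nrow(d)),
               fpr_se = stats::sd(d$fpr) / sqrt(nrow(d)),
               n_replicates = nrow(d))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$method, agg$cutoff), ]
  if (all(c("cox", "logistic") %in% agg$method)) {
    diffs <- lapply(cutoffs, function(a) {
      dc <- per_rep[per_rep$method == "cox" & per_rep$cutoff == a, ]
      dl <- per_rep[per_rep$method == "logistic" & per_rep$cutoff == a, ]
      dd <- dc$tpr[order(dc$rep)] - dl$tpr[order(dl$rep)]
      se <- stats::sd(dd) / sqrt(length(dd))
      data.frame(cutoff = a, mean_diff = mean(dd), se = se,
                 lo95 = mean(dd) - 1.96 * se, hi95 = mean(dd) + 1.96 * se)
    })
    attr(agg, "tpr_diff") <- do.call(rbind, diffs)
  }
  attr(agg, "per_replicate") <- per_rep
  class(agg) <- c("power_report", "data.frame")
  agg
}

#' @export
print.power_report <- function(x, digits = 4, ...) {
  cat("Power / type-I error across simulation replicates\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  d <- attr(x, "tpr_diff")
  if (!is.null(d)) {
    cat("\nTPR difference (Cox - logistic):\n")
    print.data.frame(d, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Genomic inflation factor
#'
#' Lambda_GC: the median association chi-square statistic (1 df, obtained
#' from the p-values) divided by the median of the null chi-square(1)
#' distribution. Values near 1 indicate calibrated tests; values above 1
#' suggest inflation (confounding or polygenicity).
#'
#' @param p_values vector of at least 100 p-values in (0, 1].
#' @return scalar lambda_GC.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L)
    stop("at least 100 p-values are required for a stable lambda_GC")
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Sensitivity for known associations grouped in LD blocks
#'
#' Counts a known phenotype-LD-block pair as detected at a cutoff when at
#' least one of its member SNPs reaches a p-value at or below that cutoff
#' in the scan. Sensitivity is detected blocks over total blocks. When a
#' comparator scan is supplied, the relative change in sensitivity
#' `(sens - sens_comparator) / sens_comparator` is included per cutoff.
#'
#' @param result a `scan_result`.
#' @param blocks data frame with columns `phenotype`, `block_id`, `snp_id`
#'   mapping known associations to scanned SNPs.
#' @param cutoffs unadjusted p-value cutoffs.
#' @param comparator optional second `scan_result` (e.g. logistic when
#'   `result` is Cox).
#' @return data frame `cutoff`, `sensitivity`, `n_blocks` (plus
#'   `sensitivity_comparator`, `relative_change` when a comparator is given).
#' @export
catalog_sensitivity <- function(result, blocks, cutoffs,
                                comparator = NULL) {
  need <- c("phenotype", "block_id", "snp_id")
  if (!all(need %in% names(blocks)))
    stop("block map needs columns: ", paste(need, collapse = ", "))
  if (!nrow(blocks))
    stop_coxscan("empty LD-block map", "coxscan_config_error")
  if (!all(blocks$snp_id %in% result$snp_id))
    stop_coxscan("block map references SNP ids absent from the scan",
                 "coxscan_config_error")
  best_p <- function(res) {
    p <- res$p[match(blocks$snp_id, res$snp_id)]
    key <- paste(blocks$phenotype, blocks$block_id, sep = "\r")
    tapply(p, key, function(v) if (all(is.na(v))) NA_real_ else
      min(v, na.rm = TRUE))
  }
  bp <- best_p(result)
  out <- data.frame(cutoff = cutoffs,
                    sensitivity = vapply(cutoffs, function(a)
                      sum(!is.na(bp) & bp <= a) / length(bp), 0),
                    n_blocks = length(bp))
  if (!is.null(comparator)) {
    if (!all(blocks$snp_id %in% comparator$snp_id))
      stop_coxscan("block map references SNP ids absent from the comparator",
                   "coxscan_config_error")
    bp2 <- best_p(comparator)
    out$sensitivity_comparator <- vapply(cutoffs, function(a)
      sum(!is.na(bp2) & bp2 <= a) / length(bp2), 0)
    out$relative_change <- (out$sensitivity - out$sensitivity_comparator) /
      out$sensitivity_comparator
  }
  out
}

#' Write a scan result as TSV
#'
#' @param result a `scan_result`.
#' @param path output path.
#' @export
write_scan_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
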