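test_that("QC removes SNPs for the stated reasons", {
  set.seed(30)
  n <- 200
  G <- cbind(
    mono = rep(0L, n),                                    # MAF 0
    gappy = ifelse(runif(n) < 0.10, NA, rbinom(n, 2, 0.3)),  # 10% missing
    good = rbinom(n, 2, 0.3),
    hwe_bad = c(rep(0L, 100), rep(2L, 100))               # no heterozygotes
  )
  qc <- qc_filter_snps(G, maf_min = 0.01, call_rate_min = 0.95,
                       hwe_p_min = 0.001)
  ex <- qc$exclusions
  expect_equal(ex$reason[ex$snp_id == "mono"], "maf")
  expect_equal(ex$reason[ex$snp_id == "gappy"], "call_rate")
  expect_equal(ex$reason[ex$snp_id == "hwe_bad"], "hwe")
  expect_true("good" %in% colnames(qc$genotypes))
  expect_error(qc_filter_snps(matrix(0L, 10, 2), maf_min = 0.01),
               class = "coxscan_qc_error")
})

test_that("exact HWE test matches direct enumeration", {
  cases <- list(c(50, 20, 30), c(3, 20, 77), c(0, 10, 90), c(10, 50, 40),
                c(1, 1, 98))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enumeration(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  # genotype counts AA=50, Aa=20, aa=30: strongly out of equilibrium
  expect_lt(hwe_exact_test(50, 20, 30), 0.001)
})

test_that("haploid genotypes skip the HWE test", {
  set.seed(31)
  G <- matrix(rbinom(400, 1L, 0.3), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  qc <- qc_filter_snps(G)
  expect_true(all(is.na(qc$snp_stats$hwe_p)))
})

test_that("scans align individuals by id, not row order", {
  cc <- simulate_cox_cohort(sim_cox_config(n_individuals = 800,
                                           n_snps = 105, n_true = 100,
                                           seed = 32))
  sc <- run_scan(cc$genotypes, cc$pheno, method = "cox")
  # permute phenotype rows; ids let the scan realign
  perm <- sample(nrow(cc$pheno))
  ph2 <- survival_phenotype(cc$pheno$entry_age[perm],
                            cc$pheno$exit_age[perm],
                            cc$pheno$event_status[perm],
                            id = cc$pheno$id[perm])
  sc2 <- run_scan(cc$genotypes, ph2, method = "cox")
  expect_equal(sc$beta, sc2$beta, tolerance = 1e-12)
  expect_equal(sc$p, sc2$p, tolerance = 1e-12)
  # id mismatch is an error
  ph3 <- survival_phenotype(cc$pheno$entry_age, cc$pheno$exit_age,
                            cc$pheno$event_status,
                            id = paste0("zz", seq_len(nrow(cc$pheno))))
  expect_error(run_scan(cc$genotypes, ph3, method = "cox"),
               class = "coxscan_alignment_error")
})

test_that("missing genotypes are handled per-SNP complete-case", {
  cc <- simulate_cox_cohort(sim_cox_config(n_individuals = 600,
                                           n_snps = 102, n_true = 100,
                                           seed = 33))
  G <- cc$genotypes
  miss <- seq(1, nrow(G), by = 7)
  G[miss, 101] <- NA
  sc <- run_scan(G, cc$pheno, method = "logistic")
  expect_equal(sc$n_used[101], nrow(G) - length(miss))
  expect_equal(sc$n_used[102], nrow(G))
  # fit equals a manual complete-case fit (cohort-wide spline design,
  # rows subset per SNP - the scan's convention)
  ok <- !is.na(G[, 101])
  ad <- logistic_age_design(cc$pheno)
  man <- fit_logistic(cbind(g = G[ok, 101], ad[ok, , drop = FALSE]),
                      cc$pheno$event_status[ok])
  expect_equal(sc$beta[101], unname(coef(man)["g"]), tolerance = 1e-10)
})

test_that("sequential scan refits exactly the filter-passing SNPs", {
  cc <- simulate_cox_cohort(sim_cox_config(n_individuals = 4000,
                                           n_snps = 110, n_true = 100,
                                           seed = 34))
  lg <- run_scan(cc$genotypes, cc$pheno, method = "logistic")
  sq <- sequential_scan(cc$genotypes, cc$pheno, filter_p = 1e-4)
  pass <- !is.na(lg$p) & lg$p <= 1e-4
  expect_true(any(pass))       # some SNPs trip the filter at this scale
  expect_true(any(!pass))
  expect_equal(sq$stage, ifelse(pass, "cox", "logistic"))
  # filtered-out SNPs keep their logistic p; refitted SNPs get the Cox p
  expect_equal(sq$p[!pass], lg$p[!pass])
  cx <- run_scan(cc$genotypes[, pass, drop = FALSE], cc$pheno, method = "cox")
  expect_equal(sq$p[pass], cx$p)
  expect_true(all(sq$method == "sequential"))
})

test_that("evaluate_power reproduces hand counts", {
  res <- make_scan_result(paste0("s", 1:5),
                          p = c(0.005, 0.03, 0.2, 0.4, 0.9) / 5,
                          m_tests = 5)
  truth <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE), paste0("s", 1:5))
  pw <- evaluate_power(res, truth, cutoffs = c(0.01, 0.05, 0.1))
  # adjusted p of the true SNPs: 0.005, 0.03, 0.2
  expect_equal(pw$tpr, c(1 / 3, 2 / 3, 2 / 3))
  expect_equal(pw$fpr, c(0, 0, 0))
  expect_error(evaluate_power(res, truth, cutoffs = c(0, 0.05)),
               "cutoffs")
})

test_that("power evaluation is invariant to SNP and replicate order", {
  set.seed(35)
  reps <- lapply(1:3, function(r)
    make_scan_result(paste0("s", 1:20), p = runif(20)^3, m_tests = 20))
  truth <- setNames(rep(c(TRUE, FALSE), 10), paste0("s", 1:20))
  pw1 <- evaluate_power(reps, list(truth, truth, truth))
  shuf <- lapply(rev(reps), function(r) {
    r2 <- r[sample(nrow(r)), ]
    class(r2) <- class(r); attr(r2, "m_tests") <- attr(r, "m_tests")
    r2
  })
  pw2 <- evaluate_power(shuf, list(truth, truth, truth))
  expect_equal(pw1$tpr, pw2$tpr)
  expect_equal(pw1$fpr, pw2$fpr)
})

test_that("flagged SNPs are excluded from power numerators and denominators", {
  res <- make_scan_result(paste0("s", 1:4), p = c(1e-9, 1e-9, 0.5, 0.5),
                          m_tests = 4)
  res$flagged[c(1, 3)] <- TRUE
  truth <- setNames(c(TRUE, TRUE, FALSE, FALSE), paste0("s", 1:4))
  pw <- evaluate_power(res, truth, cutoffs = 0.05)
  expect_equal(pw$tpr, 1)  # only s2 counted among true SNPs
  expect_equal(pw$fpr, 0)  # only s4 among null SNPs
})

test_that("genomic inflation factor behaves definitionally", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  set.seed(36)
  p <- runif(1e5)
  expect_lt(abs(genomic_inflation(p) - 1), 0.02)
  # chi-square statistics scaled by 1.2 inflate lambda to ~1.2
  chi <- qchisq(runif(2e4), df = 1, lower.tail = FALSE) * 1.2
  p_inf <- pchisq(chi, df = 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p_inf) - 1.2), 0.05)
  expect_error(genomic_inflation(runif(50)), "at least 100")
  expect_error(genomic_inflation(c(rep(0.5, 200), 0)), "p-values")
})

test_that("catalog sensitivity counts detected LD blocks", {
  res <- make_scan_result(paste0("s", 1:6),
                          p = c(1e-9, 0.5, 1e-6, 0.2, 1e-3, 0.9))
  blocks <- data.frame(
    phenotype = c("ph1", "ph1", "ph1", "ph1", "ph2", "ph2"),
    block_id = c("b1", "b1", "b2", "b2", "b3", "b3"),
    snp_id = c("s1", "s2", "s3", "s4", "s5", "s6"))
  # best p per block: 1e-9, 1e-6, 1e-3
  sens <- catalog_sensitivity(res, blocks, cutoffs = c(5e-8, 1e-5, 0.01))
  expect_equal(sens$sensitivity, c(1 / 3, 2 / 3, 1))
  expect_equal(sens$n_blocks, rep(3L, 3))
  # comparator: relative change
  res2 <- make_scan_result(paste0("s", 1:6),
                           p = c(1e-9, 0.5, 0.2, 0.2, 0.5, 0.9))
  both <- catalog_sensitivity(res, blocks, cutoffs = 1e-5, comparator = res2)
  expect_equal(both$sensitivity_comparator, 1 / 3)
  expect_equal(both$relative_change, (2 / 3 - 1 / 3) / (1 / 3))
  # errors
  expect_error(catalog_sensitivity(res, blocks[0, ], 0.05),
               class = "coxscan_config_error")
  blocks$snp_id[1] <- "absent"
  expect_error(catalog_sensitivity(res, blocks, 0.05),
               class = "coxscan_config_error")
})
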