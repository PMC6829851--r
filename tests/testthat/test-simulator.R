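test_that("sample_mafs respects its spectrum", {
  # degenerate interval
  expect_equal(sample_mafs(maf_spectrum("uniform", 0.3, 0.3), 5, seed = 1),
               rep(0.3, 5))
  # analytic mean of Unif(0.01, 0.5) is 0.255
  m <- sample_mafs(maf_spectrum("uniform", 0.01, 0.5), 1e5, seed = 2)
  se <- sqrt((0.5 - 0.01)^2 / 12 / 1e5)
  expect_lt(abs(mean(m) - 0.255), 3 * se)
  # explicit list resampling stays on its support
  v <- sample_mafs(maf_spectrum("empirical", values = c(0.1, 0.4)), 1e4,
                   seed = 3)
  expect_true(all(v %in% c(0.1, 0.4)))
  # bounds outside (0, 0.5] rejected
  expect_error(maf_spectrum("uniform", 0, 0.5), class = "coxscan_config_error")
  expect_error(maf_spectrum("uniform", 0.1, 0.6), class = "coxscan_config_error")
})

test_that("simulate_genotypes draws Binomial(ploidy, f) counts", {
  g <- simulate_genotypes(rep(0.5, 1), 1e5, ploidy = 1L, seed = 4)
  expect_true(all(g %in% 0:1))
  expect_lt(abs(mean(g) - 0.5), 3 * sqrt(0.25 / 1e5))
  g2 <- simulate_genotypes(c(0.2, 0.4), 500, ploidy = 2L, seed = 5)
  expect_true(all(g2 %in% 0:2))
  expect_error(simulate_genotypes(c(0, 0.1), 10, seed = 1),
               class = "coxscan_config_error")
  # determinism under a fixed seed
  expect_identical(simulate_genotypes(c(0.2, 0.3), 100, seed = 7),
                   simulate_genotypes(c(0.2, 0.3), 100, seed = 7))
})

test_that("Cox-cohort removal fraction matches the analytic value", {
  # With all coefficients zero and baseline scale 10,000, event times are
  # astronomically large, so removal is driven by C < L with
  # C = min(Exp(1), 2), L ~ Unif(0, 0.1):
  # P(C < L) = 1 - (1 - exp(-0.1)) / 0.1 = 0.048374
  cf <- sim_cox_config(n_individuals = 2e5, n_snps = 2, n_true = 0, seed = 8)
  cc <- simulate_cox_cohort(cf)
  p_analytic <- 1 - (1 - exp(-0.1)) / 0.1
  se <- sqrt(p_analytic * (1 - p_analytic) / 2e5)
  expect_lt(abs(cc$n_removed / 2e5 - p_analytic), 3 * se)
})

test_that("Cox-cohort null event rate matches the small-hazard closed form", {
  # P(T < min(C, 2)) ~ E[min(Exp(1), 2)] / 10000 = (1 - exp(-2)) / 1e4
  cf <- sim_cox_config(n_individuals = 4e5, n_snps = 1, n_true = 0, seed = 9)
  cc <- simulate_cox_cohort(cf)
  p_analytic <- (1 - exp(-2)) / 1e4
  se <- sqrt(p_analytic / 4e5)  # Poisson-scale MC error
  expect_lt(abs(cc$event_rate - p_analytic), 3 * se)
})

test_that("no truncation window means no removals", {
  cf <- sim_cox_config(n_individuals = 5000, n_snps = 1, n_true = 0,
                       trunc_low = 0, trunc_high = 0, seed = 10)
  # zero-width window: every subject enters at age 0 and is retained
  cc <- simulate_cox_cohort(cf)
  expect_identical(cc$n_removed, 0L)
})

test_that("event-time generator matches its survival function", {
  # Disable censoring and truncation; with zero coefficients and baseline
  # scale 2, exit times are Exp(scale 2) draws.
  cf <- sim_cox_config(n_individuals = 2e4, n_snps = 1, n_true = 0,
                       baseline_scale = 2, censor_rate = 1e-6,
                       censor_cap = 1e9, trunc_low = 0, trunc_high = 0,
                       seed = 11)
  cc <- simulate_cox_cohort(cf)
  expect_equal(cc$event_rate, 1)
  ks <- suppressWarnings(ks.test(cc$pheno$exit_age, pexp, rate = 0.5))
  expect_gt(ks$p.value, 0.001)
})

test_that("simulated cohorts are reproducible and internally consistent", {
  cf <- sim_cox_config(n_individuals = 2000, n_snps = 120, n_true = 100,
                       seed = 12)
  a <- simulate_cox_cohort(cf)
  b <- simulate_cox_cohort(cf)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$pheno, b$pheno)
  expect_identical(sum(a$truth), 100L)
  expect_true(all(a$coefficients[!a$truth] == 0))
  expect_true(all(a$coefficients[a$truth] >= 0.3 &
                    a$coefficients[a$truth] <= 0.5))
  expect_true(all(a$pheno$entry_age < a$pheno$exit_age))
  expect_identical(a$n_removed + nrow(a$pheno), 2000L)
})

test_that("logistic cohort follows its generative model", {
  # closed-form check of the event probability with a fixed intercept
  cf <- sim_logistic_config(n_individuals = 2e5, n_snps = 1, n_true = 0,
                            intercept = -0.847, age_mean = 60, age_sd = 1e-9,
                            seed = 13)
  cc <- simulate_logistic_cohort(cf)
  p_true <- plogis(-0.847 + 0.001 * 60)  # ~ sigmoid(-0.787) = 0.3128
  expect_lt(abs(mean(cc$status_raw) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 2e5))
  # saturation
  cf2 <- sim_logistic_config(n_individuals = 5000, n_snps = 1, n_true = 0,
                             intercept = -20, seed = 14)
  expect_lt(simulate_logistic_cohort(cf2)$event_rate, 0.001)
})

test_that("logistic-cohort censoring rule zeroes late events", {
  cf <- sim_logistic_config(n_individuals = 3000, n_snps = 2, n_true = 1,
                            seed = 15)
  cc <- simulate_logistic_cohort(cf)
  late <- cc$age > cc$censor_age
  expect_true(all(cc$pheno$event_status[late] == 0))
  expect_equal(cc$pheno$exit_age, pmin(cc$age, cc$censor_age))
  obs_events <- cc$status_raw == 1 & cc$age <= cc$censor_age
  expect_equal(cc$pheno$event_status, as.integer(obs_events))
})

test_that("auto intercept calibration hits the target rate", {
  cf <- sim_logistic_config(n_individuals = 5e4, n_snps = 110, n_true = 100,
                            target_rate = 0.30, seed = 16)
  cc <- simulate_logistic_cohort(cf)
  expect_lt(abs(mean(cc$status_raw) - 0.30), 0.01)
})
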