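# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# A small survival dataset with staggered entry and ~40% censoring.
random_small_surv <- function(n = 30, k = 2, seed = 1) {
  set.seed(seed)
  entry <- runif(n, 0, 0.6)
  exit <- entry + rexp(n, 1)
  status <- rbinom(n, 1, 0.6)
  if (sum(status) == 0) status[1] <- 1L
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  X[, k] <- rbinom(n, 1, 0.4)
  list(X = X, pheno = survival_phenotype(entry, exit, status),
       entry = entry, exit = exit, status = status)
}

# Brute-force Breslow log partial likelihood with risk sets enumerated
# directly from the definition entry < t <= exit (independent of the
# package's cumulative-sum path). Covariates centred to match fit_cox.
brute_partial_loglik <- function(beta, X, entry, exit, status) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  ll <- 0
  for (i in which(status == 1)) {
    t <- exit[i]
    risk <- which(entry < t & exit >= t)
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Direct enumeration oracle for the exact Hardy-Weinberg test: probability
# of each heterozygote count from log-factorials, two-sided tail.
hwe_enumeration <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  if (na > n) return(Recall(n_bb, n_ab, n_aa))
  hets <- seq(na %% 2, na, by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- match(n_ab, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# Independent implementation of Harrell's truncated-power restricted cubic
# basis, written directly from the formula.
rcs_direct <- function(x, knots) {
  K <- length(knots)
  tk <- knots[K]; tk1 <- knots[K - 1]
  pp <- function(u) ifelse(u > 0, u^3, 0)
  out <- matrix(0, length(x), K - 1)
  out[, 1] <- x
  for (j in seq_len(K - 2)) {
    out[, j + 1] <- (pp(x - knots[j]) -
                       pp(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                       pp(x - tk) * (tk1 - knots[j]) / (tk - tk1)) /
      (tk - knots[1])^2
  }
  out
}

# Build a scan_result data frame by hand (for evaluator tests).
make_scan_result <- function(snp_id, p, method = "cox", m_tests = length(p)) {
  out <- data.frame(snp_id = snp_id, af = 0.2, n_used = 100L,
                    method = method, beta = 0, se = 1, stat = 0, p = p,
                    p_bonf = pmin(1, m_tests * p), converged = TRUE,
                    flagged = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "m_tests") <- m_tests
  out
}
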