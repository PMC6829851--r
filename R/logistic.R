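# Logistic regression comparator and the restricted-cubic-spline age basis.

#' Restricted cubic spline basis (truncated power form)
#'
#' Harrell's restricted cubic spline: with knots t_1 < ... < t_K, the basis
#' has `K - 1` columns - the linear term x and, for j = 1..K-2,
#' \deqn{(x - t_j)_+^3 - (x - t_{K-1})_+^3 (t_K - t_j)/(t_K - t_{K-1})
#'       + (x - t_K)_+^3 (t_{K-1} - t_j)/(t_K - t_{K-1}),}
#' each divided by `(t_K - t_1)^2` so columns share the scale of x. The
#' resulting fit is cubic between knots and linear beyond the boundary
#' knots. Default knot locations follow Harrell's quantile recommendations
#' (for 5 knots: quantiles 0.05, 0.275, 0.5, 0.725, 0.95).
#'
#' @param x numeric vector.
#' @param n_knots number of knots (>= 3).
#' @param knots optional explicit, strictly increasing knot locations
#'   (overrides `n_knots`).
#' @return matrix with `length(knots) - 1` columns and attribute `"spec"`
#'   (a list with `kind`, `knots`) for reproducing the basis on new data.
#' @examples
#' b <- rcs_basis(rnorm(100), n_knots = 5)
#' ncol(b)  # 4
#' @export
rcs_basis <- function(x, n_knots = 5L, knots = NULL) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
      "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
      stop("n_knots must be between 3 and 7 (or supply knots explicitly)"))
    knots <- unname(stats::quantile(x, probs, type = 7, na.rm = TRUE))
  }
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing (too few distinct values?)")
  K <- length(knots)
  if (K < 3L) stop("restricted cubic splines need at least 3 knots")
  tk <- knots[K]; tk1 <- knots[K - 1L]; t1 <- knots[1L]
  norm2 <- (tk - t1)^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), K - 1L)
  B[, 1L] <- x
  for (j in seq_len(K - 2L)) {
    B[, j + 1L] <- (cube(x - knots[j]) -
                      cube(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                      cube(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm2
  }
  colnames(B) <- c("x", paste0("x'", seq_len(K - 2L)))
  attr(B, "spec") <- list(kind = "restricted_cubic", knots = knots)
  B
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald per-coefficient tests. An
#' intercept is prepended automatically. Complete (quasi-)separation is
#' flagged when fitted probabilities saturate at 0/1 for all observations of
#' either class; separated fits carry unreliable standard errors and are
#' excluded downstream.
#'
#' @param design numeric matrix (individuals x k) or vector, without
#'   intercept column.
#' @param y 0/1 outcome vector containing both classes.
#' @param tol convergence tolerance on the relative deviance change.
#' @param max_iter maximum IRLS iterations.
#' @param start optional starting coefficients (intercept first); a warm
#'   start from a covariate-only fit speeds up per-SNP scans.
#' @return object of class `logit_fit` with `coefficients`, `se`, `z`, `p`,
#'   `or`, `vcov`, `deviance`, `null_deviance`, `iter`, `converged`,
#'   `separated`, `n`.
#' @examples
#' x <- rep(c(1, 1, 0, 0), c(10, 20, 30, 40))
#' y <- rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
#' coef(fit_logistic(x, y))["x"]  # log odds ratio of the 2x2 table
#' @export
fit_logistic <- function(design, y, tol = 1e-13, max_iter = 50L,
                         start = NULL) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (anyNA(X) || any(!is.finite(X))) stop("design must be finite")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(design)")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2L)
    stop_coxscan("outcome has a single class; logistic model undefined",
                 "coxscan_fit_error")
  X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); k <- ncol(X)
  if (!is.null(start)) {
    stopifnot(length(start) == k)
    beta <- as.numeric(start)
  } else {
    beta <- numeric(k)
    beta[1L] <- stats::qlogis(mean(y))
  }
  dev_old <- Inf
  dev_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  dev <- NA_real_
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300)))
    dev_trace <- c(dev_trace, dev)
    if (abs(dev_old - dev) <= tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    if (iter > max_iter) break
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xw <- X * w
    beta_new <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, z)),
                         error = function(e) NULL)
    if (is.null(beta_new))
      stop_coxscan("singular weighted design (collinear covariates)",
                   "coxscan_identifiability_error")
    dev_old <- dev
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  eps <- 1e-8
  separated <- all(mu[y == 1] > 1 - eps) && all(mu[y == 0] < eps)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(vc), 0))
  zstat <- beta / se
  p <- 2 * stats::pnorm(-abs(zstat))
  py <- mean(y)
  null_dev <- -2 * sum(y * log(py) + (1 - y) * log(1 - py))
  names(beta) <- names(se) <- names(zstat) <- names(p) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = se, z = zstat,
                 p = pmax(p, .Machine$double.xmin), or = exp(beta),
                 vcov = vc, deviance = dev, null_deviance = null_dev,
                 dev_trace = dev_trace, iter = iter, converged = converged,
                 separated = separated, n = n),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic fit: n = %d, deviance %.3f (null %.3f)\n",
              x$n, x$deviance, x$null_deviance))
  print(round(rbind(coef = x$coefficients, `exp(coef)` = x$or,
                    se = x$se, z = x$z, p = x$p), digits))
  if (x$separated) cat("Warning: complete separation detected\n")
  if (!x$converged) cat("Warning: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(-object$deviance / 2, df = length(object$coefficients),
            class = "logLik")
}

#' Age-adjustment design for the logistic comparator
#'
#' Builds the non-genotype covariate columns used when logistic regression
#' stands in for a left-truncated Cox model: restricted cubic splines
#' (5 knots) for the exit age and, when entry ages vary (left truncation),
#' for follow-up time (exit minus entry). This mirrors adjusting for both
#' the age at event/censoring and the observation window.
#'
#' @param pheno a [survival_phenotype].
#' @param n_knots knots per spline.
#' @return covariate matrix (possibly with zero columns when ages are
#'   degenerate).
#' @export
logistic_age_design <- function(pheno, n_knots = 5L) {
  stopifnot(inherits(pheno, "survival_phenotype"))
  blocks <- list()
  if (length(unique(pheno$exit_age)) > n_knots) {
    b <- rcs_basis(pheno$exit_age, n_knots)
    colnames(b) <- paste0("exit_", seq_len(ncol(b)))
    blocks <- c(blocks, list(b))
  }
  fup <- pheno$exit_age - pheno$entry_age
  if (any(pheno$entry_age > 0) && length(unique(fup)) > n_knots) {
    b <- rcs_basis(fup, n_knots)
    colnames(b) <- paste0("fup_", seq_len(ncol(b)))
    blocks <- c(blocks, list(b))
  }
  if (!length(blocks)) return(matrix(0, nrow(pheno), 0L))
  do.call(cbind, blocks)
}
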