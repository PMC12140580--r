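# Brain-behavior inference: OLS regression with leave-one-out
# cross-validation and permutation validation, Benjamini-Hochberg FDR,
# Williams-form dependent-correlation (Steiger) test, and subgroup t tests.

#' Ordinary least squares fit
#'
#' Fits `y = b0 + sum_i b_i x_i` and reports coefficients, R-squared, the
#' overall F statistic with degrees of freedom, and its p value.
#'
#' @param x predictor vector or matrix (columns = predictors).
#' @param y outcome vector.
#' @param condition_tol condition-number tolerance for collinearity.
#' @return object of class `ols_fit`: `coefficients`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`, `fitted`, `residuals`, `n`.
#' @export
ols_fit <- function(x, y, condition_tol = 1e8) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop_("x and y lengths differ")
  if (anyNA(X) || anyNA(y)) stop_("missing values")
  if (n <= k + 1L) stop_("need n > k + 1 observations")
  Xc <- scale(X)
  if (kappa(cbind(1, Xc), exact = TRUE) > condition_tol)
    stop_("collinear predictors (condition number above tolerance)")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df1 <- k; df2 <- n - k - 1L
  f <- (tss - rss) / df1 / (rss / df2)
  structure(list(coefficients = fit$coefficients, r_squared = r2,
                 f_statistic = f, df = c(df1, df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 fitted = fit$fitted.values, residuals = res, n = n),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, R^2 = %.3f, F[%d, %d] = %.3f, p = %.4g\n",
              x$n, x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

# closed-form leave-one-out squared errors via the hat-matrix identity:
# e_(-i) = r_i / (1 - h_ii)
.loo_sq_errors <- function(X1, y, hat_diag = NULL) {
  if (is.null(hat_diag)) {
    qrX <- qr(X1)
    hat_diag <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  }
  r <- stats::lm.fit(X1, y)$residuals
  (r / (1 - hat_diag))^2
}

#' LOOCV mean squared error with permutation validation
#'
#' Computes the leave-one-out cross-validated squared prediction error of the
#' OLS model (via the hat-matrix identity), then builds a null distribution
#' of LOOCV MSEs by permuting the predictor-outcome mapping `n_perm` times.
#' The model validates internally when the observed MSE is smaller than the
#' bulk of the null; the reported p value is the add-one-corrected proportion
#' of null MSEs less than or equal to the observed MSE.
#'
#' @param x predictor vector or matrix.
#' @param y outcome vector.
#' @param n_perm number of permutations (default 10,000; >= 100).
#' @param seed integer seed.
#' @return object of class `loocv_perm`: `mse`, `sd` (of the per-subject
#'   squared errors), `p`, `null_mse`, `n`.
#' @export
loocv_permutation <- function(x, y, n_perm = 10000L, seed = 1L) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop_("need n >= 4")
  if (n_perm < 100) stop_("n_perm must be at least 100")
  X1 <- cbind(1, X)
  qrX <- qr(X1)
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  sq <- .loo_sq_errors(X1, y, h)
  mse <- mean(sq)
  null_mse <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mean(.loo_sq_errors(X1, y[sample.int(n)], h))
    }, 0)
  })
  p <- (1 + sum(null_mse <= mse)) / (n_perm + 1)
  structure(list(mse = mse, sd = stats::sd(sq), p = p, null_mse = null_mse,
                 n = n), class = "loocv_perm")
}

#' @export
print.loocv_perm <- function(x, ...) {
  cat(sprintf("<loocv_perm> n = %d, LOOCV MSE = %.3f (sd %.3f), permutation p = %.4g\n",
              x$n, x$mse, x$sd, x$p))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, returned in input order.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Steiger's test for dependent correlations (Williams' form)
#'
#' Tests `H0: rho12 = rho13` for correlations sharing variable 1, measured on
#' the same n subjects, using the Williams t statistic with `n - 3` degrees
#' of freedom and a two-sided p value.
#'
#' @param r12,r13 the two correlations being compared (shared variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (> 3).
#' @return list with `t`, `df`, `p`.
#' @export
steiger_dependent_corr <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23))
    if (!is.finite(r) || abs(r) >= 1) stop_("correlations must be in (-1, 1)")
  check_number(n, "n", lower = 4, integer = TRUE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) stop_("infeasible correlation triple")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  tt <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(t = tt, df = n - 3,
       p = 2 * stats::pt(abs(tt), n - 3, lower.tail = FALSE))
}

#' Pairwise two-sample t tests between subgroups
#'
#' Pooled-variance two-sample t tests (df = n1 + n2 - 2) for every pair of
#' subgroups.
#'
#' @param values numeric vector.
#' @param group factor/vector of subgroup labels.
#' @return data.frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p`.
#' @export
subgroup_tests <- function(values, group) {
  group <- as.factor(group)
  if (any(table(group) < 2L)) stop_("each subgroup needs at least 2 values")
  levs <- levels(group)
  pairs <- utils::combn(levs, 2L)
  out <- apply(pairs, 2L, function(pr) {
    a <- values[group == pr[1L]]; b <- values[group == pr[2L]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Paired t test
#'
#' @param values1,values2 equal-length numeric vectors (same subjects).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_test <- function(values1, values2) {
  if (length(values1) != length(values2)) stop_("unequal lengths")
  d <- values1 - values2
  if (stats::sd(d) == 0 && all(d == 0)) {
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0))
  }
  tt <- stats::t.test(values1, values2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d))
}
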