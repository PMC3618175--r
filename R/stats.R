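#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for group sizes `m` and `n`, the number of arrangements giving
#' each value of U via the standard recurrence
#' `N(m, n, u) = N(m - 1, n, u - n) + N(m, n - 1, u)`, normalized to
#' probabilities. The distribution is symmetric about `m n / 2`.
#'
#' @param m,n Group sizes.
#' @return Tibble: `u` (0 to `m n`), `prob`.
#' @export
mw_u_null_distribution <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L || n < 1L) abort("Group sizes must be >= 1.")
  N <- array(0, dim = c(m + 1L, n + 1L, m * n + 1L))
  N[1L, , 1L] <- 1
  N[, 1L, 1L] <- 1
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      u <- 0:(i * j)
      a <- numeric(length(u))
      from1 <- u - j
      ok <- from1 >= 0L
      a[ok] <- N[i, j + 1L, from1[ok] + 1L]
      a <- a + N[i + 1L, j, u + 1L]
      N[i + 1L, j + 1L, u + 1L] <- a
    }
  }
  cnt <- N[m + 1L, n + 1L, ]
  tibble(u = 0:(m * n), prob = cnt / sum(cnt))
}

#' Exact two-sided p-value for a given U
#'
#' Computes the exact p-value from the full null distribution for an
#' observed U (min convention). Two-sided probability is twice the smaller
#' tail, capped at 1 (the tail-doubling convention).
#'
#' @param u Observed U statistic.
#' @param m,n Group sizes.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   tails of U.
#' @return Exact p-value.
#' @examples
#' mw_exact_p_from_u(53, 17, 19)  # ~ 0.00034
#' @export
mw_exact_p_from_u <- function(u, m, n, alternative = "two.sided") {
  dist <- mw_u_null_distribution(m, n)
  lower <- sum(dist$prob[dist$u <= u])
  upper <- sum(dist$prob[dist$u >= u])
  switch(match.arg(alternative, c("two.sided", "less", "greater")),
         "two.sided" = min(1, 2 * min(lower, upper)),
         "less" = lower,
         "greater" = upper)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test with the exact p-value computed from the implemented null
#' distribution (no normal approximation) when the data are tie-free. With
#' ties, midranks are used and a normal approximation with tie correction
#' is applied, with a warning.
#'
#' @param x,y Numeric samples, or a data frame with `value`/`group` columns
#'   given via `value` and `group` (tidy interface).
#' @param value,group When `x` is a data frame: column names (unquoted) of
#'   the measurement and the two-level grouping factor.
#' @param alternative Currently `"two.sided"` only for the data interface.
#' @return An `mw_exact` object: list with `u` (min convention), `u1`, `u2`
#'   (both directions), `m`, `n`, `p_value`, `exact` flag. Supports
#'   [tidy()] and [glance()].
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mann_whitney_exact <- function(x, y = NULL, value = NULL, group = NULL,
                               alternative = "two.sided") {
  if (is.data.frame(x)) {
    value <- rlang::enquo(value)
    group <- rlang::enquo(group)
    v <- rlang::eval_tidy(value, x)
    g <- factor(rlang::eval_tidy(group, x))
    if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
    y <- v[g == levels(g)[2L]]
    x <- v[g == levels(g)[1L]]
  }
  if (length(x) == 0L || length(y) == 0L) abort("Empty group.")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(m)]) - m * (m + 1) / 2    # pairs where x beats y
  u2 <- m * n - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties) {
    p <- mw_exact_p_from_u(u, m, n, alternative)
    exact <- TRUE
  } else {
    warn("Ties present; using midranks and a normal approximation.")
    mu <- m * n / 2
    tie_tab <- table(c(x, y))
    N <- m + n
    sig2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (u - mu) / sqrt(sig2)
    p <- switch(match.arg(alternative, c("two.sided", "less", "greater")),
                "two.sided" = 2 * stats::pnorm(-abs(z)),
                "less" = stats::pnorm(z),
                "greater" = stats::pnorm(-z))
    exact <- FALSE
  }
  structure(list(u = u, u1 = u1, u2 = u2, m = m, n = n,
                 p_value = p, exact = exact, alternative = alternative),
            class = "mw_exact")
}

#' @export
print.mw_exact <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s)\n",
              if (x$exact) "exact" else "normal approx., ties"))
  cat(sprintf("  U = %g (U1 = %g, U2 = %g), N1 = %d, N2 = %d, p = %.5g\n",
              x$u, x$u1, x$u2, x$m, x$n, x$p_value))
  invisible(x)
}

#' Quasibinomial GLM with an F-test for a group effect
#'
#' Fits a binomial-family GLM with logit link by iteratively reweighted
#' least squares, estimates the dispersion as the Pearson chi-square of the
#' full model divided by its residual degrees of freedom, and tests the
#' group effect against the intercept-only model with
#' `F = (deviance reduction / df1) / dispersion` on `(df1, df2)` degrees of
#' freedom. This is the standard analysis for overdispersed proportions
#' such as per-bird identified-song fractions.
#'
#' @param data Data frame of per-individual proportions.
#' @param successes,totals,group Unquoted column names: success count,
#'   trial count, grouping factor (>= 2 levels).
#' @param max_iter,tol IRLS controls (relative deviance change).
#' @return A `quasibinom_f` object: list with `coefficients`, `f_statistic`,
#'   `df1`, `df2`, `p_value`, `dispersion`, `deviance`, `null_deviance`,
#'   `fitted`. Supports [tidy()] and [glance()].
#' @export
quasibinomial_glm_f <- function(data, successes, totals, group,
                                max_iter = 100L, tol = 1e-10) {
  s <- rlang::eval_tidy(rlang::enquo(successes), data)
  t_ <- rlang::eval_tidy(rlang::enquo(totals), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (any(s < 0 | s > t_)) abort("Need 0 <= successes <= totals.")
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (length(s) < 2L) abort("Need at least two individuals.")
  X_full <- stats::model.matrix(~g)
  X_null <- matrix(1, nrow = length(s))
  fit <- function(X) irls_binomial(X, s / t_, t_, max_iter, tol)
  full <- fit(X_full)
  null <- fit(X_null)
  if (any(full$fitted < 1e-8 | full$fitted > 1 - 1e-8)) {
    warn("Fitted probabilities on the boundary (separation).")
  }
  df1 <- ncol(X_full) - 1L
  df2 <- length(s) - ncol(X_full)
  pearson <- sum((s - t_ * full$fitted)^2 /
                   pmax(t_ * full$fitted * (1 - full$fitted), 1e-12))
  dispersion <- pearson / df2
  drop_dev <- null$deviance - full$deviance
  f_stat <- if (dispersion <= 1e-12) {
    if (drop_dev <= 1e-10) 0 else Inf     # perfect fit in both models
  } else {
    (drop_dev / df1) / dispersion
  }
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  coefs <- stats::setNames(full$beta, colnames(X_full))
  structure(list(coefficients = coefs, f_statistic = f_stat,
                 df1 = df1, df2 = df2, p_value = p,
                 dispersion = dispersion, deviance = full$deviance,
                 null_deviance = null$deviance, fitted = full$fitted,
                 converged = full$converged, groups = levels(g)),
            class = "quasibinom_f")
}

# IRLS for a binomial GLM with logit link; y are proportions, w trial counts.
irls_binomial <- function(X, y, w, max_iter, tol) {
  beta <- numeric(ncol(X))
  p0 <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
  beta[1L] <- log(p0 / (1 - p0))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * W)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    dev <- binomial_deviance(y, mu, w)
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged && max_iter > 1L) {
    # one more deviance evaluation for reporting
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-10), 1 - 1e-10)
    dev <- binomial_deviance(y, mu, w)
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-10), 1 - 1e-10)
  list(beta = beta, fitted = mu, deviance = binomial_deviance(y, mu, w),
       converged = converged)
}

binomial_deviance <- function(y, mu, w) {
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  2 * sum(w * (term(y, mu) + term(1 - y, 1 - mu)))
}

#' @export
print.quasibinom_f <- function(x, ...) {
  cat("Quasibinomial GLM (logit link), F-test for group effect\n")
  cat(sprintf("  F = %.3f on (%d, %d) df, p = %.4g, dispersion = %.3f\n",
              x$f_statistic, x$df1, x$df2, x$p_value, x$dispersion))
  invisible(x)
}
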