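#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname mann_whitney_exact
#' @param x An `mw_exact` object.
#' @param ... Unused.
#' @export
tidy.mw_exact <- function(x, ...) {
  tibble(statistic = x$u, u1 = x$u1, u2 = x$u2,
         p.value = x$p_value, method = if (x$exact) "exact" else "normal",
         alternative = x$alternative)
}

#' @rdname mann_whitney_exact
#' @export
glance.mw_exact <- function(x, ...) {
  tibble(n1 = x$m, n2 = x$n, statistic = x$u, p.value = x$p_value,
         exact = x$exact)
}

#' @rdname quasibinomial_glm_f
#' @param x A `quasibinom_f` object.
#' @param ... Unused.
#' @export
tidy.quasibinom_f <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname quasibinomial_glm_f
#' @export
glance.quasibinom_f <- function(x, ...) {
  tibble(statistic = x$f_statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p_value, dispersion = x$dispersion,
         deviance = x$deviance, null.deviance = x$null_deviance,
         converged = x$converged)
}

#' @rdname posterior_hybrid_class
#' @param x A `hybrid_posterior` object.
#' @param ... Unused.
#' @export
tidy.hybrid_posterior <- function(x, ...) {
  tibble(class = names(x$posterior), posterior = unname(x$posterior),
         log_likelihood = unname(x$log_likelihood[names(x$posterior)]))
}
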