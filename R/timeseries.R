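#' Polynomial trend test on an annual score series
#'
#' Ordinary least squares of the outcome on centered year powers
#' `(year - mean(year))^k`, `k = 1..degree`, fitted jointly. The
#' reported trend coefficient is the highest-order term; inference
#' uses the t distribution with `n - degree - 1` residual degrees of
#' freedom. Centering makes the coefficients invariant to shifting
#' the year origin; with only eight annual observations no
#' autocorrelation correction is attempted.
#'
#' @param panel An `annual_panel` (rows with a missing outcome are
#'   dropped).
#' @param outcome `"sas"` (default) or `"med"`.
#' @param degree Polynomial degree (2 = quadratic, 3 = cubic).
#' @return A `trend_fit`: `degree`, `coefficients` (term, estimate,
#'   se, t, p), `trend_beta`, `trend_p`, `r_squared`, `year_center`,
#'   `n`.
#' @export
polynomial_trend <- function(panel, outcome = c("sas", "med"), degree = 2L) {
  outcome <- match.arg(outcome)
  degree <- as.integer(degree)
  stopifnot(degree >= 1L)
  y <- panel[[outcome]]
  keep <- !is.na(y)
  y <- y[keep]
  yr <- panel$year[keep]
  n <- length(y)
  if (n < degree + 2L) {
    stop("polynomial trend of degree ", degree, " needs at least ",
         degree + 2L, " years; got ", n)
  }
  ctr <- mean(yr)
  x <- yr - ctr
  X <- vapply(0:degree, function(k) x^k, numeric(n))
  colnames(X) <- c("(Intercept)", paste0("year^", seq_len(degree)))
  fit <- fit_ols(y, X)
  structure(list(
    degree = degree, outcome = outcome,
    coefficients = data.table::data.table(
      term = colnames(X), estimate = fit$coefficients, se = fit$se,
      t = fit$t, p = fit$p),
    trend_beta = unname(fit$coefficients[degree + 1L]),
    trend_p = unname(fit$p[degree + 1L]),
    r_squared = fit$r_squared, year_center = ctr, n = n),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Degree-%d trend in %s (n = %d years, centered at %.1f)\n",
              x$degree, x$outcome, x$n, x$year_center))
  print(x$coefficients, digits = 4)
  cat(sprintf("trend beta = %.5g (p = %.4g), R^2 = %.3f\n",
              x$trend_beta, x$trend_p, x$r_squared))
  invisible(x)
}
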