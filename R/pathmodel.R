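#' Ordinary least squares with classical inference
#'
#' Shared estimator for every path equation. Exact least-squares
#' solution via the QR decomposition, classical (homoskedastic)
#' standard errors, t statistics and two-sided p values.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @return An `ols_fit`: `coefficients`, `se`, `t`, `p`, `r_squared`,
#'   `sigma2`, `df_residual`, `vcov`, `fitted`, `residuals`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more rows (", n, ") than columns (", p, ")")
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot),
                                 drop = FALSE]
  vc <- sigma2 * XtX_inv
  se <- sqrt(diag(vc))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 t = stats::setNames(tval, colnames(X)),
                 p = stats::setNames(pval, colnames(X)),
                 r_squared = r2, sigma2 = sigma2, df_residual = df,
                 vcov = vc, fitted = fitted, residuals = res),
            class = "ols_fit")
}

# run fn with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# closed-form a (M ~ 1 + X) and b (coef of M in Y ~ 1 + X + M) from sums;
# returns c(a, b) or NULL when the resample is degenerate
.ab_closed_form <- function(x, m, y) {
  sxx <- stats::var(x)
  if (!is.finite(sxx) || sxx == 0) return(NULL)
  sxm <- stats::cov(x, m)
  smm <- stats::var(m)
  smy <- stats::cov(m, y)
  sxy <- stats::cov(x, y)
  den <- smm * sxx - sxm^2
  if (!is.finite(den) || den <= 0) return(NULL)
  a <- sxm / sxx
  b <- (smy * sxx - sxy * sxm) / den
  c(a, b)
}

#' Single-mediator mediation analysis with percentile bootstrap
#'
#' Three OLS equations on the same sample: total effect `Y ~ X`
#' (coefficient `c`), first stage `M ~ X` (`a`), and `Y ~ X + M`
#' (direct effect `c_prime` and `b`). The indirect effect is `a * b`,
#' and `c = c_prime + a * b` holds exactly for this single-mediator
#' linear model. The bootstrap resamples rows with replacement and
#' takes percentile quantiles of `a * b`; degenerate resamples
#' (constant X or collinear X, M) are redrawn and counted.
#'
#' @param data An `annual_panel` or data.frame.
#' @param x,m,y Column names of exposure, mediator, outcome.
#' @param B Bootstrap resamples (default 5000; 0 disables the
#'   bootstrap; fewer than 1000 triggers a warning since reported CIs
#'   assume B >= 1000).
#' @param seed RNG seed, required when `B > 0`.
#' @param conf.level CI level (default 0.95).
#' @return A `mediation_result` with paths `a`, `b`, `c`, `c_prime`,
#'   `indirect`, the per-equation fits, and (when bootstrapped)
#'   `ci_indirect`, `boot_indirect`, `n_redraws`.
#' @export
mediate <- function(data, x = "policy", m = "med", y = "sas", B = 5000L,
                    seed = NULL, conf.level = 0.95) {
  d <- as.data.frame(data)[, c(x, m, y)]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < 4L) stop("mediation needs at least 4 complete rows; got ", n)
  if (n < 20L) {
    message("small-sample caution: n = ", n,
            " rows; estimates and bootstrap CIs are fragile")
  }
  xv <- as.numeric(d[[x]]); mv <- as.numeric(d[[m]]); yv <- as.numeric(d[[y]])
  one <- rep(1, n)
  fit_c <- fit_ols(yv, cbind("(Intercept)" = one, x = xv))
  fit_a <- fit_ols(mv, cbind("(Intercept)" = one, x = xv))
  fit_b <- fit_ols(yv, cbind("(Intercept)" = one, x = xv, m = mv))
  a <- unname(fit_a$coefficients["x"])
  b <- unname(fit_b$coefficients["m"])
  cc <- unname(fit_c$coefficients["x"])
  c_prime <- unname(fit_b$coefficients["x"])
  out <- list(n = n, x = x, m = m, y = y,
              a = a, b = b, c = cc, c_prime = c_prime, indirect = a * b,
              fit_total = fit_c, fit_m = fit_a, fit_y = fit_b,
              r_squared_m = fit_a$r_squared, r_squared_y = fit_b$r_squared,
              B = as.integer(B), seed = seed, conf.level = conf.level,
              ci_indirect = c(NA_real_, NA_real_), boot_indirect = NULL,
              n_redraws = 0L)
  class(out) <- "mediation_result"
  if (B > 0L) {
    if (is.null(seed)) stop("seed is required when bootstrapping")
    if (B < 1000L) {
      warning("B = ", B, " < 1000; bootstrap CI is for exploration only")
    }
    boot <- .with_seed(seed, function() {
      est <- numeric(B)
      redraws <- 0L
      for (i in seq_len(B)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          ab <- .ab_closed_form(xv[idx], mv[idx], yv[idx])
          if (!is.null(ab)) break
          redraws <- redraws + 1L
        }
        est[i] <- ab[1] * ab[2]
      }
      list(est = est, redraws = redraws)
    })
    if (boot$redraws > 0L) {
      message(boot$redraws, " degenerate bootstrap resample(s) redrawn")
    }
    g <- (1 - conf.level) / 2
    out$ci_indirect <- unname(stats::quantile(boot$est, c(g, 1 - g)))
    out$boot_indirect <- boot$est
    out$n_redraws <- boot$redraws
  }
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation of %s -> %s through %s (n = %d)\n",
              x$x, x$y, x$m, x$n))
  cat(sprintf("  total effect   c  = %.5g (t = %.3f, p = %.4g)\n",
              x$c, x$fit_total$t["x"], x$fit_total$p["x"]))
  cat(sprintf("  first stage    a  = %.5g (p = %.4g)\n",
              x$a, x$fit_m$p["x"]))
  cat(sprintf("  second stage   b  = %.5g (p = %.4g)\n",
              x$b, x$fit_y$p["m"]))
  cat(sprintf("  direct effect  c' = %.5g (p = %.4g)\n",
              x$c_prime, x$fit_y$p["x"]))
  cat(sprintf("  indirect     a*b  = %.5g", x$indirect))
  if (!is.na(x$ci_indirect[1])) {
    cat(sprintf(", %d%% percentile CI [%.5g, %.5g] (B = %d)",
                round(100 * x$conf.level), x$ci_indirect[1],
                x$ci_indirect[2], x$B))
  }
  cat("\n")
  invisible(x)
}

#' First-stage moderated mediation
#'
#' First-stage model `M = i1 + a1*X + a2*W + a3*(X*W)` (W mean-centered
#' by default) with the outcome equation `Y = i2 + c'X + b*M`. Reports
#' the interaction `a3`, conditional first-stage effects
#' `a1 + a3*w` and conditional indirect effects `(a1 + a3*w) * b` at
#' `w = mean - SD, mean, mean + SD` of the moderator, and the index of
#' moderated mediation `a3 * b` with a percentile-bootstrap CI.
#'
#' @inheritParams mediate
#' @param w Moderator column name (must have nonzero variance).
#' @param center_w Mean-center W before forming the product term
#'   (default `TRUE`; set `FALSE` to reproduce raw-scale coefficient
#'   conventions).
#' @return A `moderated_mediation_result`.
#' @export
moderated_mediation <- function(data, x = "policy", m = "med", y = "sas",
                                w = "support_ratio", B = 5000L, seed = NULL,
                                conf.level = 0.95, center_w = TRUE) {
  d <- as.data.frame(data)[, c(x, m, y, w)]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < 5L) stop("moderated mediation needs at least 5 complete rows")
  if (n < 20L) {
    message("small-sample caution: n = ", n,
            " rows; estimates and bootstrap CIs are fragile")
  }
  xv <- as.numeric(d[[x]]); mv <- as.numeric(d[[m]])
  yv <- as.numeric(d[[y]]); wv <- as.numeric(d[[w]])
  if (stats::var(wv) == 0) stop("moderator has zero variance")
  w_mean <- if (center_w) mean(wv) else 0
  wc <- wv - w_mean
  one <- rep(1, n)
  Xm <- cbind("(Intercept)" = one, x = xv, w = wc, `x:w` = xv * wc)
  fit_m <- fit_ols(mv, Xm)
  fit_y <- fit_ols(yv, cbind("(Intercept)" = one, x = xv, m = mv))
  a1 <- unname(fit_m$coefficients["x"])
  a2 <- unname(fit_m$coefficients["w"])
  a3 <- unname(fit_m$coefficients["x:w"])
  b <- unname(fit_y$coefficients["m"])
  c_prime <- unname(fit_y$coefficients["x"])
  sd_w <- stats::sd(wv)
  w_levels <- c(-sd_w, 0, sd_w)
  cond <- data.table::data.table(
    w_centered = w_levels,
    w_raw = w_levels + w_mean,
    a_conditional = a1 + a3 * w_levels,
    indirect_conditional = (a1 + a3 * w_levels) * b)
  out <- list(n = n, x = x, m = m, y = y, w = w,
              center_w = center_w, w_mean = w_mean, sd_w = sd_w,
              a1 = a1, a2 = a2, a3 = a3, b = b, c_prime = c_prime,
              fit_m = fit_m, fit_y = fit_y,
              conditional = cond,
              index = a3 * b,
              B = as.integer(B), seed = seed, conf.level = conf.level,
              ci_index = c(NA_real_, NA_real_), boot_index = NULL,
              n_redraws = 0L)
  class(out) <- "moderated_mediation_result"
  if (B > 0L) {
    if (is.null(seed)) stop("seed is required when bootstrapping")
    if (B < 1000L) {
      warning("B = ", B, " < 1000; bootstrap CI is for exploration only")
    }
    boot <- .with_seed(seed, function() {
      est <- numeric(B)
      redraws <- 0L
      for (i in seq_len(B)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          Xi <- Xm[idx, , drop = FALSE]
          fm <- stats::.lm.fit(Xi, mv[idx])
          if (fm$rank < ncol(Xi)) { redraws <- redraws + 1L; next }
          Yi <- cbind(1, xv[idx], mv[idx])
          fy <- stats::.lm.fit(Yi, yv[idx])
          if (fy$rank < 3L) { redraws <- redraws + 1L; next }
          break
        }
        est[i] <- fm$coefficients[4L] * fy$coefficients[3L]
      }
      list(est = est, redraws = redraws)
    })
    if (boot$redraws > 0L) {
      message(boot$redraws, " degenerate bootstrap resample(s) redrawn")
    }
    g <- (1 - conf.level) / 2
    out$ci_index <- unname(stats::quantile(boot$est, c(g, 1 - g)))
    out$boot_index <- boot$est
    out$n_redraws <- boot$redraws
  }
  out
}

#' @export
print.moderated_mediation_result <- function(x, ...) {
  cat(sprintf("First-stage moderated mediation: %s -> %s -> %s, moderator %s (n = %d)\n",
              x$x, x$m, x$y, x$w, x$n))
  cat(sprintf("  a1 = %.5g, a2 = %.5g, a3 (interaction) = %.5g (p = %.4g)\n",
              x$a1, x$a2, x$a3, x$fit_m$p["x:w"]))
  cat(sprintf("  b = %.5g, c' = %.5g\n", x$b, x$c_prime))
  cat("  conditional indirect effects:\n")
  print(x$conditional, digits = 4)
  cat(sprintf("  index of moderated mediation a3*b = %.5g", x$index))
  if (!is.na(x$ci_index[1])) {
    cat(sprintf(", %d%% percentile CI [%.5g, %.5g] (B = %d)",
                round(100 * x$conf.level), x$ci_index[1], x$ci_index[2],
                x$B))
  }
  cat("\n")
  invisible(x)
}

#' Simple-slopes probe of the first-stage interaction
#'
#' Conditional effect of X on M at chosen moderator values:
#' `a1 + a3*w`, with standard error
#' `sqrt(var(a1) + w^2 var(a3) + 2w cov(a1, a3))` from the first-stage
#' coefficient covariance and t inference on that fit's residual
#' degrees of freedom. `w` is interpreted on the coding used in the
#' fit (centered when `center_w = TRUE`).
#'
#' @param mm A `moderated_mediation_result`.
#' @param w_levels Moderator values (centered scale if the model
#'   centered W); defaults to mean -SD, mean, mean +SD.
#' @return `data.table` with `w`, `effect`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(mm, w_levels = NULL) {
  stopifnot(inherits(mm, "moderated_mediation_result"))
  if (is.null(w_levels)) w_levels <- mm$conditional$w_centered
  vc <- mm$fit_m$vcov
  v11 <- vc["x", "x"]; v33 <- vc["x:w", "x:w"]; v13 <- vc["x", "x:w"]
  eff <- mm$a1 + mm$a3 * w_levels
  se <- sqrt(v11 + w_levels^2 * v33 + 2 * w_levels * v13)
  tval <- eff / se
  df <- mm$fit_m$df_residual
  data.table::data.table(
    w = w_levels, effect = eff, se = se, t = tval,
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}
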