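#' Cronbach's alpha with a Feldt confidence interval
#'
#' Treats the raters as parallel measurements of the items:
#' `alpha = K/(K-1) * (1 - sum_j var_j / var_total)` where `var_j` is
#' the across-item variance of rater `j` and `var_total` the variance
#' of the item totals. The confidence interval uses Feldt's
#' F-distribution method: `(1 - alpha)` is scaled by F quantiles with
#' `n - 1` and `(n - 1)(K - 1)` degrees of freedom.
#'
#' @param ratings Numeric matrix, items in rows, raters in columns.
#'   At least 3 items, 2 raters, no missing cells.
#' @param conf.level Confidence level (default 0.95).
#' @return List of class `cronbach_alpha`: `alpha`, `ci` (length-2),
#'   `n_items`, `n_raters`, `conf.level`. With zero total variance
#'   alpha is undefined and reported as `NA`.
#' @export
cronbach_alpha <- function(ratings, conf.level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("at least two raters required")
  if (n < 3L) stop("at least three items required")
  if (anyNA(ratings)) stop("missing cells not supported")
  var_total <- stats::var(rowSums(ratings))
  out <- list(alpha = NA_real_, ci = c(NA_real_, NA_real_),
              n_items = n, n_raters = k, conf.level = conf.level)
  class(out) <- "cronbach_alpha"
  if (var_total == 0) {
    warning("zero total variance: alpha undefined")
    return(out)
  }
  var_j <- apply(ratings, 2L, stats::var)
  alpha <- k / (k - 1) * (1 - sum(var_j) / var_total)
  g <- 1 - conf.level
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  lower <- 1 - (1 - alpha) * stats::qf(1 - g / 2, df1, df2)
  upper <- 1 - (1 - alpha) * stats::qf(g / 2, df1, df2)
  out$alpha <- alpha
  out$ci <- c(lower, upper)
  out
}

#' @export
print.cronbach_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha: %.3f, %d%% CI: %.3f-%.3f (%d items, %d raters)\n",
              x$alpha, round(100 * x$conf.level), x$ci[1], x$ci[2],
              x$n_items, x$n_raters))
  invisible(x)
}

# shared aggregation for the two annual scores
.annual_score <- function(records, lexicon, value_col, weighting) {
  stopifnot(inherits(records, "collocate_records"))
  scores <- lexicon_scores(lexicon)
  retained <- NULL
  kept <- records$records[retained == TRUE]
  x <- merge(kept, scores, by = "word")
  if (nrow(x) < nrow(kept)) {
    stop("retained collocate(s) without lexicon rating: ",
         paste(setdiff(kept$word, x$word), collapse = ", "))
  }
  year <- f_near <- NULL
  if (weighting == "type") {
    out <- x[, .(score = mean(.SD[[value_col]]), n_collocates = .N),
             by = year, .SDcols = value_col]
  } else {
    out <- x[, .(score = sum(.SD[[value_col]] * f_near) / sum(f_near),
                 n_collocates = .N),
             by = year, .SDcols = value_col]
  }
  # years seen in the corpus but with nothing retained -> NA, with warning
  all_years <- sort(unique(records$records$year))
  missing_years <- setdiff(all_years, out$year)
  if (length(missing_years)) {
    warning("no retained collocates in year(s) ",
            paste(missing_years, collapse = ", "), "; score set to NA")
    out <- rbind(out, data.table::data.table(
      year = missing_years, score = NA_real_, n_collocates = 0L))
  }
  data.table::setorder(out, year)
  out[]
}

#' Annual Societal Age Stereotype (SAS) score
#'
#' Mean rater sentiment (1-5) over the year's retained collocates.
#' Type weighting (default) counts each retained collocate once;
#' token weighting weights each word by its in-span frequency
#' `F_near`.
#'
#' @param records A `collocate_records` object.
#' @param lexicon The `rating_lexicon` used for filtering.
#' @param weighting `"type"` or `"token"`.
#' @return `data.table` with `year`, `sas`, `n_collocates`; SAS lies
#'   in \[1, 5\] wherever defined.
#' @export
annual_sas <- function(records, lexicon, weighting = c("type", "token")) {
  weighting <- match.arg(weighting)
  out <- .annual_score(records, lexicon, "sentiment", weighting)
  data.table::setnames(out, "score", "sas")
  out
}

#' Annual Medicalization-of-Aging score
#'
#' Mean per-word medical value (mean of 0/1 rater flags, so
#' disagreement contributes 0.5) over the year's retained collocates,
#' i.e. the proportion of the year's collocate set that is
#' physical-health vocabulary. Proportion rather than count keeps the
#' mediator scale-free across years with different collocate yields.
#'
#' @inheritParams annual_sas
#' @return `data.table` with `year`, `med` in \[0, 1\], `n_collocates`.
#' @export
annual_medicalization <- function(records, lexicon,
                                  weighting = c("type", "token")) {
  weighting <- match.arg(weighting)
  out <- .annual_score(records, lexicon, "medical", weighting)
  data.table::setnames(out, "score", "med")
  out
}

#' Assemble the annual analysis panel
#'
#' One row per year: SAS, medicalization, collocate count, the policy
#' indicator (0 before `policy_year`, 1 from `policy_year` on) and the
#' old-age support ratio (working-age adults aged 20-64 per person
#' 65+).
#'
#' @param sas Output of [annual_sas()].
#' @param med Output of [annual_medicalization()].
#' @param covariates data.frame with `year` and `support_ratio`
#'   (optionally `policy_indicator`, checked for consistency if
#'   `policy_year` is also given). Must cover every scored year.
#' @param policy_year First year with the policy indicator on. If
#'   `NULL`, the covariate table's `policy_indicator` is used.
#' @return An `annual_panel` data.table: `year`, `sas`, `med`,
#'   `n_collocates`, `policy`, `support_ratio`.
#' @export
build_panel <- function(sas, med, covariates, policy_year = NULL) {
  x <- merge(data.table::as.data.table(sas),
             data.table::as.data.table(med)[, c("year", "med"), with = FALSE],
             by = "year")
  cov <- data.table::as.data.table(covariates)
  if (!"year" %in% names(cov) || !"support_ratio" %in% names(cov)) {
    stop("covariates need 'year' and 'support_ratio' columns")
  }
  uncovered <- setdiff(x$year, cov$year)
  if (length(uncovered)) {
    stop("covariates missing for year(s): ",
         paste(uncovered, collapse = ", "))
  }
  x <- merge(x, cov, by = "year")
  if (!is.null(policy_year)) {
    policy <- as.integer(x$year >= policy_year)
    if ("policy_indicator" %in% names(cov) &&
        !identical(policy, as.integer(x$policy_indicator))) {
      warning("covariate policy_indicator disagrees with policy_year ",
              policy_year, "; policy_year takes precedence")
    }
    x$policy <- policy
  } else if ("policy_indicator" %in% names(cov)) {
    x$policy <- as.integer(x$policy_indicator)
  } else {
    stop("either policy_year or a policy_indicator column is required")
  }
  out <- x[, c("year", "sas", "med", "n_collocates", "policy",
               "support_ratio"), with = FALSE]
  data.table::setorder(out, year)
  as_annual_panel(out)
}

#' Validate and class an annual panel
#'
#' @param x data.frame with columns `year`, `sas`, `med`, `policy`,
#'   `support_ratio` (and optionally `n_collocates`).
#' @param strict Enforce the measurement-scale ranges `sas` in
#'   \[1, 5\] and `med` in \[0, 1\]. Synthetic score-level panels from
#'   [generate_panel()] live on an unconstrained scale and use
#'   `strict = FALSE`.
#' @return An `annual_panel` data.table.
#' @export
as_annual_panel <- function(x, strict = TRUE) {
  x <- data.table::as.data.table(x)
  need <- c("year", "sas", "med", "policy", "support_ratio")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$year)) stop("duplicate years in panel")
  data.table::setorder(x, year)
  if (is.unsorted(x$policy)) {
    stop("policy indicator must be non-decreasing in year")
  }
  if (strict) {
    ok_sas <- is.na(x$sas) | (x$sas >= 1 & x$sas <= 5)
    ok_med <- is.na(x$med) | (x$med >= 0 & x$med <= 1)
    if (!all(ok_sas)) stop("sas outside [1, 5]")
    if (!all(ok_med)) stop("med outside [0, 1]")
    if (any(x$support_ratio <= 0, na.rm = TRUE)) {
      stop("support_ratio must be positive")
    }
  }
  data.table::setattr(x, "class",
                      c("annual_panel", class(data.table::data.table())))
  x[]
}

#' Read / write the annual panel TSV
#'
#' The panel TSV is the contract between the measurement half
#' (corpus to scores) and the inference half (trend and path models).
#'
#' @param path File path.
#' @export
read_panel <- function(path) {
  as_annual_panel(data.table::fread(path, sep = "\t"))
}

#' @rdname read_panel
#' @param panel An `annual_panel`.
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(panel, path, sep = "\t")
  invisible(path)
}
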