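#' Run the measurement and inference chain on in-memory objects
#'
#' The computational core shared by [run_pipeline()] and the
#' end-to-end tests: corpus -> tokens -> collocation counts -> MI ->
#' lexicon filter -> annual scores -> panel -> trend and path models.
#'
#' @param corpus A `corpus`.
#' @param lexicon A `rating_lexicon`.
#' @param covariates data.frame with `year`, `support_ratio` (and
#'   optionally `policy_indicator`).
#' @param node_words Node word set.
#' @param span Span positions per side.
#' @param mi_threshold MI retention threshold (bits, inclusive).
#' @param policy_year First policy-on year.
#' @param weighting `"type"` or `"token"` collocate weighting.
#' @param stopword_policy Passed to [count_collocates()].
#' @param trend_degrees Polynomial degrees to fit on the SAS series.
#' @param B,seed Bootstrap settings for the path models (`B = 0`
#'   gives point estimates only).
#' @param run_pathmodels Fit mediation / moderated mediation (needs
#'   enough complete years).
#' @return List with `counts`, `mi`, `records`, `sas`, `med`,
#'   `panel`, `trends`, `mediation`, `moderated`, `alpha`
#'   (inter-rater reliability of the sentiment ratings over retained
#'   words).
#' @export
analyze_corpus <- function(corpus, lexicon, covariates,
                           node_words = "elderly", span = 6L,
                           mi_threshold = 1.5, policy_year = 2014L,
                           weighting = c("type", "token"),
                           stopword_policy = c("consume", "skip"),
                           trend_degrees = c(2L, 3L), B = 0L, seed = NULL,
                           run_pathmodels = TRUE) {
  weighting <- match.arg(weighting)
  stopword_policy <- match.arg(stopword_policy)
  tokens <- tokenize_corpus(corpus)
  counts <- count_collocates(tokens, node_words, span = span,
                             stopword_policy = stopword_policy)
  mi <- mutual_information(counts)
  records <- filter_collocates(mi, lexicon, threshold = mi_threshold)
  sas <- annual_sas(records, lexicon, weighting = weighting)
  med <- annual_medicalization(records, lexicon, weighting = weighting)
  panel <- build_panel(sas, med, covariates, policy_year = policy_year)

  retained_words <- unique(records$records$word[records$records$retained])
  alpha <- NULL
  s_cols <- grep("^s_rater", names(lexicon), value = TRUE)
  rated <- lexicon[lexicon$word %in% retained_words, s_cols, with = FALSE]
  if (nrow(rated) >= 3L) {
    alpha <- cronbach_alpha(as.matrix(rated))
  }

  trends <- lapply(trend_degrees, function(d) {
    n_ok <- sum(!is.na(panel$sas))
    if (n_ok >= d + 2L) polynomial_trend(panel, "sas", d) else NULL
  })
  names(trends) <- paste0("degree", trend_degrees)

  mediation <- moderated <- NULL
  if (run_pathmodels) {
    ok <- stats::complete.cases(panel[, c("policy", "med", "sas")])
    if (sum(ok) >= 4L) {
      mediation <- suppressMessages(
        mediate(panel, "policy", "med", "sas", B = B, seed = seed))
    }
    okw <- stats::complete.cases(
      panel[, c("policy", "med", "sas", "support_ratio")])
    if (sum(okw) >= 5L) {
      moderated <- suppressMessages(
        moderated_mediation(panel, "policy", "med", "sas", "support_ratio",
                            B = B, seed = seed))
    }
  }
  list(counts = counts, mi = mi, records = records, sas = sas, med = med,
       panel = panel, trends = trends, mediation = mediation,
       moderated = moderated, alpha = alpha)
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML or JSON file (by extension) or a list. Required
#' fields: `manifest` (or `corpus_jsonl`), `lexicon`, `covariates`,
#' `out_dir`. Optional fields with defaults: `node_words`
#' ("elderly"), `span` (6), `mi_threshold` (1.5), `policy_year`
#' (2014), `weighting` ("type"), `stopword_policy` ("consume"),
#' `trend_degrees` (2, 3), `boot_B` (5000), `seed` (required when
#' `boot_B > 0`). All referenced paths must resolve at validation
#' time, before any computation.
#'
#' @param config Path or list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(node_words = "elderly", span = 6L, mi_threshold = 1.5,
                   policy_year = 2014L, weighting = "type",
                   stopword_policy = "consume", trend_degrees = c(2L, 3L),
                   boot_B = 5000L, seed = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  has_manifest <- !is.null(config$manifest)
  has_jsonl <- !is.null(config$corpus_jsonl)
  if (!has_manifest && !has_jsonl) {
    stop("config needs 'manifest' or 'corpus_jsonl'")
  }
  for (nm in c(if (has_manifest) "manifest" else "corpus_jsonl",
               "lexicon", "covariates")) {
    if (is.null(config[[nm]])) stop("config missing required field: ", nm)
    if (!file.exists(config[[nm]])) {
      stop("config field '", nm, "' points to a missing file: ",
           config[[nm]])
    }
  }
  if (is.null(config$out_dir)) stop("config missing required field: out_dir")
  if (config$boot_B > 0 && is.null(config$seed)) {
    stop("seed is required when boot_B > 0")
  }
  structure(config, class = "pipeline_config")
}

.trend_to_list <- function(tr) {
  if (is.null(tr)) return(NULL)
  list(degree = tr$degree, outcome = tr$outcome,
       coefficients = as.data.frame(tr$coefficients),
       trend_beta = tr$trend_beta, trend_p = tr$trend_p,
       r_squared = tr$r_squared, year_center = tr$year_center, n = tr$n)
}

.ols_to_list <- function(fit) {
  list(term = names(fit$coefficients),
       estimate = unname(fit$coefficients), se = unname(fit$se),
       t = unname(fit$t), p = unname(fit$p), r_squared = fit$r_squared)
}

.mediation_to_list <- function(md) {
  if (is.null(md)) return(NULL)
  list(n = md$n, a = md$a, b = md$b, c = md$c, c_prime = md$c_prime,
       indirect = md$indirect,
       ci_indirect = md$ci_indirect, B = md$B, seed = md$seed,
       conf_level = md$conf.level, n_redraws = md$n_redraws,
       equation_total = .ols_to_list(md$fit_total),
       equation_m = .ols_to_list(md$fit_m),
       equation_y = .ols_to_list(md$fit_y))
}

.moderated_to_list <- function(mm) {
  if (is.null(mm)) return(NULL)
  list(n = mm$n, center_w = mm$center_w, w_mean = mm$w_mean, sd_w = mm$sd_w,
       a1 = mm$a1, a2 = mm$a2, a3 = mm$a3, b = mm$b, c_prime = mm$c_prime,
       index = mm$index, ci_index = mm$ci_index, B = mm$B, seed = mm$seed,
       conf_level = mm$conf.level, n_redraws = mm$n_redraws,
       conditional = as.data.frame(mm$conditional),
       simple_slopes = as.data.frame(simple_slopes(mm)),
       equation_m = .ols_to_list(mm$fit_m),
       equation_y = .ols_to_list(mm$fit_y))
}

.write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE, null = "null")
}

#' Run the full pipeline from files to a result bundle
#'
#' Reads the corpus, lexicon and covariates named in the config,
#' runs [analyze_corpus()], and writes `collocates.tsv`,
#' `needs_rating.tsv`, `panel.tsv`, `trend.json`, `mediation.json`,
#' `moderated_mediation.json`, and `run_log.json` (recording every
#' threshold, seed, and the package version) to `out_dir`. Reruns
#' with an identical config rewrite byte-identical reports.
#'
#' @param config Path, list, or `pipeline_config`.
#' @return The in-memory result bundle from [analyze_corpus()],
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  cf <- pipeline_config(config)
  corpus <- if (!is.null(cf$manifest)) {
    read_corpus(cf$manifest)
  } else {
    read_corpus_jsonl(cf$corpus_jsonl)
  }
  lexicon <- read_lexicon(cf$lexicon)
  covariates <- data.table::fread(cf$covariates, sep = "\t")
  res <- analyze_corpus(
    corpus, lexicon, covariates,
    node_words = cf$node_words, span = cf$span,
    mi_threshold = cf$mi_threshold, policy_year = cf$policy_year,
    weighting = cf$weighting, stopword_policy = cf$stopword_policy,
    trend_degrees = cf$trend_degrees, B = cf$boot_B, seed = cf$seed)

  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cf$out_dir, f)
  write_collocates(res$records, out("collocates.tsv"),
                   out("needs_rating.tsv"))
  write_panel(res$panel, out("panel.tsv"))
  .write_report(lapply(res$trends, .trend_to_list), out("trend.json"))
  .write_report(.mediation_to_list(res$mediation), out("mediation.json"))
  .write_report(.moderated_to_list(res$moderated),
                out("moderated_mediation.json"))
  log <- list(
    package = "agestereo",
    version = as.character(utils::packageVersion("agestereo")),
    settings = cf[c("node_words", "span", "mi_threshold", "policy_year",
                    "weighting", "stopword_policy", "trend_degrees",
                    "boot_B", "seed")],
    inputs = cf[intersect(c("manifest", "corpus_jsonl", "lexicon",
                            "covariates"), names(cf))],
    n_documents = nrow(corpus),
    n_collocates_scored = nrow(res$records$records),
    n_collocates_retained = sum(res$records$records$retained),
    n_needs_rating = nrow(res$records$needs_rating))
  .write_report(log, out("run_log.json"))
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `run --config C` (full pipeline) and
#' `generate --out DIR [--seed S]` (write a synthetic corpus bundle).
#' Invoke as
#' `Rscript -e 'agestereo::agestereo_cli()' run --config config.yaml`.
#'
#' @param args Command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit-style integer status, invisibly.
#' @export
agestereo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: agestereo_cli run --config FILE | generate --out DIR [--seed S]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i[1] < length(rest)) rest[i[1] + 1L] else default
  }
  if (cmd == "run") {
    cfg <- getopt("--config")
    if (is.null(cfg)) stop("run needs --config FILE")
    run_pipeline(cfg)
  } else if (cmd == "generate") {
    outdir <- getopt("--out")
    if (is.null(outdir)) stop("generate needs --out DIR")
    seed <- as.integer(getopt("--seed", "1"))
    write_corpus(generate_corpus(corpus_gen_config(seed = seed)), outdir)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
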