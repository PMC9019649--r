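#' Configuration for the score-level panel generator
#'
#' The structural model is the one the path analysis estimates:
#' `X` a pre/post policy step, `W` a linearly declining support
#' ratio, `M = i1 + a1*X + a2*W + a3*X*W + e_M`,
#' `Y = i2 + c_prime*X + b*M + e_Y` with Gaussian noise. Defaults
#' mirror the study's shape: 8 years (2010-2017), policy step at
#' 2014, support ratio falling 7.4 to 5.1, a policy-driven rise in
#' the medical share of collocates (conditional first-stage effect of
#' about +0.04 to +0.07, stronger at lower support ratios), a
#' negative mediator-to-outcome slope, and no direct effect. Noise
#' SDs are small because each annual score aggregates hundreds of
#' collocates.
#'
#' @param n_years Number of years (>= 4).
#' @param start_year First calendar year.
#' @param policy_year First year with the policy on.
#' @param i1,a1,a2,a3 First-stage intercept and coefficients (W on
#'   its raw scale).
#' @param i2,b,c_prime Outcome-equation intercept and coefficients.
#' @param noise_m,noise_y Gaussian noise SDs (> 0).
#' @param support_start,support_end Support-ratio endpoints, linearly
#'   interpolated.
#' @param seed RNG seed.
#' @return A `panel_gen_config` list.
#' @export
panel_gen_config <- function(n_years = 8L, start_year = 2010L,
                             policy_year = 2014L,
                             i1 = 0.1, a1 = 0.225, a2 = 0.02, a3 = -0.03,
                             i2 = 3.9, b = -2, c_prime = 0,
                             noise_m = 0.005, noise_y = 0.01,
                             support_start = 7.4, support_end = 5.1,
                             seed = 1L) {
  stopifnot(n_years >= 4L, noise_m > 0, noise_y > 0)
  structure(as.list(environment()), class = "panel_gen_config")
}

#' Generate a synthetic annual panel with known path coefficients
#'
#' A pure function of `(config, seed)`: the same config yields the
#' same panel.
#'
#' @param config A [panel_gen_config()].
#' @return List with `panel` (an `annual_panel` on an unconstrained
#'   synthetic scale) and `truth` (the planted coefficients).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_gen_config"))
  cf <- config
  .with_seed(cf$seed, function() {
    years <- cf$start_year + seq_len(cf$n_years) - 1L
    x <- as.integer(years >= cf$policy_year)
    w <- seq(cf$support_start, cf$support_end, length.out = cf$n_years)
    m <- cf$i1 + cf$a1 * x + cf$a2 * w + cf$a3 * x * w +
      stats::rnorm(cf$n_years, 0, cf$noise_m)
    y <- cf$i2 + cf$c_prime * x + cf$b * m +
      stats::rnorm(cf$n_years, 0, cf$noise_y)
    panel <- as_annual_panel(data.table::data.table(
      year = years, sas = y, med = m, n_collocates = NA_integer_,
      policy = x, support_ratio = w), strict = FALSE)
    list(panel = panel,
         truth = cf[c("i1", "a1", "a2", "a3", "i2", "b", "c_prime",
                      "noise_m", "noise_y", "policy_year")])
  })
}

#' Default planted vocabulary for the corpus generator
#'
#' Words appearing only inside node-word windows, with a true
#' sentiment (1-5), a medical flag, and an association strength that
#' sets their relative sampling weight. The inventory mixes
#' physical-health vocabulary (negative sentiment) with positive and
#' neutral non-medical words, echoing the kinds of words raters see
#' in newspaper text about older adults.
#'
#' @return data.frame with columns `word`, `sentiment`, `medical`,
#'   `strength`.
#' @export
default_vocabulary <- function() {
  data.frame(
    word = c("sick", "dementia", "diabetic", "comorbidities", "illness",
             "rheumatism", "frail", "bedridden", "chronic", "ailing",
             "empowering", "hero", "venerable", "grateful", "special",
             "respected", "active", "wise", "pioneering", "contributing",
             "resident", "community", "programme", "neighbourhood"),
    sentiment = c(1L, 1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 2L,
                  5L, 5L, 5L, 4L, 4L, 5L, 4L, 5L, 5L, 4L,
                  3L, 3L, 3L, 3L),
    medical = c(rep(1L, 10), rep(0L, 14)),
    strength = rep(1, 24))
}

#' Configuration for the document-level corpus generator
#'
#' Documents are streams of background tokens (a Zipf-like frequency
#' list plus articles and stop words at fixed rates) with node-word
#' occurrences planted at `node_rate` per 1,000 tokens. Window
#' positions around each node occurrence are overwritten, with
#' probability `window_fill`, by vocabulary words sampled with
#' probability proportional to association strength; from
#' `policy_year` on, medical words' strengths are multiplied by
#' `medical_boost`, raising the medical share of collocates and,
#' through their low sentiment, lowering the SAS score. Planted
#' vocabulary words never occur in the background, so a word with
#' strength 0 never occurs at all.
#'
#' @param years Calendar years covered.
#' @param articles_per_year,tokens_per_article Corpus size knobs.
#' @param node_rate Node occurrences per 1,000 tokens. The expected
#'   per-year node count should be >= 20 so MI is estimable; a
#'   warning is raised otherwise.
#' @param node_word The planted node noun.
#' @param policy_year First boosted year.
#' @param medical_boost Multiplier (>= 1) on medical-word association
#'   strength from `policy_year` on; 1 means no regime shift.
#' @param window_fill Probability that a window slot is overwritten
#'   by a vocabulary word.
#' @param vocabulary data.frame as [default_vocabulary()].
#' @param background_vocab_size Zipf background vocabulary size.
#' @param article_rate,stopword_rate Background rates of articles and
#'   non-article stop words.
#' @param mean_sentence_len Mean sentence length in tokens.
#' @param seed RNG seed.
#' @return A `corpus_gen_config` list.
#' @export
corpus_gen_config <- function(years = 2010:2017, articles_per_year = 25L,
                              tokens_per_article = 150L, node_rate = 8,
                              node_word = "elderly", policy_year = 2014L,
                              medical_boost = 3, window_fill = 0.6,
                              vocabulary = default_vocabulary(),
                              background_vocab_size = 400L,
                              article_rate = 0.08, stopword_rate = 0.22,
                              mean_sentence_len = 12, seed = 1L) {
  stopifnot(all(vocabulary$strength >= 0), medical_boost > 0,
            window_fill >= 0, window_fill <= 1, node_rate > 0)
  exp_node <- articles_per_year * tokens_per_article * node_rate / 1000
  if (exp_node < 20) {
    warning("expected node count per year is ", round(exp_node, 1),
            " (< 20); MI estimates will be unstable")
  }
  structure(as.list(environment()), class = "corpus_gen_config")
}

#' Generate a synthetic corpus with planted collocation structure
#'
#' A pure function of `(config, seed)`. Returns the documents, the
#' ground-truth rating lexicon (two identical raters holding the true
#' sentiment and medical labels, every word relevant), and the truth
#' parameters, so the whole measurement pipeline can be tested
#' without human raters.
#'
#' @param config A [corpus_gen_config()].
#' @return List with `corpus` (a `corpus`), `lexicon` (a
#'   `rating_lexicon`), and `truth`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_gen_config"))
  cf <- config
  vocab <- cf$vocabulary
  stop_pool <- setdiff(default_stopwords(), default_articles())
  stop_pool <- head(stop_pool, 40L)
  zipf_p <- (1 / seq_len(cf$background_vocab_size))
  zipf_p <- zipf_p / sum(zipf_p)
  bg_words <- sprintf("w%04d", seq_len(cf$background_vocab_size))

  .with_seed(cf$seed, function() {
    docs <- vector("list", length(cf$years) * cf$articles_per_year)
    k <- 0L
    for (yr in cf$years) {
      boost <- ifelse(vocab$medical == 1L & yr >= cf$policy_year,
                      cf$medical_boost, 1)
      strength <- vocab$strength * boost
      has_vocab <- sum(strength) > 0
      for (j in seq_len(cf$articles_per_year)) {
        n_tok <- cf$tokens_per_article
        cat_draw <- runif(n_tok)
        toks <- character(n_tok)
        is_art <- cat_draw < cf$article_rate
        is_stp <- !is_art & cat_draw < cf$article_rate + cf$stopword_rate
        is_bg <- !is_art & !is_stp
        toks[is_art] <- sample(c("the", "a", "an"), sum(is_art),
                               replace = TRUE, prob = c(0.6, 0.3, 0.1))
        toks[is_stp] <- sample(stop_pool, sum(is_stp), replace = TRUE)
        toks[is_bg] <- sample(bg_words, sum(is_bg), replace = TRUE,
                              prob = zipf_p)
        # sentence segmentation: break after each token w.p. 1/mean length
        brk <- runif(n_tok) < 1 / cf$mean_sentence_len
        brk[n_tok] <- TRUE
        sent_id <- c(0L, cumsum(brk))[seq_len(n_tok)]
        # plant node occurrences
        n_nodes <- stats::rbinom(1L, n_tok, cf$node_rate / 1000)
        if (n_nodes > 0L) {
          node_pos <- sort(sample.int(n_tok, min(n_nodes, n_tok)))
          toks[node_pos] <- cf$node_word
          if (has_vocab) {
            for (p in node_pos) {
              off <- p + c(-(6:1), 1:6)
              off <- off[off >= 1L & off <= n_tok]
              off <- off[sent_id[off] == sent_id[p]]
              off <- off[toks[off] != cf$node_word]
              fill <- off[runif(length(off)) < cf$window_fill]
              if (length(fill)) {
                toks[fill] <- sample(vocab$word, length(fill),
                                     replace = TRUE,
                                     prob = strength / sum(strength))
              }
            }
          }
        }
        sent_texts <- vapply(split(toks, sent_id), paste,
                             character(1), collapse = " ")
        k <- k + 1L
        docs[[k]] <- data.table::data.table(
          doc_id = sprintf("y%d_a%03d", yr, j), year = yr,
          source = "synthetic",
          text = paste0(paste(sent_texts, collapse = ". "), "."))
      }
    }
    corpus <- as_corpus(data.table::rbindlist(docs))
    lexicon <- as_rating_lexicon(data.frame(
      word = vocab$word, relevant = 1L,
      s_rater1 = vocab$sentiment, s_rater2 = vocab$sentiment,
      m_rater1 = vocab$medical, m_rater2 = vocab$medical))
    list(corpus = corpus, lexicon = lexicon,
         truth = cf[c("node_word", "node_rate", "policy_year",
                      "medical_boost", "window_fill", "seed")])
  })
}

#' Write a generated corpus to disk
#'
#' Writes one text file per document, a `manifest.tsv`, the
#' ground-truth `lexicon.tsv`, and `truth.json`.
#'
#' @param gen Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(gen, dir) {
  dir.create(file.path(dir, "texts"), recursive = TRUE, showWarnings = FALSE)
  paths <- file.path("texts", paste0(gen$corpus$doc_id, ".txt"))
  for (i in seq_len(nrow(gen$corpus))) {
    writeLines(gen$corpus$text[i], file.path(dir, paths[i]))
  }
  man <- data.table::data.table(
    doc_id = gen$corpus$doc_id, year = gen$corpus$year,
    source = gen$corpus$source, path = paths)
  data.table::fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  write_lexicon(gen$lexicon, file.path(dir, "lexicon.tsv"))
  jsonlite::write_json(gen$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
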