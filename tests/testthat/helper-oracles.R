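# Independent oracles and tiny fixture builders shared across tests.
# Each oracle deliberately takes a different computational route from
# the implementation it checks.

ext_path <- function(...) {
  system.file("extdata", ..., package = "agestereo", mustWork = TRUE)
}

# Build a token table from a list of character-vector sentences, all
# belonging to one document per year entry.
make_tokens <- function(sentences, year = 2015L, doc_id = "d1",
                        stopwords = default_stopwords(),
                        articles = default_articles()) {
  parts <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    data.table::data.table(
      doc_id = doc_id, year = as.integer(year), sentence = i,
      position = seq_along(s), token = s,
      is_stopword = s %in% stopwords, is_article = s %in% articles)
  })
  data.table::rbindlist(parts)
}

# Naive quadratic-time collocation oracle: for every node occurrence,
# scan outward token by token applying the span/article/boundary rules
# literally; a token instance inside several windows counts once.
oracle_count_collocates <- function(tokens, node_words, span = 6L,
                                    stopword_policy = "consume") {
  tokens <- as.data.frame(tokens)
  key <- paste(tokens$doc_id, tokens$sentence)
  hits <- list()
  for (i in seq_len(nrow(tokens))) {
    if (!tokens$token[i] %in% node_words) next
    same_sent <- which(key == key[i])
    for (dir in c(-1L, 1L)) {
      consumed <- 0L
      j <- i + dir
      while (j %in% same_sent && consumed < span) {
        is_art <- tokens$is_article[j]
        is_stp <- tokens$is_stopword[j] && !is_art
        if (is_art || (stopword_policy == "skip" && is_stp)) {
          j <- j + dir
          next
        }
        consumed <- consumed + 1L
        if (!is_stp && !tokens$token[j] %in% node_words) {
          hits[[length(hits) + 1L]] <- j
        }
        j <- j + dir
      }
    }
  }
  idx <- unique(unlist(hits))
  if (!length(idx)) {
    return(data.table::data.table(year = integer(), word = character(),
                                  f_near = integer()))
  }
  out <- data.table::as.data.table(
    table(year = tokens$year[idx], word = tokens$token[idx]))
  out <- out[out$N > 0L, ]
  data.table::setnames(out, "N", "f_near")
  out$year <- as.integer(out$year)
  out$f_near <- as.integer(out$f_near)
  data.table::setorder(out, year, word)
  out[]
}

# Hoyt ANOVA route to Cronbach's alpha: alpha = 1 - MSE / MSB from the
# two-way items x raters decomposition.
oracle_alpha <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  ss_items <- k * sum((rowMeans(X) - grand)^2)
  ss_raters <- n * sum((colMeans(X) - grand)^2)
  ss_total <- sum((X - grand)^2)
  ss_res <- ss_total - ss_items - ss_raters
  msb <- ss_items / (n - 1)
  mse <- ss_res / ((n - 1) * (k - 1))
  1 - mse / msb
}

# Explicit normal-equations least squares.
oracle_ols <- function(y, X) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Random small token stream over a tiny alphabet, for property tests.
random_tokens <- function(n_tokens = 60L, n_sentences = 4L,
                          node = "elderly") {
  alphabet <- c(node, "the", "a", "and", "of", "was",
                "cat", "dog", "tree", "house", "river", "cloud")
  toks <- sample(alphabet, n_tokens, replace = TRUE)
  sent <- sort(sample(seq_len(n_sentences), n_tokens, replace = TRUE))
  parts <- split(toks, sent)
  make_tokens(unname(parts), year = 2012L)
}

fixture_bundle <- function(B = 0, seed = NULL, ...) {
  corpus <- read_corpus(ext_path("corpus", "manifest.tsv"))
  lex <- read_lexicon(ext_path("lexicon.tsv"))
  cov <- read.delim(ext_path("covariates_support_ratio_synthetic.tsv"))
  analyze_corpus(corpus, lex, cov, B = B, seed = seed, ...)
}
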