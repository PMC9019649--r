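test_that("span rules: articles skipped, stop words consumed, node excluded", {
  toks <- make_tokens(list(c("the", "elderly", "suffer", "dementia")))
  counts <- count_collocates(toks, "elderly", span = 6)
  co <- as.data.frame(counts$co_occurrence)
  expect_setequal(co$word, c("suffer", "dementia"))
  expect_equal(co$f_near, c(1L, 1L))
  expect_equal(counts$totals$f_node, 1L)

  # stop words consume span positions but are not emitted
  toks <- make_tokens(list(c("elderly", "and", "of", "to", "in", "on", "at",
                             "cat")))
  counts <- count_collocates(toks, "elderly", span = 6)
  expect_equal(nrow(counts$co_occurrence), 0L) # six stop words fill the span
  counts <- count_collocates(toks, "elderly", span = 6,
                             stopword_policy = "skip")
  expect_equal(counts$co_occurrence$word, "cat")

  # articles do not consume: six articles then a content word still counts
  toks <- make_tokens(list(c("elderly", "the", "a", "an", "the", "a", "an",
                             "cat")))
  counts <- count_collocates(toks, "elderly", span = 1)
  expect_equal(counts$co_occurrence$word, "cat")

  # node word never its own collocate
  toks <- make_tokens(list(c("elderly", "meets", "elderly")))
  counts <- count_collocates(toks, "elderly", span = 6)
  expect_equal(counts$co_occurrence$word, "meets")
  expect_equal(counts$totals$f_node, 2L)
})

test_that("windows never cross sentence boundaries", {
  toks <- make_tokens(list(c("he", "left"), c("elderly", "thrive")))
  counts <- count_collocates(toks, "elderly", span = 6)
  expect_equal(counts$co_occurrence$word, "thrive")

  # zero node occurrences -> empty counts, f_node 0
  toks <- make_tokens(list(c("no", "nodes", "here")))
  counts <- count_collocates(toks, "elderly", span = 6)
  expect_equal(nrow(counts$co_occurrence), 0L)
  expect_equal(counts$totals$f_node, 0L)
})

test_that("count_collocates matches the naive oracle on crafted sentences", {
  crafted <- list(
    c("the", "elderly", "suffer", "dementia"),
    c("he", "left"), c("elderly", "thrive"),
    c("an", "elderly", "woman", "and", "her", "dog", "walked", "home"),
    c("care", "for", "the", "elderly"),
    c("elderly", "the", "a", "an", "cat", "dog", "tree", "house", "river",
      "cloud", "sun"),
    c("one", "two", "three", "four", "five", "six", "seven", "elderly"),
    c("elderly", "elderly", "care"),
    c("deep", "in", "the", "woods", "an", "elderly", "fox", "slept"),
    c("the", "cat", "sat"), c("elderly"), c("a", "a", "a", "elderly"),
    c("wise", "and", "active", "elderly", "people", "volunteer", "daily"),
    c("hero", "elderly", "hero"),
    c("of", "of", "of", "of", "of", "of", "elderly", "of", "of", "of",
      "of", "of", "of", "cat"),
    c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "elderly", "y1", "y2",
      "y3", "y4", "y5", "y6", "y7"),
    c("the", "elderly", "the", "cat", "the", "dog", "the", "tree", "the",
      "house", "the", "river", "the", "cloud", "the", "extra"),
    c("to", "be", "or", "not", "to", "be"),
    c("elderly", "care", "elderly", "care", "elderly"),
    c("a", "quick", "brown", "fox", "jumps", "over", "an", "elderly",
      "dog"),
    c("night", "fell", "quietly"), c("elderly", "neighbours", "sang"))
  toks <- make_tokens(crafted)
  for (policy in c("consume", "skip")) {
    got <- as.data.frame(
      count_collocates(toks, "elderly", span = 6,
                       stopword_policy = policy)$co_occurrence)
    want <- as.data.frame(
      oracle_count_collocates(toks, "elderly", span = 6,
                              stopword_policy = policy))
    expect_equal(got, want, info = policy)
  }
})

test_that("brute-force equivalence holds on random small corpora", {
  set.seed(421)
  for (rep in 1:25) {
    toks <- random_tokens(n_tokens = sample(20:200, 1),
                          n_sentences = sample(2:8, 1))
    span <- sample(1:6, 1)
    got <- as.data.frame(
      count_collocates(toks, "elderly", span = span)$co_occurrence)
    want <- as.data.frame(
      oracle_count_collocates(toks, "elderly", span = span))
    expect_equal(got, want)
  }
})

test_that("sum conservation and permutation invariance", {
  set.seed(99)
  toks <- random_tokens(n_tokens = 150, n_sentences = 6)
  span <- 3L
  counts <- count_collocates(toks, "elderly", span = span)
  expect_lte(sum(counts$co_occurrence$f_near),
             counts$totals$f_node * 2L * span)
  expect_true(all(counts$co_occurrence$f_near >= 0L))
  m <- merge(counts$co_occurrence, counts$corpus_freq,
             by = c("year", "word"))
  expect_true(all(m$f_near <= m$f_colloc))

  # shuffle document order (two docs); counts must be unchanged
  toks2 <- random_tokens(n_tokens = 80, n_sentences = 4)
  toks2$doc_id <- "d2"
  fwd <- count_collocates(rbind(toks, toks2), "elderly", span = span)
  rev <- count_collocates(rbind(toks2, toks), "elderly", span = span)
  expect_equal(as.data.frame(fwd$co_occurrence),
               as.data.frame(rev$co_occurrence))
  expect_equal(as.data.frame(fwd$totals), as.data.frame(rev$totals))
})

test_that("MI matches the stated formula and its identities", {
  # direct evaluation of the example counts
  expect_equal(mi_score(8, 100000, 10, 50, span = 6),
               log2(8 * 100000 / (10 * 50 * 12)))
  expect_equal(mi_score(8, 100000, 10, 50, span = 6), 7.0588937,
               tolerance = 1e-6)
  # independence -> 0: F_near/(F_node*S) == F_colloc/N
  expect_equal(mi_score(12, 1200, 10, 120, span = 6), 0)
  # doubling F_near adds exactly one bit
  expect_equal(mi_score(16, 100000, 10, 50, 6) -
                 mi_score(8, 100000, 10, 50, 6), 1)
})

test_that("mutual_information on counts agrees with a probability-ratio oracle", {
  set.seed(7)
  toks <- random_tokens(n_tokens = 180, n_sentences = 6)
  counts <- count_collocates(toks, "elderly", span = 4)
  mi <- mutual_information(counts)
  tot <- as.data.frame(counts$totals)
  m <- merge(as.data.frame(counts$co_occurrence),
             as.data.frame(counts$corpus_freq), by = c("year", "word"))
  for (i in seq_len(nrow(m))) {
    p_near <- m$f_near[i] / (tot$f_node * 2 * 4)
    p_corp <- m$f_colloc[i] / tot$n_tokens
    expect_equal(mi$mi[mi$word == m$word[i]], log2(p_near / p_corp),
                 tolerance = 1e-12)
  }
  # monotonicity: MI strictly increasing in F_near, decreasing in F_colloc
  base <- mi_score(5, 10000, 20, 40)
  expect_gt(mi_score(6, 10000, 20, 40), base)
  expect_lt(mi_score(5, 10000, 20, 41), base)
})

test_that("MI drops F_near = 0 silently and flags inconsistent counts", {
  toks <- make_tokens(list(c("elderly", "cat", "unrelated", "words")))
  counts <- count_collocates(toks, "elderly", span = 1)
  mi <- mutual_information(counts)
  expect_false("unrelated" %in% mi$word) # outside span -> absent, no -Inf
  expect_true(all(is.finite(mi$mi)))

  counts$corpus_freq <- counts$corpus_freq[0L, ]
  expect_error(mutual_information(counts), "F_colloc = 0")
})

test_that("years without node occurrences warn and are dropped", {
  with_node <- make_tokens(list(c("elderly", "cat")), year = 2010)
  without <- make_tokens(list(c("dog", "tree")), year = 2011, doc_id = "d2")
  counts <- count_collocates(rbind(with_node, without), "elderly")
  expect_warning(mi <- mutual_information(counts), "2011")
  expect_equal(unique(mi$year), 2010L)
})

test_that("filter threshold is inclusive and unrated words are routed", {
  scored <- data.table::data.table(
    year = 2010L, word = c("hero", "abuse", "mystery"),
    f_near = c(2L, 3L, 4L), f_colloc = c(2L, 3L, 4L),
    mi = c(1.5, 1.49, 2.0))
  lex <- as_rating_lexicon(data.frame(
    word = c("hero", "abuse"), relevant = c(1L, 1L),
    s_rater1 = c(5L, 1L), s_rater2 = c(5L, 1L),
    m_rater1 = 0L, m_rater2 = 0L))
  out <- filter_collocates(scored, lex, threshold = 1.5)
  rec <- as.data.frame(out$records)
  expect_true(rec$retained[rec$word == "hero"])   # exactly 1.5 retained
  expect_false(rec$retained[rec$word == "abuse"]) # 1.49 excluded
  expect_equal(out$needs_rating$word, "mystery")  # unrated, above bar

  # irrelevant word is never retained even with high MI
  lex2 <- as_rating_lexicon(data.frame(
    word = "hero", relevant = 0L, s_rater1 = 5L, s_rater2 = 5L,
    m_rater1 = 0L, m_rater2 = 0L))
  out2 <- filter_collocates(scored[scored$word == "hero", ], lex2)
  expect_false(any(out2$records$retained))
})

test_that("pooled MI aggregates counts over years", {
  t1 <- make_tokens(list(c("elderly", "cat")), year = 2010)
  t2 <- make_tokens(list(c("elderly", "cat")), year = 2011, doc_id = "d2")
  counts <- count_collocates(rbind(t1, t2), "elderly")
  pooled <- mutual_information(counts, pooling = "pooled")
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$f_near, 2L)
  expect_equal(pooled$mi, mi_score(2, 4, 2, 2, span = 6))
})
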