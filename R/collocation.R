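#' Windowed collocate counts around a node word
#'
#' For every occurrence of a node word, collects the tokens inside a
#' lexical span of `span` positions to each side, under these rules:
#' article tokens never consume a span position and are never
#' collected; non-article stop words consume a position but are not
#' emitted as collocates (set `stopword_policy = "skip"` to make them
#' behave like articles instead); node words are never counted as
#' their own collocates (they consume a position); the window never
#' crosses a sentence boundary in either direction, so a node at the
#' start of a sentence takes nothing from the previous sentence. A
#' token instance lying inside the windows of two nearby node
#' occurrences is counted once, which keeps `F_near <= F_colloc`.
#'
#' @param tokens Tokenized corpus from [tokenize_corpus()].
#' @param node_words Lowercase node word set (e.g. `"elderly"`).
#' @param span Content-word positions each side (default 6).
#' @param stopword_policy `"consume"` (default: non-article stop words
#'   use up span positions) or `"skip"` (they are passed over like
#'   articles).
#' @return A `collocation_counts` object: list with `span`,
#'   `stopword_policy`, `totals` (per-year `n_tokens`, `n_content`,
#'   `f_node`), `co_occurrence` (`year`, `word`, `f_near`) and
#'   `corpus_freq` (`year`, `word`, `f_colloc` for every co-occurring
#'   word).
#' @export
count_collocates <- function(tokens, node_words, span = 6L,
                             stopword_policy = c("consume", "skip")) {
  stopword_policy <- match.arg(stopword_policy)
  stopifnot(span >= 1L)
  tokens <- data.table::as.data.table(tokens)
  empty_counts <- function() {
    structure(list(
      span = as.integer(span), stopword_policy = stopword_policy,
      totals = data.table::data.table(year = integer(), n_tokens = integer(),
                                      n_content = integer(),
                                      f_node = integer()),
      co_occurrence = data.table::data.table(year = integer(),
                                             word = character(),
                                             f_near = integer()),
      corpus_freq = data.table::data.table(year = integer(),
                                           word = character(),
                                           f_colloc = integer())),
      class = "collocation_counts")
  }
  if (!nrow(tokens)) return(empty_counts())

  tok <- tokens$token
  art <- tokens$is_article
  stp <- tokens$is_stopword & !art
  nd <- tok %in% node_words
  yr <- tokens$year
  skip_stop <- stopword_policy == "skip"

  year <- n_tokens <- n_content <- f_node <- is_article <- is_stopword <-
    token <- NULL # data.table NSE
  totals <- tokens[, .(n_tokens = .N,
                       n_content = sum(!is_stopword & !is_article)),
                   by = year]
  totals <- merge(totals,
                  data.table::data.table(year = yr, node = nd)[
                    , .(f_node = sum(node)), by = year],
                  by = "year", all.x = TRUE)
  data.table::setorder(totals, year)

  # sentence-group bounds in stream order
  grp <- cumsum(c(TRUE, tokens$doc_id[-1] != tokens$doc_id[-nrow(tokens)] |
                    tokens$sentence[-1] != tokens$sentence[-nrow(tokens)]))
  gstart <- which(c(TRUE, diff(grp) != 0L))
  gend <- c(gstart[-1] - 1L, nrow(tokens))
  lo_of <- rep(gstart, gend - gstart + 1L)
  hi_of <- rep(gend, gend - gstart + 1L)

  node_idx <- which(nd)
  if (!length(node_idx)) {
    out <- empty_counts()
    out$totals <- totals
    return(out)
  }

  hit_idx <- integer(0)
  hit_node <- integer(0) # owning node occurrence, for de-duplication below
  for (i in node_idx) {
    lo <- lo_of[i]; hi <- hi_of[i]
    for (step in c(-1L, 1L)) {
      consumed <- 0L
      j <- i + step
      while (j >= lo && j <= hi && consumed < span) {
        if (art[j] || (skip_stop && stp[j])) { j <- j + step; next }
        consumed <- consumed + 1L
        if (!stp[j] && !nd[j]) {
          hit_idx <- c(hit_idx, j)
          hit_node <- c(hit_node, i)
        }
        j <- j + step
      }
    }
  }
  hit_idx <- unique(hit_idx) # one count per token instance

  co <- data.table::data.table(year = yr[hit_idx], word = tok[hit_idx])
  f_near <- word <- NULL
  co <- co[, .(f_near = .N), by = .(year, word)]
  data.table::setorder(co, year, word)

  freq <- data.table::data.table(year = yr, token = tok)[
    token %in% unique(co$word), .(f_colloc = .N), by = .(year, word = token)]
  data.table::setorder(freq, year, word)

  structure(list(span = as.integer(span), stopword_policy = stopword_policy,
                 totals = totals, co_occurrence = co, corpus_freq = freq),
            class = "collocation_counts")
}

#' @export
print.collocation_counts <- function(x, ...) {
  cat("Collocation counts (span ", x$span, ", stop words ",
      x$stopword_policy, ")\n", sep = "")
  cat("  years:", paste(x$totals$year, collapse = ", "), "\n")
  cat("  node occurrences:", sum(x$totals$f_node), "; distinct collocates:",
      length(unique(x$co_occurrence$word)), "\n")
  invisible(x)
}

#' Span-adjusted pointwise mutual information
#'
#' `MI = log2( (F_near * N) / (F_node * F_colloc * S) )` with
#' `S = 2 * span`, the window size in positions. This is the
#' association score used by the large web-corpus query interfaces:
#' the log-ratio (bits) of the observed co-occurrence rate to the rate
#' expected if the collocate were spread over the corpus independently
#' of the node word. Collocates with `F_near = 0` are simply absent
#' (no `-Inf` scores are emitted).
#'
#' @param counts A `collocation_counts` object.
#' @param pooling `"per_year"` (default; annual scores are the
#'   analysis unit) or `"pooled"` (counts summed over years first).
#' @param denominator Which corpus-size count to use for `N` and which
#'   population `F_colloc` is drawn from: `"all"` tokens (default) or
#'   `"content"` (stop words and articles excluded from `N`).
#' @return `data.table` with `year`, `word`, `f_near`, `f_colloc`,
#'   `mi`; attribute `span`. Years with `F_node = 0` are dropped with
#'   a warning (their SAS is missing downstream, never a silent zero).
#' @export
mutual_information <- function(counts, pooling = c("per_year", "pooled"),
                               denominator = c("all", "content")) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "collocation_counts"))
  totals <- data.table::copy(counts$totals)
  co <- data.table::copy(counts$co_occurrence)
  freq <- data.table::copy(counts$corpus_freq)
  year <- n_tokens <- n_content <- f_node <- f_near <- f_colloc <- NULL
  if (pooling == "pooled") {
    totals <- totals[, .(year = NA_integer_, n_tokens = sum(n_tokens),
                         n_content = sum(n_content), f_node = sum(f_node))]
    co <- co[, .(f_near = sum(f_near)), by = .(word)][, year := NA_integer_]
    freq <- freq[, .(f_colloc = sum(f_colloc)), by = .(word)][
      , year := NA_integer_]
  }
  dead <- totals[f_node == 0L | n_tokens == 0L]
  if (nrow(dead)) {
    warning("no node occurrences in year(s) ",
            paste(dead$year, collapse = ", "),
            "; no collocates scored there")
    totals <- totals[f_node > 0L & n_tokens > 0L]
  }
  x <- merge(co, freq, by = c("year", "word"), all.x = TRUE)
  x <- merge(x, totals, by = "year")
  if (any(is.na(x$f_colloc) | x$f_colloc == 0L)) {
    bad <- x[is.na(f_colloc) | f_colloc == 0L]
    stop("count inconsistency: F_colloc = 0 with F_near > 0 for '",
         bad$word[1], "'")
  }
  n_col <- if (denominator == "all") "n_tokens" else "n_content"
  s_total <- 2 * counts$span
  x$mi <- log2((x$f_near * x[[n_col]]) /
                 (x$f_node * x$f_colloc * s_total))
  out <- x[, c("year", "word", "f_near", "f_colloc", "mi"), with = FALSE]
  data.table::setorder(out, year, word)
  data.table::setattr(out, "span", counts$span)
  out[]
}

#' Evaluate the span-adjusted MI formula directly
#'
#' @param f_near Co-occurrences inside the span.
#' @param n_tokens Corpus size in tokens.
#' @param f_node Node-word occurrences.
#' @param f_colloc Collocate corpus frequency.
#' @param span Span size per side; the window size is `2 * span`.
#' @return MI in bits.
#' @export
mi_score <- function(f_near, n_tokens, f_node, f_colloc, span = 6) {
  log2((f_near * n_tokens) / (f_node * f_colloc * (2 * span)))
}

#' Filter MI-scored collocates through the rating lexicon
#'
#' Retains records with `mi >= threshold` (inclusive: 1.5 exactly
#' passes) whose word the lexicon marks relevant. Words passing the MI
#' bar but absent from the lexicon are routed to a needs-rating
#' report, never silently dropped.
#'
#' @param mi_scores Output of [mutual_information()].
#' @param lexicon A `rating_lexicon`.
#' @param threshold MI threshold in bits (default 1.5).
#' @return List of class `collocate_records`: `records` (`year`,
#'   `word`, `f_near`, `mi`, `relevant`, `retained`), `needs_rating`
#'   (above-threshold words with no lexicon entry) and `threshold`.
#' @export
filter_collocates <- function(mi_scores, lexicon, threshold = 1.5) {
  stopifnot(is.finite(threshold))
  scores <- lexicon_scores(lexicon)
  x <- merge(mi_scores,
             scores[, c("word", "relevant"), with = FALSE],
             by = "word", all.x = TRUE)
  known <- !is.na(x$relevant)
  mi <- NULL
  needs <- x[!known & mi >= threshold,
             c("year", "word", "f_near", "mi"), with = FALSE]
  records <- x[known]
  records$retained <- records$mi >= threshold & records$relevant
  records <- records[, c("year", "word", "f_near", "mi", "relevant",
                         "retained"), with = FALSE]
  data.table::setorder(records, year, word)
  data.table::setorder(needs, year, word)
  structure(list(records = records, needs_rating = needs,
                 threshold = threshold),
            class = "collocate_records")
}

#' @export
print.collocate_records <- function(x, ...) {
  cat("Collocate records: ", nrow(x$records), " scored, ",
      sum(x$records$retained), " retained (MI >= ", x$threshold,
      " and relevant); ", nrow(x$needs_rating), " need rating\n", sep = "")
  invisible(x)
}

#' Write collocate records and the needs-rating report to TSV
#'
#' @param records A `collocate_records` object.
#' @param records_path,needs_path Output paths.
#' @export
write_collocates <- function(records, records_path, needs_path) {
  data.table::fwrite(records$records, records_path, sep = "\t")
  data.table::fwrite(records$needs_rating, needs_path, sep = "\t")
  invisible(records_path)
}
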