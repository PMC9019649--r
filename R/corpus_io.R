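#' Default stop-word and article sets
#'
#' The shipped stop-word inventory covers standard English function
#' words (prepositions, conjunctions, pronouns, auxiliaries,
#' determiners). Articles are a subset of the stop words but get their
#' own flag because they do not consume positions in the collocation
#' span.
#'
#' @return Lowercase character vector.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "agestereo",
                      mustWork = TRUE)
  words <- readLines(path, encoding = "UTF-8")
  words <- trimws(words)
  words[nzchar(words) & !startsWith(words, "#")]
}

#' @rdname default_stopwords
#' @export
default_articles <- function() c("a", "an", "the")

#' Read a year-stamped corpus from a manifest
#'
#' The manifest is a TSV with columns `doc_id`, `year`, `source`,
#' `path`; `path` is resolved relative to the manifest's directory.
#' Rows whose year does not parse are kept with `NA` year and reported
#' in a warning, never silently dropped.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param text_encoding Encoding of the referenced text files.
#' @return A `data.table` of class `corpus` with columns `doc_id`,
#'   `year`, `source`, `text`.
#' @export
read_corpus <- function(manifest_path, text_encoding = "UTF-8") {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- data.table::fread(manifest_path, sep = "\t", colClasses = "character",
                           header = TRUE)
  required <- c("doc_id", "year", "source", "path")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- man$doc_id[duplicated(man$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id in manifest: ", paste(unique(dup), collapse = ", "))
  }
  year <- suppressWarnings(as.integer(man$year))
  bad <- which(is.na(year) & !is.na(man$year))
  if (length(bad)) {
    warning("manifest rows with unparseable year kept as NA: ",
            paste(sprintf("row %d (doc_id %s)", bad, man$doc_id[bad]),
                  collapse = "; "))
  }
  base_dir <- dirname(normalizePath(manifest_path))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base_dir, man$path))
  absent <- which(!file.exists(paths))
  if (length(absent)) {
    stop("text file missing for doc_id ", man$doc_id[absent[1]],
         " (manifest row ", absent[1], "): ", man$path[absent[1]])
  }
  text <- vapply(paths, function(p) {
    paste(readLines(p, encoding = text_encoding, warn = FALSE),
          collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  out <- data.table::data.table(doc_id = man$doc_id, year = year,
                                source = man$source, text = text)
  as_corpus(out)
}

#' Read a corpus from newline-delimited JSON records
#'
#' Each line is a JSON object with fields `id`, `year`, `source`,
#' `text`.
#'
#' @param path Path to the JSONL file.
#' @return A `corpus` as from [read_corpus()].
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.table::data.table(
    doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    source = vapply(recs, function(r) as.character(r$source %||% ""),
                    character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)))
  dup <- out$doc_id[duplicated(out$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "))
  }
  as_corpus(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and class a document table as a corpus
#'
#' @param x data.frame with columns `doc_id`, `year`, `source`, `text`.
#' @return `x` as a `corpus` data.table.
#' @export
as_corpus <- function(x) {
  x <- data.table::as.data.table(x)
  required <- c("doc_id", "year", "source", "text")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("corpus lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  empty <- which(!nzchar(trimws(x$text)))
  if (length(empty)) {
    stop("empty text for doc_id: ",
         paste(x$doc_id[empty], collapse = ", "))
  }
  x$year <- as.integer(x$year)
  data.table::setattr(x, "class", c("corpus", class(data.table::data.table())))
  x[]
}

# -- tokenization -----------------------------------------------------------

# Lowercase, strip possessive 's, collapse all characters outside
# [a-z0-9'-] to spaces, split on whitespace, and trim stray leading or
# trailing hyphens/apostrophes. Hyphenated words stay whole.
.clean_tokens <- function(sentence) {
  s <- tolower(sentence)
  s <- gsub("’", "'", s, fixed = TRUE)
  s <- gsub("'s\\b", "", s, perl = TRUE)
  s <- gsub("[^a-z0-9'-]+", " ", s, perl = TRUE)
  toks <- strsplit(trimws(s), "[ ]+")[[1]]
  toks <- gsub("^[-']+|[-']+$", "", toks)
  toks[nzchar(toks)]
}

#' Tokenize a document into annotated sentences
#'
#' Sentences are split on terminal punctuation (`.`, `!`, `?`)
#' followed by whitespace; tokens are lowercased with punctuation
#' stripped. Stop words are *flagged, not deleted*, so the collocation
#' span rule can skip them deterministically; articles carry a
#' separate flag.
#'
#' @param document One-row corpus (or list with `doc_id`, `year`,
#'   `text`).
#' @param stopwords,articles Lowercase word sets.
#' @return A `data.table` with columns `doc_id`, `year`, `sentence`
#'   (1-based index within the document), `position` (1-based within
#'   sentence), `token`, `is_stopword`, `is_article`. Empty documents
#'   give zero rows.
#' @export
tokenize <- function(document, stopwords = default_stopwords(),
                     articles = default_articles()) {
  doc <- as.list(document)
  text <- doc$text
  if (is.null(text)) stop("document has no text field")
  sents <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  tok_list <- lapply(sents, .clean_tokens)
  keep <- lengths(tok_list) > 0L
  tok_list <- tok_list[keep]
  if (!length(tok_list)) {
    return(data.table::data.table(
      doc_id = character(), year = integer(), sentence = integer(),
      position = integer(), token = character(),
      is_stopword = logical(), is_article = logical()))
  }
  n <- lengths(tok_list)
  token <- unlist(tok_list, use.names = FALSE)
  out <- data.table::data.table(
    doc_id = rep(as.character(doc$doc_id %||% NA_character_), sum(n)),
    year = rep(as.integer(doc$year %||% NA_integer_), sum(n)),
    sentence = rep(seq_along(tok_list), n),
    position = unlist(lapply(n, seq_len), use.names = FALSE),
    token = token,
    is_stopword = token %in% stopwords,
    is_article = token %in% articles)
  out
}

#' Tokenize every document of a corpus
#'
#' @param corpus A `corpus` from [read_corpus()].
#' @inheritParams tokenize
#' @return One `data.table` in the layout of [tokenize()], documents in
#'   corpus order.
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords(),
                            articles = default_articles()) {
  parts <- lapply(seq_len(nrow(corpus)), function(i) {
    tokenize(corpus[i, ], stopwords = stopwords, articles = articles)
  })
  data.table::rbindlist(parts)
}

# -- rating lexicon ---------------------------------------------------------

#' Read a multi-rater word lexicon
#'
#' TSV with columns `word`, `relevant`, `s_rater1..s_raterK`
#' (sentiment, integers 1-5) and `m_rater1..m_raterK` (medical flags,
#' 0/1). At least two raters are required and the rater count must
#' match between the sentiment and medical blocks.
#'
#' @param path Path to the lexicon TSV.
#' @return A `rating_lexicon` data.table; attribute `n_raters` holds
#'   the rater count.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon not found: ", path)
  lex <- data.table::fread(path, sep = "\t", header = TRUE)
  as_rating_lexicon(lex)
}

#' @rdname read_lexicon
#' @param x data.frame in the lexicon layout.
#' @export
as_rating_lexicon <- function(x) {
  lex <- data.table::as.data.table(x)
  if (!all(c("word", "relevant") %in% names(lex))) {
    stop("lexicon needs 'word' and 'relevant' columns")
  }
  s_cols <- grep("^s_rater", names(lex), value = TRUE)
  m_cols <- grep("^m_rater", names(lex), value = TRUE)
  if (length(s_cols) < 2L) {
    stop("lexicon needs at least two sentiment rater columns (s_rater*)")
  }
  if (length(m_cols) != length(s_cols)) {
    stop("inconsistent rater count: ", length(s_cols), " sentiment vs ",
         length(m_cols), " medical rater columns")
  }
  dup <- lex$word[duplicated(lex$word)]
  if (length(dup)) {
    stop("duplicate lexicon word(s): ", paste(unique(dup), collapse = ", "))
  }
  for (cc in s_cols) {
    v <- lex[[cc]]
    bad <- which(is.na(v) | v %% 1 != 0 | v < 1 | v > 5)
    if (length(bad)) {
      stop("sentiment rating outside 1-5 in column ", cc, ", row ", bad[1],
           " (word '", lex$word[bad[1]], "')")
    }
    lex[[cc]] <- as.integer(v)
  }
  for (cc in m_cols) {
    v <- lex[[cc]]
    bad <- which(is.na(v) | !v %in% c(0, 1))
    if (length(bad)) {
      stop("medical flag not 0/1 in column ", cc, ", row ", bad[1],
           " (word '", lex$word[bad[1]], "')")
    }
    lex[[cc]] <- as.integer(v)
  }
  lex$word <- tolower(as.character(lex$word))
  lex$relevant <- as.logical(as.integer(lex$relevant))
  data.table::setcolorder(lex, c("word", "relevant", s_cols, m_cols))
  data.table::setattr(lex, "n_raters", length(s_cols))
  data.table::setattr(lex, "class",
                      c("rating_lexicon", class(data.table::data.table())))
  lex[]
}

#' Write a rating lexicon back to TSV
#'
#' Writing then re-reading yields an identical structure (round-trip
#' contract).
#'
#' @param lexicon A `rating_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- data.table::copy(data.table::as.data.table(lexicon))
  out$relevant <- as.integer(out$relevant)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Per-word mean sentiment and medical scores from a lexicon
#'
#' Sentiment is the arithmetic mean of the 1-5 rater scores; the
#' medical score is the mean of the 0/1 rater flags (so a 2-rater
#' disagreement contributes 0.5).
#'
#' @param lexicon A `rating_lexicon`.
#' @return data.table with columns `word`, `relevant`, `sentiment`,
#'   `medical`.
#' @export
lexicon_scores <- function(lexicon) {
  s_cols <- grep("^s_rater", names(lexicon), value = TRUE)
  m_cols <- grep("^m_rater", names(lexicon), value = TRUE)
  data.table::data.table(
    word = lexicon$word,
    relevant = lexicon$relevant,
    sentiment = rowMeans(as.matrix(lexicon[, s_cols, with = FALSE])),
    medical = rowMeans(as.matrix(lexicon[, m_cols, with = FALSE])))
}

#' Mean sentiment of one lexicon entry
#'
#' @param ratings Integer ratings in 1-5, one per rater.
#' @return Mean rating, a real number in \[1, 5\].
#' @export
mean_sentiment <- function(ratings) {
  if (!length(ratings)) stop("at least one rating required")
  if (any(is.na(ratings) | ratings < 1 | ratings > 5)) {
    stop("ratings must lie in 1-5")
  }
  mean(ratings)
}
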