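#' Percentage with half-up rounding at the printed precision
#'
#' `100 * numerator / denominator`, rounded half-up (not banker's) to
#' `decimals` places, using exact integer rational arithmetic so the result
#' agrees with hand arithmetic at the printed precision.
#'
#' @param numerator,denominator Nonnegative counts; the denominator must be
#'   positive.
#' @param decimals Number of decimal places (>= 0).
#' @return The rounded percentage as a number.
#' @export
percent <- function(numerator, denominator, decimals = 2L) {
  assert_that(length(denominator) == 1L && denominator > 0,
              "denominator must be positive")
  assert_that(decimals >= 0, "decimals must be >= 0")
  scale <- 10^decimals
  scaled <- as.numeric(numerator) * 100 * scale
  q <- scaled %/% as.numeric(denominator)
  r <- scaled %% as.numeric(denominator)
  q <- q + as.numeric(2 * r >= denominator)
  q / scale
}

#' Subscriber participation distribution
#'
#' Sorts authors by message count (descending, ties broken by author name)
#' and reports the cumulative message share held by the top fraction of
#' authors at each requested boundary. Boundaries are fractions of posting
#' authors by default; with `of = "subscribers"` they are fractions of the
#' total list size (`n_subscribers`), which is external config metadata —
#' passive subscribers post nothing and cannot be counted from the corpus.
#'
#' @param corpus A `mail_corpus` (or any data frame with an `author`
#'   column); must be nonempty.
#' @param boundaries Fractions in (0, 1].
#' @param n_subscribers Optional total list size; enables the passive
#'   subscriber count and `of = "subscribers"`.
#' @param of Base population for the boundaries.
#' @return A tibble: `boundary`, `n_authors`, `author_share`, `n_messages`,
#'   `message_share`; attributes `n_posting`, `n_subscribers`, `n_passive`.
#' @export
participation_distribution <- function(corpus,
                                       boundaries = c(0.05, 0.11, 1),
                                       n_subscribers = NULL,
                                       of = c("authors", "subscribers")) {
  of <- match.arg(of)
  assert_that(nrow(corpus) > 0, "empty corpus")
  assert_that(all(boundaries > 0 & boundaries <= 1),
              "boundaries must be fractions in (0, 1]")
  if (of == "subscribers")
    assert_that(!is.null(n_subscribers), "of = 'subscribers' needs n_subscribers")

  counts <- sort(table(corpus$author), decreasing = TRUE)
  # stable tie-break by author name
  counts <- counts[order(-as.integer(counts), names(counts))]
  n_posting <- length(counts)
  total <- sum(counts)
  base <- if (of == "authors") n_posting else n_subscribers

  rows <- lapply(boundaries, function(f) {
    k <- min(n_posting, max(1L, round(f * base)))
    tibble::tibble(
      boundary = f,
      n_authors = k,
      author_share = k / base,
      n_messages = as.integer(sum(counts[seq_len(k)])),
      message_share = sum(counts[seq_len(k)]) / total
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_posting") <- n_posting
  attr(out, "n_subscribers") <- n_subscribers
  attr(out, "n_passive") <- if (!is.null(n_subscribers))
    n_subscribers - n_posting else NA_integer_
  out
}

#' Run the full message-mining workflow
#'
#' Executes ingest, clean, tokenize, content-filter, collocate, keyword
#' extraction, retrieval, delivery, and reporting in the fixed workflow
#' order: collocations are computed from the content-filtered token stream,
#' while retrieval runs on the cleaned (not NLP-filtered) text. Emits a
#' stage-accounting table in which each filtering stage's input count equals
#' the previous stage's output count.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `mailbox` + `format` (or a ready `corpus`); optional `noise_patterns`
#'   (file), `names`, `places` (files or character vectors), `stopwords`
#'   (file or vector), `min_len` (4), `content_min_len` (6),
#'   `content_min_freq` (8), `k_per_type` (300), `min_count` (2),
#'   `span_messages` (FALSE), `lexicon` (file or lexicon object),
#'   `categories`, `max_gap` (100), `equiv` (file), `outdir`,
#'   `n_subscribers`.
#' @return A list of artifacts: `corpus`, `clean`, `stream_raw` counts,
#'   `stream1`, `content`, `bigrams`, `trigrams`, `collocations`,
#'   `keywords`, `retrieval`, `report`, `participation`, `stage_reports`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)

  read_list <- function(x) {
    if (is.null(x)) return(character())
    if (length(x) == 1L && file.exists(x)) {
      l <- readLines(x, warn = FALSE, encoding = "UTF-8")
      return(tolower(trimws(l[nzchar(trimws(l))])))
    }
    tolower(as.character(x))
  }

  corpus <- config$corpus %||%
    read_mailbox(config$mailbox, config$format %||% "mbox", quiet = TRUE)
  rules <- if (!is.null(config$noise_patterns)) noise_rules(config$noise_patterns)
           else noise_rules()
  clean <- clean_corpus(corpus, rules,
                        names = read_list(config$names),
                        places = read_list(config$places))

  stopwords <- if (is.null(config$stopwords)) default_stopwords()
               else read_list(config$stopwords)
  min_len <- config$min_len %||% 4L
  raw_stream <- tokenize_corpus(clean, stopwords = NULL, min_len = 1L)
  stream1 <- tokenize_corpus(clean, stopwords = stopwords, min_len = min_len)
  freq1 <- build_freq_table(stream1)
  content <- content_filter(stream1, freq1,
                            min_len = config$content_min_len %||% 6L,
                            min_freq = config$content_min_freq %||% 8L)

  span <- isTRUE(config$span_messages)
  bigrams <- build_ngrams(content$stream, 2L, span_messages = span)
  trigrams <- build_ngrams(content$stream, 3L, span_messages = span)
  collocations <- top_collocations(bigrams, trigrams, content$freq,
                                   k_per_type = config$k_per_type %||% 300L,
                                   min_count = config$min_count %||% 2L)
  equiv <- if (!is.null(config$equiv)) equivalence_map(config$equiv) else NULL
  keywords <- extract_keywords(collocations, equiv = equiv)

  retrieval <- NULL; report <- NULL
  lex <- config$lexicon
  if (!is.null(lex)) {
    if (is.character(lex)) lex <- load_lexicon(lex)
    retrieval <- retrieve(clean, lex, categories = config$categories,
                          max_gap = config$max_gap %||% 100L)
    report <- retrieval_report(retrieval)
    if (!is.null(config$outdir))
      deliver(retrieval, clean, config$outdir)
  }

  participation <- if (nrow(corpus) > 0)
    participation_distribution(corpus,
                               n_subscribers = config$n_subscribers) else NULL

  n_raw <- nrow(raw_stream)
  stage_reports <- tibble::tibble(
    stage = c("ingest", "clean", "tokens_raw", "tokens_stage1",
              "tokens_content", "vocabulary", "collocations"),
    unit = c("messages", "messages", "tokens", "tokens", "tokens", "types",
             "ngrams"),
    n_in = c(nrow(corpus), nrow(corpus), NA, n_raw, nrow(stream1),
             nrow(content$stream), nrow(bigrams) + nrow(trigrams)),
    n_out = c(nrow(corpus), nrow(clean), n_raw, nrow(stream1),
              nrow(content$stream), attr(content$freq, "n_types"),
              nrow(collocations)),
    pct_of_raw = c(NA, NA, NA,
                   if (n_raw > 0) percent(nrow(stream1), n_raw, 2L) else NA,
                   if (n_raw > 0) percent(nrow(content$stream), n_raw, 2L) else NA,
                   if (nrow(content$stream) > 0)
                     percent(attr(content$freq, "n_types"),
                             nrow(content$stream), 2L) else NA,
                   NA)
  )

  list(corpus = corpus, clean = clean,
       n_tokens_raw = n_raw, stream1 = stream1, freq1 = freq1,
       content = content, bigrams = bigrams, trigrams = trigrams,
       collocations = collocations, keywords = keywords,
       retrieval = retrieval, report = report,
       participation = participation, stage_reports = stage_reports)
}
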