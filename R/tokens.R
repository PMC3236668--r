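#' Default English stopword list
#'
#' The classic 127-word English function-word list, shipped as a plain-text
#' file (one word per line) and replaceable via the `path` argument of any
#' function that takes a stoplist.
#'
#' @param path Stopword file; `NULL` uses the shipped default.
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_en.txt",
                                package = "clinicolloc")
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tolower(trimws(words[nzchar(trimws(words))]))
}

#' Tokenize cleaned text into alphabetic tokens
#'
#' A token is a maximal run of letter characters, lowercased; digits and
#' hyphens split tokens (so "x-ray" gives "x" and "ray"). Tokens shorter
#' than `min_len` characters are dropped (the first-stage length filter;
#' the conventional reading of a "length > 3" rule is keep length >= 4).
#' Offsets point at each run's first character in the clean text (1-based).
#'
#' @param text Cleaned message text.
#' @param min_len Minimum token length kept.
#' @return A tibble with columns `token`, `start`.
#' @export
tokenize <- function(text, min_len = 4L) {
  if (length(text) == 0L || is.na(text) || !nzchar(text))
    return(tibble::tibble(token = character(), start = integer()))
  loc <- stringi::stri_locate_all_regex(text, "\\p{L}+")[[1]]
  if (all(is.na(loc[, 1])))
    return(tibble::tibble(token = character(), start = integer()))
  tok <- tolower(stringi::stri_sub(text, loc[, 1], loc[, 2]))
  keep <- nchar(tok) >= min_len
  tibble::tibble(token = tok[keep], start = as.integer(loc[keep, 1]))
}

#' Tokenize every message of a cleaned corpus
#'
#' @param clean A [clean_corpus()] tibble.
#' @param stopwords Stoplist applied after tokenization (`NULL` to skip).
#' @inheritParams tokenize
#' @return A token-stream tibble: `id`, `token`, `start`, in corpus order.
#' @export
tokenize_corpus <- function(clean, stopwords = default_stopwords(),
                            min_len = 4L) {
  streams <- lapply(seq_len(nrow(clean)), function(i) {
    s <- tokenize(clean$text[i], min_len = min_len)
    s$id <- clean$id[i]
    s
  })
  out <- dplyr::bind_rows(streams)
  if (nrow(out) == 0L)
    out <- tibble::tibble(id = integer(), token = character(),
                          start = integer())
  out <- out[, c("id", "token", "start")]
  if (!is.null(stopwords)) out <- remove_stopwords(out, stopwords)
  out
}

#' Remove stopwords from a token stream
#'
#' Tokens in the stoplist are dropped; offsets of the survivors are
#' unchanged. An empty stoplist is the identity.
#'
#' @param stream A token-stream tibble (`id`, `token`, `start`).
#' @param stoplist Lowercase character vector.
#' @return The filtered stream.
#' @export
remove_stopwords <- function(stream, stoplist = default_stopwords()) {
  if (length(stoplist) == 0L) return(stream)
  stream[!(stream$token %in% stoplist), , drop = FALSE]
}

#' Corpus-wide token frequency table
#'
#' @param stream A token-stream tibble over the whole corpus.
#' @return A tibble (`token`, `count`) sorted by decreasing count then
#'   token, with attributes `total_tokens` and `n_types`.
#' @export
build_freq_table <- function(stream) {
  if (nrow(stream) == 0L) {
    out <- tibble::tibble(token = character(), count = integer())
  } else {
    tab <- table(stream$token)
    out <- tibble::tibble(token = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$token), , drop = FALSE]
  }
  attr(out, "total_tokens") <- sum(out$count)
  attr(out, "n_types") <- nrow(out)
  out
}

#' Second-stage content filter
#'
#' Keeps content-bearing tokens: length at least `min_len` characters AND
#' corpus-wide frequency at least `min_freq` (the conventional reading of
#' "length > 5 and frequency > 7"). The frequency is taken from the
#' first-stage table built over the merged corpus stream, not per message.
#'
#' @param stream First-stage token stream (post stopword removal).
#' @param freq First-stage frequency table from [build_freq_table()].
#' @param min_len,min_freq Filter thresholds.
#' @return A list: `stream` (the surviving tokens, offsets unchanged) and
#'   `freq` (frequency table over the survivors; its `n_types` attribute is
#'   the size of the content vocabulary).
#' @export
content_filter <- function(stream, freq = build_freq_table(stream),
                           min_len = 6L, min_freq = 8L) {
  keep_types <- freq$token[freq$count >= min_freq & nchar(freq$token) >= min_len]
  kept <- stream[stream$token %in% keep_types, , drop = FALSE]
  list(stream = kept, freq = build_freq_table(kept))
}
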