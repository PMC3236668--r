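# shared builders for in-code fixtures

# a clean_corpus tibble from plain texts (ids 1..n, daily dates)
mk_clean <- function(texts, start_date = "2008-04-18") {
  out <- tibble::tibble(
    id = seq_along(texts),
    date = as.POSIXct(start_date, tz = "UTC") + (seq_along(texts) - 1) * 86400,
    text = texts,
    removal_log = rep(list(NULL), length(texts))
  )
  class(out) <- c("clean_corpus", class(out))
  out
}

# a token-stream tibble from a list of per-message token vectors
mk_stream <- function(tokens_by_msg) {
  rows <- lapply(seq_along(tokens_by_msg), function(i) {
    toks <- tokens_by_msg[[i]]
    tibble::tibble(id = i, token = toks,
                   start = cumsum(c(1L, utils::head(nchar(toks) + 1L, -1L))))
  })
  dplyr::bind_rows(rows)
}

# independent brute-force PMI oracle: enumerates contiguous windows directly
brute_pmi <- function(tokens_by_msg, words) {
  n <- length(words)
  W <- 0L; c_ng <- 0L
  for (toks in tokens_by_msg) {
    if (length(toks) < n) next
    for (i in seq_len(length(toks) - n + 1L)) {
      W <- W + 1L
      if (all(toks[i:(i + n - 1L)] == words)) c_ng <- c_ng + 1L
    }
  }
  all_tokens <- unlist(tokens_by_msg)
  T <- length(all_tokens)
  p_uni <- vapply(words, function(w) sum(all_tokens == w) / T, numeric(1))
  log2((c_ng / W) / prod(p_uni))
}

# a small two-category lexicon used across retrieval tests
mk_lexicon <- function() {
  as_lexicon(list(
    `systemic disease` = list(
      phrases = list("herpes zoster", "fistula filled obturation"),
      keywords = list("mercury")),
    medication = list(
      phrases = list("intravenous bisphosphonates"),
      keywords = list("amoxicillin"))
  ))
}

# a raw mail_corpus from body strings (ids 1..n, daily dates)
mk_corpus <- function(bodies) {
  out <- tibble::tibble(
    id = seq_along(bodies),
    date = as.POSIXct("2008-04-18", tz = "UTC") + (seq_along(bodies) - 1) * 86400,
    author = sprintf("author%03d", seq_along(bodies)),
    subject = "Re: test",
    body = bodies,
    dated = TRUE)
  class(out) <- c("mail_corpus", class(out))
  out
}

# separator giving exactly `g` characters between two whole words
gap_sep <- function(g) {
  if (g == 0) return("")
  if (g == 1) return(" ")
  paste0(" ", strrep("-", g - 2), " ")
}
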