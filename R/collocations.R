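#' Build an n-gram table over content token streams
#'
#' Counts contiguous n-token windows (n = 2 or 3) over the content-filtered
#' stream. With `span_messages = FALSE` (the default) windows never cross a
#' message boundary; setting it `TRUE` reproduces the merged-file behaviour
#' of concatenating all messages in date order before windowing.
#'
#' @param stream A content token-stream tibble (`id`, `token`, `start`),
#'   ordered by message id then offset.
#' @param n Window size, 2 or 3.
#' @param span_messages Allow windows to cross message boundaries.
#' @return An `ngram_table`: a tibble with word columns `w1..wn` and
#'   `count`, plus attributes `n`, `window_total` (number of windows) and
#'   `n_distinct` (number of distinct n-gram types).
#' @export
build_ngrams <- function(stream, n, span_messages = FALSE) {
  assert_that(n %in% c(2L, 3L), "n must be 2 or 3")
  n <- as.integer(n)
  stream <- stream[order(stream$id, stream$start), , drop = FALSE]
  toks <- stream$token
  grp <- if (span_messages || nrow(stream) == 0L) rep(1L, length(toks))
         else stream$id

  len <- length(toks)
  windows <- 0L
  cols <- replicate(n, character(), simplify = FALSE)
  if (len >= n) {
    # a window is valid when all n positions lie in the same group
    idx <- seq_len(len - n + 1L)
    same <- grp[idx] == grp[idx + n - 1L]
    idx <- idx[same]
    windows <- length(idx)
    cols <- lapply(seq_len(n) - 1L, function(k) toks[idx + k])
  }
  key <- do.call(paste, c(cols, sep = " "))
  if (length(key)) {
    tab <- table(key)
    parts <- stringi::stri_split_fixed(names(tab), " ")
    out <- tibble::as_tibble(stats::setNames(
      lapply(seq_len(n), function(k) vapply(parts, `[[`, character(1), k)),
      paste0("w", seq_len(n))))
    out$count <- as.integer(tab)
    out <- out[order(-out$count, out$w1, out$w2), , drop = FALSE]
  } else {
    out <- tibble::as_tibble(stats::setNames(
      replicate(n, character(), simplify = FALSE), paste0("w", seq_len(n))))
    out$count <- integer()
  }
  structure(out, n = n, window_total = windows, n_distinct = nrow(out),
            class = c("ngram_table", class(out)))
}

#' Pointwise mutual information of an n-gram, in bits
#'
#' PMI compares the n-gram's observed window probability with the product of
#' its words' marginal unigram probabilities: for a bigram,
#' `log2((c12 / W) / ((c1 / T) (c2 / T)))`, and for a trigram the analogous
#' form with the product of three unigram probabilities. `W` is the window
#' total of the n-gram table and `T` the unigram token total, so an n-gram
#' whose words co-occur exactly as often as independence predicts scores 0.
#'
#' @param words Character vector of 2 or 3 tokens.
#' @param ngram_table An [build_ngrams()] table containing the tuple.
#' @param unigram_freq Unigram frequency table ([build_freq_table()]) over
#'   the same content stream.
#' @return PMI in bits (finite; zero counts violate the precondition and
#'   are an error).
#' @export
pmi <- function(words, ngram_table, unigram_freq) {
  n <- attr(ngram_table, "n")
  assert_that(length(words) == n,
              sprintf("expected %d words for this table", n))
  sel <- rep(TRUE, nrow(ngram_table))
  for (k in seq_len(n))
    sel <- sel & ngram_table[[paste0("w", k)]] == words[k]
  assert_that(any(sel), sprintf("n-gram not in table: %s",
                                paste(words, collapse = " ")))
  c_ng <- ngram_table$count[which(sel)[1]]
  W <- attr(ngram_table, "window_total")
  T <- attr(unigram_freq, "total_tokens")
  c_uni <- unigram_freq$count[match(words, unigram_freq$token)]
  assert_that(!anyNA(c_uni) && all(c_uni > 0) && c_ng > 0 && W > 0 && T > 0,
              "zero or missing counts: precondition violated")
  log2((c_ng / W) / prod(c_uni / T))
}

# Vectorised PMI over all rows of an n-gram table.
pmi_all <- function(ngram_table, unigram_freq) {
  n <- attr(ngram_table, "n")
  if (nrow(ngram_table) == 0L) return(numeric())
  W <- attr(ngram_table, "window_total")
  T <- attr(unigram_freq, "total_tokens")
  p <- ngram_table$count / W
  for (k in seq_len(n)) {
    c_uni <- unigram_freq$count[match(ngram_table[[paste0("w", k)]],
                                      unigram_freq$token)]
    p <- p / (c_uni / T)
  }
  log2(p)
}

#' Top PMI-ranked collocations
#'
#' Scores every n-gram with count at least `min_count` by PMI and returns
#' the `k_per_type` best of each type (bigrams first, then trigrams). Within
#' a type the sort order is PMI descending, count descending, words
#' ascending. A minimum count of 2 is the default because PMI at count 1
#' maximally rewards noise.
#'
#' @param bigrams,trigrams [build_ngrams()] tables (either may be `NULL`).
#' @param unigram_freq Unigram frequency table over the content stream.
#' @param k_per_type Collocations kept per n-gram type.
#' @param min_count Minimum n-gram count to be scored.
#' @return A tibble of scored collocations: `rank` (within type), `n`,
#'   `words` (space-joined), `count`, `pmi`.
#' @export
top_collocations <- function(bigrams = NULL, trigrams = NULL, unigram_freq,
                             k_per_type = 300L, min_count = 2L) {
  assert_that(min_count >= 1L, "min_count must be >= 1")
  score_one <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    n <- attr(tab, "n")
    scores <- pmi_all(tab, unigram_freq)
    keep <- tab$count >= min_count
    if (!any(keep)) return(NULL)
    words <- do.call(paste, lapply(seq_len(n),
                                   function(k) tab[[paste0("w", k)]]))
    out <- tibble::tibble(n = n, words = words[keep],
                          count = tab$count[keep], pmi = scores[keep])
    out <- out[order(-out$pmi, -out$count, out$words), , drop = FALSE]
    if (nrow(out) < k_per_type)
      message(sprintf("only %d candidate %d-grams (k = %d requested)",
                      nrow(out), n, k_per_type))
    out <- utils::head(out, k_per_type)
    out$rank <- seq_len(nrow(out))
    out[, c("rank", "n", "words", "count", "pmi")]
  }
  out <- dplyr::bind_rows(score_one(bigrams), score_one(trigrams))
  if (nrow(out) == 0L)
    out <- tibble::tibble(rank = integer(), n = integer(),
                          words = character(), count = integer(),
                          pmi = numeric())
  out
}

#' Write scored collocations as a tab-separated file
#'
#' Columns: `rank`, `n`, `words` (space-joined), `count`, `pmi_bits`.
#'
#' @param collocations A [top_collocations()] tibble.
#' @param path Output file.
#' @export
write_collocations <- function(collocations, path) {
  out <- collocations
  names(out)[names(out) == "pmi"] <- "pmi_bits"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
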