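#' Compile a phrase into an order-free proximity query
#'
#' A discovered phrase is searched as its word set, recombined in any order
#' with at most `max_gap` characters between consecutive matched words
#' (words in messages are sometimes reordered relative to the discovered
#' phrase, e.g. "mutans streptococci" versus "streptococci mutans").
#'
#' @param phrase Character vector of 2 or 3 words, or a single space-joined
#'   string.
#' @param max_gap Maximum characters allowed between consecutive matched
#'   words (default 100).
#' @param order_free Ignore word order (default `TRUE`).
#' @return A `phrase_query` object.
#' @export
compile_phrase_query <- function(phrase, max_gap = 100L, order_free = TRUE) {
  words <- if (length(phrase) == 1L)
    strsplit(trimws(phrase), "\\s+")[[1]] else as.character(phrase)
  words <- tolower(words)
  assert_that(length(words) %in% 2:3,
              sprintf("phrase must have 2 or 3 words, got %d", length(words)))
  assert_that(!anyDuplicated(words), "phrase words must be distinct")
  assert_that(max_gap >= 0, "max_gap must be >= 0")
  structure(list(words = words, max_gap = as.integer(max_gap),
                 order_free = isTRUE(order_free)),
            class = "phrase_query")
}

#' Compile keyword search terms for a category
#'
#' Each keyword is searched standalone; when a keyword appears adjacent to
#' another keyword inside one of the category's phrases, the concatenated
#' string is also searched with the order preserved.
#'
#' @param keywords Character vector of keywords.
#' @param phrases Character vector of space-joined phrases used to detect
#'   adjacent keywords.
#' @return Character vector of search terms (single- or multi-word).
#' @export
compile_keyword_queries <- function(keywords, phrases = character()) {
  keywords <- unique(tolower(keywords))
  terms <- keywords
  for (p in tolower(phrases)) {
    w <- strsplit(trimws(p), "\\s+")[[1]]
    if (length(w) < 2L) next
    r <- rle(w %in% keywords)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= 2L)
        terms <- c(terms,
                   paste(w[pos:(pos + r$lengths[k] - 1L)], collapse = " "))
      pos <- pos + r$lengths[k]
    }
  }
  unique(terms)
}

# All whole-word, case-insensitive occurrences of `words` in `text`:
# matrix-like tibble word, start, end sorted by start.
locate_words <- function(text, words) {
  hits <- lapply(unique(words), function(w) {
    pat <- if (grepl(" ", w, fixed = TRUE)) {
      # multi-word term: words in order, any whitespace between
      parts <- strsplit(w, " ", fixed = TRUE)[[1]]
      paste0("(?<!\\p{L})",
             paste(vapply(parts, function(p)
               stringi::stri_replace_all_regex(
                 p, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"), character(1)),
               collapse = "\\s+"),
             "(?!\\p{L})")
    } else word_pattern(w)
    loc <- stringi::stri_locate_all_regex(
      text, pat,
      opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE))[[1]]
    if (all(is.na(loc[, 1]))) return(NULL)
    tibble::tibble(word = w, start = as.integer(loc[, 1]),
                   end = as.integer(loc[, 2]))
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L)
    return(tibble::tibble(word = character(), start = integer(),
                          end = integer()))
  out[order(out$start, out$end), , drop = FALSE]
}

# Leftmost non-overlapping phrase instances. An instance is one occurrence
# per query word, in text order, with every consecutive gap (characters
# strictly between spans) <= max_gap. All valid windows are enumerated, then
# selected greedily by earliest end so that overlapping candidate windows
# count once and matched occurrences are consumed.
find_phrase_instances <- function(occ, words, max_gap) {
  occ_by_word <- split(seq_len(nrow(occ)), occ$word)
  if (!all(words %in% names(occ_by_word))) return(list())
  combos <- expand.grid(lapply(words, function(w) occ_by_word[[w]]),
                        KEEP.OUT.ATTRS = FALSE)
  valid <- list()
  for (r in seq_len(nrow(combos))) {
    idx <- as.integer(combos[r, ])
    idx <- idx[order(occ$start[idx])]
    s <- occ$start[idx]; e <- occ$end[idx]
    if (length(s) > 1L) {
      if (any(s[-1L] <= e[-length(e)])) next            # overlapping spans
      if (any(s[-1L] - e[-length(e)] - 1L > max_gap)) next
    }
    valid[[length(valid) + 1L]] <- idx
  }
  if (!length(valid)) return(list())
  w_start <- vapply(valid, function(i) min(occ$start[i]), integer(1))
  w_end <- vapply(valid, function(i) max(occ$end[i]), integer(1))
  ord <- order(w_end, w_start)
  chosen <- list()
  last_end <- 0L
  for (k in ord) {
    if (w_start[k] <= last_end) next
    chosen[[length(chosen) + 1L]] <- valid[[k]]
    last_end <- w_end[k]
  }
  chosen[order(vapply(chosen, function(i) min(occ$start[i]), integer(1)))]
}

#' Match one message against a phrase or keyword query
#'
#' Matching is whole-word and case-insensitive on the cleaned text. For a
#' phrase query, an instance is a leftmost non-overlapping window containing
#' every word of the set with each consecutive pair of matched occurrences
#' separated by at most `max_gap` characters. For a keyword query, every
#' whole-word occurrence of the term is one instance. Each match records
#' the matched spans, the inclusive character gaps, and a secondary gap
#' count excluding whitespace and punctuation.
#'
#' @param clean A `clean_message` (or any list with `id` and `text`).
#' @param query A [compile_phrase_query()] object or a character keyword
#'   term.
#' @return A tibble with one row per instance: `id`, `kind`, `query`,
#'   `start`, `end`, and list-columns `spans`, `gaps`, `gaps_nowsp`.
#' @export
match_message <- function(clean, query) {
  text <- as.character(clean$text %||% "")
  id <- as.integer(clean$id %||% NA_integer_)
  empty <- tibble::tibble(id = integer(), kind = character(),
                          query = character(), start = integer(),
                          end = integer(), spans = list(), gaps = list(),
                          gaps_nowsp = list())
  if (!nzchar(text)) return(empty)

  if (inherits(query, "phrase_query")) {
    occ <- locate_words(text, query$words)
    if (!all(query$words %in% occ$word)) return(empty)
    chains <- find_phrase_instances(occ, query$words, query$max_gap)
    if (!length(chains)) return(empty)
    rows <- lapply(chains, function(ch) {
      sp <- occ[ch, c("start", "end")]
      gaps <- if (nrow(sp) > 1L)
        sp$start[-1L] - sp$end[-nrow(sp)] - 1L else integer()
      gnw <- vapply(seq_along(gaps), function(k) {
        between <- stringi::stri_sub(text, sp$end[k] + 1L, sp$start[k + 1L] - 1L)
        as.integer(stringi::stri_count_regex(between, "[^\\s\\p{P}]"))
      }, integer(1))
      tibble::tibble(id = id, kind = "phrase",
                     query = paste(query$words, collapse = " "),
                     start = sp$start[1], end = sp$end[nrow(sp)],
                     spans = list(sp), gaps = list(gaps),
                     gaps_nowsp = list(gnw))
    })
    return(dplyr::bind_rows(rows))
  }

  # keyword term (possibly multi-word, order preserved)
  term <- tolower(as.character(query))
  occ <- locate_words(text, term)
  if (nrow(occ) == 0L) return(empty)
  tibble::tibble(id = id, kind = "keyword", query = term,
                 start = occ$start, end = occ$end,
                 spans = lapply(seq_len(nrow(occ)), function(k)
                   occ[k, c("start", "end")]),
                 gaps = rep(list(integer()), nrow(occ)),
                 gaps_nowsp = rep(list(integer()), nrow(occ)))
}

#' Retrieve messages by category lexicon
#'
#' Tests every cleaned message against every phrase and keyword query of the
#' selected categories, bins matches by category and kind (phrase/keyword),
#' deduplicates message folders, and builds the aggregate folders
#' (`_all_phrase`, `_all_keyword`, `_all_either`).
#'
#' @param clean A [clean_corpus()] tibble.
#' @param lexicon A [load_lexicon()] lexicon.
#' @param categories Categories to search (default: all in the lexicon);
#'   unknown names are an error.
#' @param max_gap Proximity bound for phrase queries, in characters.
#' @return A `retrieval_set`: list with `matches` (tibble of instances),
#'   `folders` (named list of deduplicated message-id vectors, names
#'   `<category>/<kind>` plus aggregates), `categories`, `max_gap`.
#' @export
retrieve <- function(clean, lexicon, categories = NULL, max_gap = 100L) {
  categories <- categories %||% lexicon$categories
  unknown <- setdiff(categories, lexicon$categories)
  assert_that(length(unknown) == 0L,
              sprintf("unknown categories: %s", paste(unknown, collapse = ", ")))

  # cheap vectorised prefilter: a message can only match a query if every
  # query word occurs as a substring of its lowercased text
  ltext <- stringi::stri_trans_tolower(clean$text)
  candidates <- function(words) {
    hit <- rep(TRUE, length(ltext))
    for (w in unique(unlist(strsplit(words, " ", fixed = TRUE))))
      hit <- hit & stringi::stri_detect_fixed(ltext, w)
    which(hit)
  }

  all_matches <- list()
  for (cat in categories) {
    phrases <- lexicon$phrases$phrase[lexicon$phrases$category == cat]
    keywords <- lexicon$keywords$keyword[lexicon$keywords$category == cat]
    pqueries <- lapply(phrases, compile_phrase_query, max_gap = max_gap)
    kterms <- compile_keyword_queries(keywords, phrases)
    for (q in pqueries) {
      for (i in candidates(q$words)) {
        m <- match_message(list(id = clean$id[i], text = clean$text[i]), q)
        if (nrow(m)) {
          m$category <- cat
          all_matches[[length(all_matches) + 1L]] <- m
        }
      }
    }
    for (term in kterms) {
      for (i in candidates(term)) {
        m <- match_message(list(id = clean$id[i], text = clean$text[i]), term)
        if (nrow(m)) {
          m$category <- cat
          all_matches[[length(all_matches) + 1L]] <- m
        }
      }
    }
  }
  matches <- if (length(all_matches)) dplyr::bind_rows(all_matches)
    else tibble::tibble(id = integer(), kind = character(),
                        query = character(), start = integer(),
                        end = integer(), spans = list(), gaps = list(),
                        gaps_nowsp = list(), category = character())

  folders <- list()
  for (cat in categories) {
    for (kind in c("phrase", "keyword")) {
      ids <- sort(unique(matches$id[matches$category == cat &
                                      matches$kind == kind]))
      folders[[paste0(cat, "/", kind)]] <- ids
    }
  }
  folders[["_all_phrase"]] <- sort(unique(matches$id[matches$kind == "phrase"]))
  folders[["_all_keyword"]] <- sort(unique(matches$id[matches$kind == "keyword"]))
  folders[["_all_either"]] <- sort(unique(matches$id))

  structure(list(matches = matches, folders = folders,
                 categories = categories, max_gap = as.integer(max_gap)),
            class = "retrieval_set")
}

#' Per-category retrieval summary table
#'
#' For each category: number of distinct messages (and instances) matched by
#' phrases, by keywords, and by either, plus a `Total` row in which instance
#' totals are sums across categories and message totals are deduplicated
#' unions.
#'
#' @param set A [retrieve()] result.
#' @return A tibble: `category`, `phrase_messages`, `phrase_instances`,
#'   `keyword_messages`, `keyword_instances`, `either_messages`,
#'   `either_instances`.
#' @export
retrieval_report <- function(set) {
  m <- set$matches
  row_for <- function(cat) {
    sel <- m$category == cat
    tibble::tibble(
      category = cat,
      phrase_messages = length(unique(m$id[sel & m$kind == "phrase"])),
      phrase_instances = sum(sel & m$kind == "phrase"),
      keyword_messages = length(unique(m$id[sel & m$kind == "keyword"])),
      keyword_instances = sum(sel & m$kind == "keyword"),
      either_messages = length(unique(m$id[sel])),
      either_instances = sum(sel)
    )
  }
  out <- dplyr::bind_rows(lapply(set$categories, row_for))
  total <- tibble::tibble(
    category = "Total",
    phrase_messages = length(unique(m$id[m$kind == "phrase"])),
    phrase_instances = sum(m$kind == "phrase"),
    keyword_messages = length(unique(m$id[m$kind == "keyword"])),
    keyword_instances = sum(m$kind == "keyword"),
    either_messages = length(unique(m$id)),
    either_instances = nrow(m)
  )
  dplyr::bind_rows(out, total)
}

#' Deliver retrieved messages as a folder tree
#'
#' Writes one directory per `<category>/<kind>` folder plus the aggregate
#' folders, with each message written once per folder under its
#' `YYYYMMDD_id.txt` name.
#'
#' @param set A [retrieve()] result.
#' @param clean The [clean_corpus()] the retrieval ran on.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a tibble of `folder`, `n_files`.
#' @export
deliver <- function(set, clean, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  counts <- list()
  for (fname in names(set$folders)) {
    dir_path <- file.path(outdir, fname)
    if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
    ids <- set$folders[[fname]]
    for (id in ids) {
      row <- clean[clean$id == id, ]
      write_message_file(list(id = row$id, date = row$date, text = row$text),
                         dir_path)
    }
    counts[[length(counts) + 1L]] <- tibble::tibble(
      folder = fname, n_files = length(ids))
  }
  invisible(dplyr::bind_rows(counts))
}

#' @export
print.retrieval_set <- function(x, ...) {
  cat(sprintf("<retrieval_set> %d match instance(s) in %d message(s), %d categories, max_gap = %d\n",
              nrow(x$matches), length(unique(x$matches$id)),
              length(x$categories), x$max_gap))
  invisible(x)
}
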