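#' Load a category lexicon from a YAML file
#'
#' A lexicon is the human classification scheme mapping clinical categories
#' (optionally with subcategories) to collocated phrases (2- or 3-word
#' strings) and keywords. The YAML layout is one mapping per category:
#'
#' ```yaml
#' systemic disease:
#'   phrases: [herpes zoster, fistula filled obturation]
#'   keywords: [mercury]
#'   subcategories:
#'     cardiovascular:
#'       phrases: [atherosclerotic plaques]
#'       keywords: [cardiac]
#' ```
#'
#' @param path YAML file.
#' @return A `lexicon` object: list with tibbles `phrases` (`category`,
#'   `subcategory`, `phrase`) and `keywords` (`category`, `subcategory`,
#'   `keyword`), and `categories` (character vector).
#' @export
load_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  as_lexicon(raw)
}

#' Build a lexicon from a nested list
#'
#' Programmatic equivalent of [load_lexicon()]; the list mirrors the YAML
#' layout. Phrases must have 2 or 3 words and be unique within a category;
#' keywords are lowercased.
#'
#' @param x Named list of categories.
#' @return A `lexicon` object.
#' @export
as_lexicon <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    out <- list(
      phrases = tibble::tibble(category = character(),
                               subcategory = character(),
                               phrase = character()),
      keywords = tibble::tibble(category = character(),
                                subcategory = character(),
                                keyword = character()),
      categories = character())
    class(out) <- "lexicon"
    return(out)
  }
  assert_that(!is.null(names(x)) && all(nzchar(names(x))),
              "lexicon categories must be named")
  ph <- list(); kw <- list()
  harvest <- function(cat, sub, node) {
    for (p in as.character(node$phrases %||% character())) {
      nw <- length(strsplit(trimws(p), "\\s+")[[1]])
      assert_that(nw %in% 2:3,
                  sprintf("phrase must have 2 or 3 words: '%s' (category '%s')",
                          p, cat))
      ph[[length(ph) + 1L]] <<- tibble::tibble(
        category = cat, subcategory = sub, phrase = tolower(trimws(p)))
    }
    for (k in as.character(node$keywords %||% character()))
      kw[[length(kw) + 1L]] <<- tibble::tibble(
        category = cat, subcategory = sub, keyword = tolower(trimws(k)))
  }
  for (cat in names(x)) {
    node <- x[[cat]]
    # a bare list of phrases is allowed as shorthand
    if (is.null(names(node))) node <- list(phrases = node)
    harvest(cat, NA_character_, node)
    subs <- node$subcategories %||% list()
    for (sub in names(subs)) harvest(cat, sub, subs[[sub]])
  }
  phrases <- if (length(ph)) dplyr::bind_rows(ph)
             else tibble::tibble(category = character(),
                                 subcategory = character(),
                                 phrase = character())
  keywords <- if (length(kw)) dplyr::bind_rows(kw)
              else tibble::tibble(category = character(),
                                  subcategory = character(),
                                  keyword = character())
  dup <- duplicated(phrases[, c("category", "phrase")])
  assert_that(!any(dup),
              sprintf("duplicate phrase within a category: '%s'",
                      paste(phrases$phrase[dup], collapse = "', '")))
  out <- list(phrases = phrases, keywords = keywords, categories = names(x))
  class(out) <- "lexicon"
  out
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d categories, %d phrases, %d keyword instances\n",
              length(x$categories), nrow(x$phrases), nrow(x$keywords)))
  invisible(x)
}

#' Equivalence classes of keyword variants
#'
#' Groups tokens that count as one occurrence class during keyword
#' extraction: morphological variants (plaque/plaques) and closely related
#' terms (cardiac/myocardial). Sets must be disjoint; the class
#' representative is the lexicographically first member.
#'
#' @param sets A list of character vectors (each one class), or a file path
#'   to a plain-text file with one comma- or whitespace-separated class per
#'   line.
#' @return An `equivalence_map` object.
#' @export
equivalence_map <- function(sets = list()) {
  if (is.character(sets) && length(sets) == 1L && file.exists(sets)) {
    lines <- readLines(sets, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    sets <- lapply(lines, function(l)
      strsplit(trimws(l), "[,\\s]+")[[1]])
  }
  sets <- lapply(sets, function(s) sort(unique(tolower(s))))
  sets <- sets[lengths(sets) > 0L]
  all_words <- unlist(sets)
  assert_that(!anyDuplicated(all_words),
              "equivalence classes must be disjoint")
  structure(list(sets = sets), class = "equivalence_map")
}

# token -> class key; unmapped tokens fall through to plural merging or
# themselves.
equiv_key <- function(tokens, equiv = NULL, merge_plurals = TRUE) {
  key <- if (merge_plurals) singular_key(tokens) else tokens
  if (!is.null(equiv) && length(equiv$sets)) {
    members <- unlist(equiv$sets)
    class_id <- rep(seq_along(equiv$sets), lengths(equiv$sets))
    hit <- match(tokens, members)
    key[!is.na(hit)] <- paste0("=eq", class_id[hit[!is.na(hit)]])
  }
  key
}

# simple -s / -es suffix merge: plaques -> plaque, boxes -> box; -ss kept.
singular_key <- function(w) {
  out <- w
  es <- stringi::stri_detect_regex(w, "(?:[sxz]|ch|sh)es$")
  out[es] <- stringi::stri_sub(w[es], 1, -3)
  s <- !es & stringi::stri_detect_regex(w, "[^s]s$")
  out[s] <- stringi::stri_sub(w[s], 1, -2)
  out
}

#' Extract keywords from a set of collocations
#'
#' A keyword is a word occurring at least twice across all word slots of the
#' selected collocations, where each variant or closely related word counts
#' as an occurrence of the same class. Simple plural variants (-s, -es) are
#' auto-merged by a suffix rule (switchable off); semantically related pairs
#' must be supplied via an [equivalence_map()]. Each qualifying class emits
#' one keyword: its representative (lexicographically first member of the
#' equivalence class, or of the observed variants for suffix-merged
#' classes).
#'
#' @param collocations A [top_collocations()] tibble (its `words` column is
#'   used) or a character vector of space-joined phrases.
#' @param equiv An [equivalence_map()], or `NULL`.
#' @param merge_plurals Auto-merge -s/-es variants.
#' @return Sorted character vector of keywords.
#' @export
extract_keywords <- function(collocations, equiv = NULL,
                             merge_plurals = TRUE) {
  phrases <- if (is.data.frame(collocations)) collocations$words
             else as.character(collocations)
  if (length(phrases) == 0L) return(character())
  tokens <- unlist(stringi::stri_split_regex(phrases, "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(character())
  keys <- equiv_key(tokens, equiv, merge_plurals)
  counts <- table(keys)
  hot <- names(counts)[counts >= 2L]
  if (!length(hot)) return(character())
  reps <- vapply(hot, function(k) {
    if (startsWith(k, "=eq")) {
      idx <- as.integer(sub("^=eq", "", k))
      equiv$sets[[idx]][1]
    } else {
      sort(unique(tokens[keys == k]))[1]
    }
  }, character(1))
  sort(unname(reps))
}

#' Check a lexicon against discovered collocations
#'
#' Reports lexicon phrases that are not among the discovered collocations
#' (warnings, not errors — the human scheme may keep phrases the current
#' corpus does not reproduce) and per-category phrase/keyword tallies in the
#' layout of a category-distribution table.
#'
#' @param lex A [load_lexicon()] lexicon.
#' @param collocations A [top_collocations()] tibble or character vector of
#'   space-joined phrases.
#' @return A list: `missing` (tibble `category`, `phrase`), `tallies`
#'   (tibble `category`, `n_phrases`, `pct_phrases`, `n_keywords`,
#'   `pct_keywords`), and `totals` (list with `n_phrases`,
#'   `n_keyword_instances`, `n_unique_keywords`, `n_categories`).
#' @export
validate_lexicon <- function(lex, collocations = character()) {
  discovered <- if (is.data.frame(collocations)) collocations$words
                else as.character(collocations)
  missing <- lex$phrases[!(lex$phrases$phrase %in% tolower(discovered)),
                         c("category", "phrase")]
  cats <- lex$categories
  tallies <- tibble::tibble(
    category = cats,
    n_phrases = vapply(cats, function(c)
      sum(lex$phrases$category == c), integer(1), USE.NAMES = FALSE),
    n_keywords = vapply(cats, function(c)
      sum(lex$keywords$category == c), integer(1), USE.NAMES = FALSE)
  )
  tot_ph <- sum(tallies$n_phrases)
  tot_kw <- sum(tallies$n_keywords)
  tallies$pct_phrases <- if (tot_ph > 0)
    vapply(tallies$n_phrases, percent, numeric(1), denominator = tot_ph,
           decimals = 0L) else rep(NA_real_, nrow(tallies))
  tallies$pct_keywords <- if (tot_kw > 0)
    vapply(tallies$n_keywords, percent, numeric(1), denominator = tot_kw,
           decimals = 0L) else rep(NA_real_, nrow(tallies))
  tallies <- tallies[, c("category", "n_phrases", "pct_phrases",
                         "n_keywords", "pct_keywords")]
  list(
    missing = missing,
    tallies = tallies,
    totals = list(
      n_phrases = tot_ph,
      n_keyword_instances = tot_kw,
      n_unique_keywords = length(unique(lex$keywords$keyword)),
      n_categories = length(cats)
    )
  )
}
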