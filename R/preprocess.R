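#' Noise rule set for message cleaning
#'
#' Loads the pattern groups used to strip reply/forward content and
#' boilerplate from message bodies. The default set ships with the package
#' (`inst/extdata/noise_patterns.txt`) and approximates the usual noise
#' classes of mailing-list email: quoted replies and attribution lines,
#' forwarded-message blocks, signatures, advertisements and footers,
#' virus/spam-free notices, mail-client notices, and embedded-image
#' placeholders. Every group can be switched off and the file is editable:
#' one `<group><TAB><regex>` entry per line, `#` comments.
#'
#' @param path Pattern file; `NULL` uses the shipped default.
#' @param disable Character vector of group names to switch off.
#' @return A `noise_rules` object (named list of pattern groups plus an
#'   `enabled` flag per group).
#' @export
noise_rules <- function(path = NULL, disable = character()) {
  path <- path %||% system.file("extdata", "noise_patterns.txt",
                                package = "clinicolloc")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- stringi::stri_split_fixed(lines, "\t", n = 2)
  ok <- lengths(parts) == 2L
  assert_that(all(ok), "malformed noise pattern line (expected <group>\\t<regex>)")
  grp <- vapply(parts, `[[`, character(1), 1)
  pat <- vapply(parts, `[[`, character(1), 2)
  patterns <- split(pat, grp)
  enabled <- stats::setNames(!(names(patterns) %in% disable), names(patterns))
  structure(list(patterns = patterns, enabled = enabled),
            class = "noise_rules")
}

active_patterns <- function(rules, group) {
  if (!group %in% names(rules$patterns)) return(character())
  if (!isTRUE(rules$enabled[[group]])) return(character())
  rules$patterns[[group]]
}

line_matches <- function(lines, patterns) {
  hit <- rep(FALSE, length(lines))
  for (p in patterns)
    hit <- hit | stringi::stri_detect_regex(lines, p)
  hit
}

#' Strip quoted replies and forwarded blocks
#'
#' Removes threaded content from a message body: lines carrying quote
#' markers (leading `>` or `|`), attribution lines ("On ... wrote:"), and
#' everything from a forwarded-message marker to the end. The line order of
#' surviving text is preserved; a body with no such content is returned
#' unchanged.
#'
#' @param body Message body text (single string, `\n`-separated lines).
#' @param rules A [noise_rules()] object.
#' @return The body with reply/forward content removed.
#' @export
strip_reply_content <- function(body, rules = noise_rules()) {
  lines <- split_lines(body)
  if (length(lines) == 0L) return(body)
  fwd <- line_matches(lines, active_patterns(rules, "forwarded_block"))
  if (any(fwd)) lines <- lines[seq_len(which(fwd)[1] - 1L)]
  drop <- line_matches(lines, active_patterns(rules, "quoted_reply")) |
    line_matches(lines, active_patterns(rules, "attribution"))
  paste(lines[!drop], collapse = "\n")
}

#' Strip signatures, advertisements, and notice boilerplate
#'
#' Removes (a) everything from a signature delimiter line (`-- `) to the end
#' of the message, (b) a trailing run of up to 6 signature-like lines
#' (credential, phone, or URL tokens), applied to a fixed point, and
#' (c) any line matching an advertisement/footer, virus-notice, mail-client
#' notice, or embedded-image pattern.
#'
#' @inheritParams strip_reply_content
#' @return A list with `text` (the stripped body) and `removal_log` (a
#'   tibble of `rule`, `n_lines`, `n_chars` for each rule that fired).
#' @export
strip_boilerplate <- function(body, rules = noise_rules()) {
  lines <- split_lines(body)
  log <- list()
  note <- function(rule, removed) {
    if (length(removed))
      log[[length(log) + 1L]] <<- tibble::tibble(
        rule = rule, n_lines = length(removed),
        n_chars = sum(nchar(removed)))
  }

  delim <- line_matches(lines, active_patterns(rules, "signature_delim"))
  if (any(delim)) {
    cut <- which(delim)[1]
    note("signature_delim", lines[cut:length(lines)])
    lines <- lines[seq_len(cut - 1L)]
  }

  sig_pats <- active_patterns(rules, "signature_line")
  if (length(sig_pats)) {
    repeat {
      nonblank <- which(nzchar(trimws(lines)))
      if (!length(nonblank)) break
      hits <- line_matches(lines, sig_pats) & nzchar(trimws(lines))
      run <- integer()
      for (i in rev(nonblank)) {
        if (hits[i]) run <- c(i, run) else break
      }
      if (!length(run) || length(run) > 6L) break
      note("signature_heuristic", lines[run[1]:length(lines)])
      lines <- lines[seq_len(run[1] - 1L)]
    }
  }

  for (group in c("advertisement", "virus_notice", "client_notice", "image_ref")) {
    hit <- line_matches(lines, active_patterns(rules, group))
    if (any(hit)) {
      note(group, lines[hit])
      lines <- lines[!hit]
    }
  }

  list(
    text = paste(lines, collapse = "\n"),
    removal_log = if (length(log)) dplyr::bind_rows(log)
      else tibble::tibble(rule = character(), n_lines = integer(),
                          n_chars = integer())
  )
}

#' Replace listed names and places with a neutral placeholder
#'
#' Whole-word, case-insensitive occurrences of listed names and places are
#' replaced by a short placeholder token (`"xx"` by default, short enough
#' that the downstream token length filter removes it automatically). All
#' other text is untouched; empty lists give the identity transform. Word
#' boundaries are letter/non-letter transitions, so `"smithing"` is not
#' touched by the name `"smith"`.
#'
#' @param text Cleaned message text.
#' @param names,places Lowercase word vectors (name list and place
#'   gazetteer).
#' @param placeholder Replacement token.
#' @return Deidentified text.
#' @export
deidentify <- function(text, names = character(), places = character(),
                       placeholder = "xx") {
  words <- unique(c(names, places))
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(text)
  stringi::stri_replace_all_regex(
    text, word_pattern(words), placeholder,
    opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE)
  )
}

#' Clean one raw message
#'
#' Composes the cleaning stages in the workflow order: whitespace
#' normalization, reply/forward stripping, boilerplate stripping,
#' deidentification, and a final normalization pass that collapses runs of
#' horizontal whitespace and drops emptied lines (newlines between surviving
#' lines are preserved). Cleaning is idempotent.
#'
#' @param raw A list or one-row data frame with `id`, `date`, `body`.
#' @param rules A [noise_rules()] object.
#' @inheritParams deidentify
#' @return A `clean_message` list: `id`, `date`, `text`, `removal_log`.
#' @export
clean_message <- function(raw, rules = noise_rules(), names = character(),
                          places = character()) {
  body <- as.character(raw$body %||% "")
  if (length(body) == 0L || is.na(body)) body <- ""
  x0 <- normalize_ws(body)
  x1 <- strip_reply_content(x0, rules)
  sb <- strip_boilerplate(x1, rules)
  x2 <- deidentify(sb$text, names, places)
  text <- normalize_ws(x2)

  log <- sb$removal_log
  n_reply <- nchar(x0) - nchar(x1)
  if (n_reply > 0L)
    log <- dplyr::bind_rows(
      tibble::tibble(rule = "reply_content", n_lines = NA_integer_,
                     n_chars = n_reply),
      log)
  date <- raw$date
  if (is.list(date)) date <- date[[1]]
  structure(list(id = as.integer(raw$id), date = date, text = text,
                 removal_log = log),
            class = "clean_message")
}

#' Clean every message in a corpus
#'
#' @param corpus A [read_mailbox()] corpus.
#' @inheritParams clean_message
#' @return A tibble of class `clean_corpus`: `id`, `date`, `text`, and a
#'   `removal_log` list-column.
#' @export
clean_corpus <- function(corpus, rules = noise_rules(), names = character(),
                         places = character()) {
  cleaned <- lapply(seq_len(nrow(corpus)), function(i)
    clean_message(corpus[i, ], rules, names, places))
  out <- tibble::tibble(
    id = vapply(cleaned, `[[`, integer(1), "id"),
    date = as.POSIXct(vapply(cleaned, function(m) as.numeric(m$date),
                             numeric(1)),
                      origin = "1970-01-01", tz = "UTC"),
    text = vapply(cleaned, `[[`, character(1), "text"),
    removal_log = lapply(cleaned, `[[`, "removal_log")
  )
  class(out) <- c("clean_corpus", class(out))
  out
}

split_lines <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character())
  stringi::stri_split_fixed(x, "\n")[[1]]
}

# Collapse runs of spaces/tabs to one space, trim line ends, drop empty lines.
normalize_ws <- function(x) {
  lines <- split_lines(x)
  if (!length(lines)) return("")
  lines <- trimws(stringi::stri_replace_all_regex(lines, "[ \t\r]+", " "))
  paste(lines[nzchar(lines)], collapse = "\n")
}
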