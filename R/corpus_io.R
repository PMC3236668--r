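#' Read a mailbox into a date-ordered corpus
#'
#' Ingests a mailbox and returns a corpus tibble sorted by posting date, with
#' stable integer identifiers `1..N` assigned in date order. Date ties are
#' broken by original mailbox order, so re-reading the same mailbox always
#' yields identical identifiers. Messages whose date header cannot be parsed
#' are kept, placed after all dated messages (in mailbox order), and flagged
#' via the `dated` column.
#'
#' @param path Path to an mbox file (`format = "mbox"`), or to a directory of
#'   RFC-822 message files (`"eml-dir"`), or to a directory of plain-text
#'   files whose first line is a `Date: ...` header (`"txt-dir"`).
#' @param format One of `"mbox"`, `"eml-dir"`, `"txt-dir"`.
#' @param quiet Suppress the ingestion message count.
#'
#' @return A tibble of class `mail_corpus` with columns `id`, `date`
#'   (POSIXct, UTC), `author`, `subject`, `body`, `dated` (logical), and a
#'   `span` attribute holding the earliest and latest parseable dates
#'   (`NULL` for an empty corpus).
#'
#' @details Only the first text part of a message is used; MIME multipart
#'   decoding and attachments are out of scope. Unparseable message blocks
#'   are skipped with a warning.
#' @export
read_mailbox <- function(path, format = c("mbox", "eml-dir", "txt-dir"),
                         quiet = FALSE) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("path does not exist: %s", path))

  msgs <- switch(format,
    "mbox"    = read_mbox_messages(path),
    "eml-dir" = read_eml_dir(path),
    "txt-dir" = read_txt_dir(path)
  )

  n_skipped <- attr(msgs, "n_skipped") %||% 0L
  if (n_skipped > 0L)
    warning(sprintf("skipped %d unparseable message(s)", n_skipped), call. = FALSE)

  corpus <- as_mail_corpus(msgs)
  if (!quiet)
    message(sprintf("ingested %d message(s) from %s", nrow(corpus), path))
  corpus
}

# Sort stably by date (undated last, mailbox order preserved) and assign ids.
as_mail_corpus <- function(msgs) {
  if (nrow(msgs) == 0L) {
    out <- tibble::tibble(
      id = integer(), date = as.POSIXct(character(), tz = "UTC"),
      author = character(), subject = character(), body = character(),
      dated = logical()
    )
    attr(out, "span") <- NULL
    class(out) <- c("mail_corpus", class(out))
    return(out)
  }
  dated <- !is.na(msgs$date)
  ord <- order(!dated, as.numeric(msgs$date), seq_len(nrow(msgs)),
               na.last = FALSE)
  out <- msgs[ord, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$dated <- !is.na(out$date)
  out <- tibble::as_tibble(out[, c("id", "date", "author", "subject", "body", "dated")])
  attr(out, "span") <- if (any(out$dated)) range(out$date[out$dated]) else NULL
  class(out) <- c("mail_corpus", class(out))
  out
}

MONTHS3 <- c(jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
             jul = 7L, aug = 8L, sep = 9L, oct = 10L, nov = 11L, dec = 12L)

#' Parse a mail date header
#'
#' Accepts RFC-2822 dates (`Thu, 18 Apr 2008 09:30:00 -0400`) and ISO-8601
#' dates (`2008-04-18 09:30:00`), with or without a time component. Month
#' names are resolved with an explicit table so parsing does not depend on
#' the locale. Numeric zone offsets are applied; anything unparseable gives
#' `NA`.
#'
#' @param x Character vector of date headers.
#' @return POSIXct vector in UTC.
#' @export
parse_mail_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")

  rfc <- stringi::stri_match_first_regex(
    x,
    "^(?:[A-Za-z]{3},\\s*)?(\\d{1,2})\\s+([A-Za-z]{3})[a-z]*\\s+(\\d{4})(?:\\s+(\\d{1,2}):(\\d{2})(?::(\\d{2}))?)?(?:\\s+([+-]\\d{4}))?"
  )
  iso <- stringi::stri_match_first_regex(
    x,
    "^(\\d{4})-(\\d{2})-(\\d{2})(?:[T ](\\d{1,2}):(\\d{2})(?::(\\d{2}))?)?(?:\\s*([+-]\\d{4})|Z)?"
  )

  mk <- function(y, mo, d, h, mi, s, off) {
    h <- ifelse(is.na(h), 0, h); mi <- ifelse(is.na(mi), 0, mi)
    s <- ifelse(is.na(s), 0, s)
    t <- ISOdatetime(y, mo, d, h, mi, s, tz = "UTC")
    off_min <- ifelse(is.na(off), 0,
                      sign_num(off) * (abs_hhmm(off) %/% 100 * 60 + abs_hhmm(off) %% 100))
    t - off_min * 60
  }

  use_iso <- !is.na(iso[, 1])
  if (any(use_iso)) {
    out[use_iso] <- mk(
      as.integer(iso[use_iso, 2]), as.integer(iso[use_iso, 3]),
      as.integer(iso[use_iso, 4]), suppressWarnings(as.integer(iso[use_iso, 5])),
      suppressWarnings(as.integer(iso[use_iso, 6])),
      suppressWarnings(as.numeric(iso[use_iso, 7])), iso[use_iso, 8]
    )
  }
  use_rfc <- !use_iso & !is.na(rfc[, 1])
  if (any(use_rfc)) {
    mo <- MONTHS3[tolower(rfc[use_rfc, 3])]
    out[use_rfc] <- mk(
      as.integer(rfc[use_rfc, 4]), mo, as.integer(rfc[use_rfc, 2]),
      suppressWarnings(as.integer(rfc[use_rfc, 5])),
      suppressWarnings(as.integer(rfc[use_rfc, 6])),
      suppressWarnings(as.numeric(rfc[use_rfc, 7])), rfc[use_rfc, 8]
    )
  }
  out
}

sign_num <- function(off) ifelse(substr(off, 1, 1) == "-", -1, 1)
abs_hhmm <- function(off) as.integer(substr(off, 2, 5))

# Split an mbox file on "From " separator lines and parse each block.
read_mbox_messages <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) return(empty_raw_messages())
  starts <- which(stringi::stri_startswith_fixed(lines, "From "))
  if (length(starts) == 0L) {
    attr_skip(empty_raw_messages(), 1L)
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
    blocks <- Map(function(s, e) lines[(s + 1L):e], starts, ends)
    parse_message_blocks(blocks)
  }
}

read_eml_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) return(empty_raw_messages())
  blocks <- lapply(files, readLines, warn = FALSE, encoding = "UTF-8")
  parse_message_blocks(blocks)
}

# Plain-text messages: first line "Date: ...", optional Author:/Subject:
# lines, then the body.
read_txt_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) return(empty_raw_messages())
  blocks <- lapply(files, readLines, warn = FALSE, encoding = "UTF-8")
  parse_message_blocks(blocks)
}

empty_raw_messages <- function() {
  tibble::tibble(date = as.POSIXct(character(), tz = "UTC"),
                 author = character(), subject = character(),
                 body = character())
}

attr_skip <- function(x, n) { attr(x, "n_skipped") <- n; x }

# Headers end at the first blank line; continuation lines (leading
# whitespace) are unfolded onto the previous header.
parse_message_blocks <- function(blocks) {
  n_skipped <- 0L
  rows <- lapply(blocks, function(b) {
    if (length(b) == 0L || !any(nzchar(trimws(b[1])))) {
      # no header line at all: unparseable block
      return(NULL)
    }
    # headers: leading run of "Name: value" lines plus their continuations
    hdr_like <- stringi::stri_detect_regex(b, "^[A-Za-z][A-Za-z-]*:")
    cont_like <- stringi::stri_detect_regex(b, "^[ \t]+\\S")
    is_hdr <- logical(length(b))
    for (i in seq_along(b)) {
      ok <- hdr_like[i] || (i > 1 && cont_like[i] && is_hdr[i - 1L])
      if (!ok) break
      is_hdr[i] <- TRUE
    }
    hdr_end <- sum(is_hdr)
    if (hdr_end == 0L) return(NULL)
    hdr <- b[seq_len(hdr_end)]
    body_start <- hdr_end + 1L
    while (body_start <= length(b) && !nzchar(trimws(b[body_start])))
      body_start <- body_start + 1L
    body <- if (body_start <= length(b)) b[body_start:length(b)] else character()
    while (length(body) && !nzchar(trimws(body[length(body)])))
      body <- body[-length(body)]
    # unfold continuations
    cont <- stringi::stri_detect_regex(hdr, "^[ \t]") & seq_along(hdr) > 1
    if (any(cont)) {
      for (i in rev(which(cont))) {
        hdr[i - 1L] <- paste0(hdr[i - 1L], " ", trimws(hdr[i]))
      }
      hdr <- hdr[!cont]
    }
    get_hdr <- function(name) {
      hit <- stringi::stri_detect_regex(hdr, paste0("^", name, ":"),
                                        case_insensitive = TRUE)
      if (!any(hit)) return(NA_character_)
      trimws(sub("^[^:]+:", "", hdr[which(hit)[1]]))
    }
    list(
      date = get_hdr("Date"),
      author = get_hdr("From") %na% get_hdr("Author") %na% "unknown",
      subject = get_hdr("Subject") %na% "",
      body = paste(body, collapse = "\n")
    )
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_skipped <- sum(!keep)
  rows <- rows[keep]
  out <- tibble::tibble(
    date = parse_mail_date(vapply(rows, `[[`, character(1), "date")),
    author = vapply(rows, `[[`, character(1), "author"),
    subject = vapply(rows, `[[`, character(1), "subject"),
    body = vapply(rows, `[[`, character(1), "body")
  )
  attr_skip(out, n_skipped)
}

`%na%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Write a cleaned message to a folder
#'
#' The filename is `<YYYYMMDD>_<id>.txt` (date of posting plus the corpus
#' identifier), so lexicographic order is chronological and every message in
#' a corpus maps to a distinct name. Writing the same message twice is
#' idempotent; a name collision with *different* content signals a
#' duplicated identifier and is an error.
#'
#' @param msg A list or one-row data frame with fields `id`, `date`, `text`.
#' @param folder Existing or creatable output directory.
#' @return The filename (invisibly returns the full path as an attribute).
#' @export
write_message_file <- function(msg, folder) {
  if (!dir.exists(folder)) dir.create(folder, recursive = TRUE)
  id <- as.integer(msg$id)
  date <- msg$date
  if (is.list(date)) date <- date[[1]]
  fname <- sprintf("%s_%d.txt", format(date, "%Y%m%d", tz = "UTC"), id)
  path <- file.path(folder, fname)
  text <- as.character(msg$text)
  if (file.exists(path)) {
    old <- readChar(path, file.size(path), useBytes = TRUE)
    if (!identical(old, enc2utf8(text)))
      stop(sprintf("filename collision with different content: %s", fname),
           call. = FALSE)
    return(structure(fname, path = path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
  structure(fname, path = path)
}

#' @export
print.mail_corpus <- function(x, ...) {
  span <- attr(x, "span")
  cat(sprintf("<mail_corpus> %d message(s)", nrow(x)))
  if (!is.null(span))
    cat(sprintf(", %s to %s", format(span[1], "%Y-%m-%d"),
                format(span[2], "%Y-%m-%d")))
  cat("\n")
  NextMethod()
}
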