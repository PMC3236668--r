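#' Keyword-in-context (KWIC) concordance
#'
#' Returns fixed-width lines of context around each whole-word,
#' case-insensitive occurrence of a target word, in corpus date order then
#' offset order within a message, up to `max_lines` lines. Each line is
#' exactly `width` characters with the target centred: the left context gets
#' `floor((width - nchar(target)) / 2)` characters, and lines near text
#' edges are space-padded. Newlines in the message text are shown as spaces.
#'
#' @param clean A [clean_corpus()] tibble.
#' @param target A single word.
#' @param width Line width in characters (must be at least
#'   `nchar(target) + 2`).
#' @param max_lines Maximum number of lines returned.
#' @return A tibble: `id`, `line` (the fixed-width text), `target_start`
#'   (position of the target within the line). An absent target gives zero
#'   rows.
#' @export
kwic <- function(clean, target, width = 80L, max_lines = 25L) {
  assert_that(length(target) == 1L && nzchar(target), "target must be one word")
  assert_that(width >= nchar(target) + 2L, "width too small for target")
  assert_that(max_lines >= 1L, "max_lines must be >= 1")

  left <- (width - nchar(target)) %/% 2L
  pat <- word_pattern(target)
  out <- list()
  n_found <- 0L
  for (i in seq_len(nrow(clean))) {
    if (n_found >= max_lines) break
    text <- stringi::stri_replace_all_fixed(clean$text[i], "\n", " ")
    loc <- stringi::stri_locate_all_regex(
      text, pat,
      opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE))[[1]]
    if (all(is.na(loc[, 1]))) next
    for (j in seq_len(nrow(loc))) {
      if (n_found >= max_lines) break
      s <- loc[j, 1]; e <- loc[j, 2]
      lpad <- max(0L, left - (s - 1L))
      lctx <- stringi::stri_sub(text, max(1L, s - left), s - 1L)
      line <- paste0(strrep(" ", lpad), lctx, stringi::stri_sub(text, s, e))
      line <- stringi::stri_sub(paste0(
        line, stringi::stri_sub(text, e + 1L, e + width), strrep(" ", width)),
        1L, width)
      n_found <- n_found + 1L
      out[[n_found]] <- tibble::tibble(id = clean$id[i], line = line,
                                       target_start = left + 1L)
    }
  }
  if (!length(out))
    return(tibble::tibble(id = integer(), line = character(),
                          target_start = integer()))
  dplyr::bind_rows(out)
}
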