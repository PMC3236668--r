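`%||%` <- function(x, y) if (is.null(x)) y else x

# Whole-word regex for retrieval/deidentification/KWIC: word boundary is a
# letter/non-letter transition (digits and underscores do NOT join words).
word_pattern <- function(words) {
  esc <- stringi::stri_replace_all_regex(words, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1")
  paste0("(?<!\\p{L})(?:", paste(esc, collapse = "|"), ")(?!\\p{L})")
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
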