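small_cfg <- function(seed = 1, n = 50, plantings = list(), ...) {
  sim_config(seed = seed, n_messages = n, n_subscribers = 30, n_posting = 15,
             group_sizes = c(top = 2, mid = 3),
             group_shares = c(top = 0.5, mid = 0.25),
             plantings = plantings, ...)
}

test_that("zero messages give an empty mailbox and manifest", {
  g <- generate_corpus(sim_config(seed = 1, n_messages = 0, n_posting = 0,
                                  group_sizes = c(top = 0, mid = 0)))
  expect_equal(nrow(g$corpus), 0L)
  expect_equal(nrow(g$manifest$plantings), 0L)
})

test_that("generation is deterministic: same seed, byte-identical output", {
  cfg <- small_cfg(seed = 99, plantings = list(
    list(category = "c", words = c("herpes", "zoster"), n = 5, gaps = 10)))
  m1 <- withr::local_tempfile(); m2 <- withr::local_tempfile()
  g1 <- generate_corpus(cfg, mbox = m1)
  g2 <- generate_corpus(cfg, mbox = m2)
  expect_identical(g1$corpus$body, g2$corpus$body)
  expect_identical(g1$manifest$plantings, g2$manifest$plantings)
  expect_identical(readLines(m1, warn = FALSE), readLines(m2, warn = FALSE))
  # and a different seed gives a different corpus
  g3 <- generate_corpus(small_cfg(seed = 100))
  expect_false(identical(g1$corpus$body, g3$corpus$body))
})

test_that("planted gaps control retrievability and the manifest is the oracle", {
  cfg <- small_cfg(seed = 7, plantings = list(
    list(category = "c", words = c("herpes", "zoster"), n = 5,
         gaps = c(1, 10, 100)),
    list(category = "c", words = c("herpes", "zoster"), n = 2, gaps = 150)))
  g <- generate_corpus(cfg)
  pl <- g$manifest$plantings
  retrievable <- vapply(pl$gaps, function(x) all(x <= 100), logical(1))
  expect_equal(sum(retrievable), 5L)
  expect_equal(sum(!retrievable), 2L)
  # every planted item is locatable verbatim in the raw body
  for (k in seq_len(nrow(pl)))
    expect_true(grepl(pl$text[k], g$corpus$body[g$corpus$id == pl$id[k]],
                      fixed = TRUE))
})

test_that("infeasible planting quotas are rejected", {
  expect_error(small_cfg(n = 10, plantings = list(
    list(category = "c", words = c("a", "b"), n = 11))), "infeasible")
})

test_that("mbox output re-ingests to the identical corpus", {
  cfg <- small_cfg(seed = 13)
  mbox <- withr::local_tempfile(fileext = ".mbox")
  g <- generate_corpus(cfg, mbox = mbox)
  back <- read_mailbox(mbox, "mbox", quiet = TRUE)
  expect_identical(back$id, g$corpus$id)
  expect_identical(back$body, g$corpus$body)
  expect_identical(back$author, g$corpus$author)
  expect_true(all(abs(as.numeric(back$date) - as.numeric(g$corpus$date)) < 1))
})

test_that("participation is calibrated to the configured group shares", {
  g <- generate_corpus(sim_config(seed = 5, n_messages = 14576))
  counts <- sort(table(g$corpus$author), decreasing = TRUE)
  expect_equal(length(counts), 245L)
  expect_equal(sum(counts), 14576L)
  # core group of 21 authors holds half the traffic by construction
  expect_equal(sum(counts[1:21]) / 14576, 0.50, tolerance = 1e-3)
  expect_equal(sum(counts[1:50]) / 14576, 0.75, tolerance = 1e-3)

  # cumulative participation curve is monotone, non-decreasing, reaching 1
  curve <- cumsum(as.integer(counts)) / sum(counts)
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve[length(curve)], 1)
})

test_that("retrieval scored against the manifest separates cleaning effects", {
  # a phrase planted only inside a quoted block: cleaning removes it
  corpus <- mk_corpus(
    "filler line\n> quoted herpes zoster inside reply\nmore filler")
  lex <- as_lexicon(list(c1 = list(phrases = list("herpes zoster"))))
  cleaned <- clean_corpus(corpus)
  expect_equal(nrow(retrieve(cleaned, lex)$matches), 0L)
  # with cleaning disabled (raw body as text) the match is counted
  raw_as_clean <- mk_clean(corpus$body)
  expect_equal(nrow(retrieve(raw_as_clean, lex)$matches), 1L)
})

test_that("perfect pipeline scores recall 1 and precision 1; vacuous recall is 1", {
  cfg <- small_cfg(seed = 21, n = 80, plantings = list(
    list(category = "c1", words = c("herpes", "zoster"), n = 10,
         gaps = c(1, 50, 100)),
    list(category = "c1", words = "mercury", kind = "keyword", n = 6)))
  g <- generate_corpus(cfg)
  cl <- clean_corpus(g$corpus)
  lex <- as_lexicon(list(c1 = list(phrases = list("herpes zoster"),
                                   keywords = list("mercury"))))
  sc <- score_against_manifest(retrieve(cl, lex), g$manifest)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)

  # all plantings beyond the gap bound: 0 retrievable, recall vacuously 1
  cfg2 <- small_cfg(seed = 22, plantings = list(
    list(category = "c1", words = c("herpes", "zoster"), n = 4, gaps = 150)))
  g2 <- generate_corpus(cfg2)
  sc2 <- score_against_manifest(retrieve(clean_corpus(g2$corpus), lex),
                                g2$manifest)
  expect_equal(sc2$recall, 1)
  expect_equal(sum(sc2$detail$retrievable), 0L)
})
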