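test_that("phrase queries require 2-3 distinct words", {
  q <- compile_phrase_query(c("herpes", "zoster"))
  expect_s3_class(q, "phrase_query")
  expect_equal(q$max_gap, 100L)
  expect_error(compile_phrase_query("mercury"), "2 or 3")
  expect_error(compile_phrase_query(c("a", "b", "c", "d")), "2 or 3")
})

test_that("order-free matching finds reordered words", {
  q <- compile_phrase_query(c("mutans", "streptococci"))
  msg <- list(id = 1L, text = "the streptococci mutans colonies grew")
  m <- match_message(msg, q)
  expect_equal(nrow(m), 1L)
  expect_equal(m$kind, "phrase")
})

test_that("the gap boundary is exact: 100 characters match, 101 do not", {
  q <- compile_phrase_query(c("herpes", "zoster"), max_gap = 100)
  at100 <- list(id = 1L, text = paste0("herpes", gap_sep(100), "zoster"))
  at101 <- list(id = 2L, text = paste0("herpes", gap_sep(101), "zoster"))
  expect_equal(nrow(match_message(at100, q)), 1L)
  expect_equal(nrow(match_message(at101, q)), 0L)
  # recorded gap is the inclusive character count
  expect_equal(match_message(at100, q)$gaps[[1]], 100L)
})

test_that("matches record a secondary gap excluding whitespace and punctuation", {
  q <- compile_phrase_query(c("fistula", "obturation"))
  msg <- list(id = 1L, text = "fistula (pus filled canal) before obturation")
  m <- match_message(msg, q)
  expect_equal(nrow(m), 1L)
  g <- m$gaps[[1]]; gn <- m$gaps_nowsp[[1]]
  expect_lt(gn, g)  # spaces and parentheses are not counted
  expect_equal(gn, nchar("pusfilledcanalbefore"))
})

test_that("matching is whole-word; empty messages never match", {
  q <- compile_phrase_query(c("plaque", "control"))
  expect_equal(nrow(match_message(
    list(id = 1L, text = "plaques control group"), q)), 0L)
  expect_equal(nrow(match_message(list(id = 2L, text = ""), q)), 0L)
  # keyword instances: one per whole-word occurrence
  m <- match_message(list(id = 3L, text = "mercury here, mercury there"),
                     "mercury")
  expect_equal(nrow(m), 2L)
  expect_equal(m$kind, rep("keyword", 2))
})

test_that("adjacent keywords compile to an order-preserving concatenated term", {
  terms <- compile_keyword_queries(c("mutans", "streptococci"),
                                   phrases = "mutans streptococci presence")
  expect_true("mutans streptococci" %in% terms)
  m <- match_message(list(id = 1L, text = "found mutans streptococci here"),
                     "mutans streptococci")
  expect_equal(nrow(m), 1L)
  # reversed order does not match the concatenated term
  m2 <- match_message(list(id = 1L, text = "found streptococci mutans here"),
                      "mutans streptococci")
  expect_equal(nrow(m2), 0L)
})

test_that("overlapping candidate windows count once (leftmost, consuming)", {
  q <- compile_phrase_query(c("herpes", "zoster"), max_gap = 100)
  # one zoster between two herpes: exactly one instance
  m <- match_message(list(id = 1L, text = "herpes then zoster then herpes"), q)
  expect_equal(nrow(m), 1L)
  # two full occurrences: two instances
  m2 <- match_message(
    list(id = 1L, text = "herpes zoster ... more ... herpes zoster"), q)
  expect_equal(nrow(m2), 2L)
})

test_that("retrieve bins by category, deduplicates folders, and builds aggregates", {
  clean <- mk_clean(c(
    "nothing relevant at all",
    "patient with herpes zoster on the palate",
    "suspect herpes zoster again; also prescribed amoxicillin",
    paste0("mercury levels and intravenous", gap_sep(5), "bisphosphonates")))
  lex <- mk_lexicon()
  rs <- retrieve(clean, lex)
  expect_equal(rs$folders[["systemic disease/phrase"]], c(2L, 3L))
  expect_equal(rs$folders[["medication/phrase"]], 4L)
  expect_equal(rs$folders[["medication/keyword"]], 3L)
  expect_equal(rs$folders[["systemic disease/keyword"]], 4L)
  expect_equal(rs$folders[["_all_phrase"]], c(2L, 3L, 4L))
  expect_equal(rs$folders[["_all_either"]], c(2L, 3L, 4L))

  # aggregates are unions of the per-category folders
  expect_equal(rs$folders[["_all_keyword"]],
               sort(unique(c(rs$folders[["systemic disease/keyword"]],
                             rs$folders[["medication/keyword"]]))))

  # a message matching two categories appears once per category folder
  expect_error(retrieve(clean, lex, categories = "nonexistent"), "unknown")

  # dedup idempotence: retrieving twice yields identical results
  rs2 <- retrieve(clean, lex)
  expect_identical(rs$folders, rs2$folders)
  expect_equal(nrow(rs$matches), nrow(rs2$matches))
})

test_that("phrase matching is monotone in max_gap", {
  texts <- vapply(c(1, 40, 80, 99, 100, 101, 140), function(g)
    paste0("herpes", gap_sep(g), "zoster"), character(1))
  clean <- mk_clean(texts)
  lex <- as_lexicon(list(cat = list(phrases = list("herpes zoster"))))
  prev <- integer()
  for (g in c(0, 50, 100, 150)) {
    ids <- retrieve(clean, lex, max_gap = g)$folders[["cat/phrase"]]
    expect_true(all(prev %in% ids),
                info = sprintf("gap %d contains gap-smaller matches", g))
    prev <- ids
  }
  expect_equal(retrieve(clean, lex, max_gap = 100)$folders[["cat/phrase"]],
               which(c(1, 40, 80, 99, 100, 101, 140) <= 100))
})

test_that("retrieval_report totals: instances sum, messages deduplicate", {
  clean <- mk_clean(c(
    "herpes zoster and mercury in one message",
    "intravenous bisphosphonates infusion",
    "mercury alone"))
  rs <- retrieve(clean, mk_lexicon())
  rep <- retrieval_report(rs)
  tot <- rep[rep$category == "Total", ]
  per <- rep[rep$category != "Total", ]
  expect_equal(tot$phrase_instances, sum(per$phrase_instances))
  expect_equal(tot$keyword_instances, sum(per$keyword_instances))
  expect_equal(tot$either_instances,
               tot$phrase_instances + tot$keyword_instances)
  expect_lte(tot$either_messages, sum(per$either_messages))
  expect_equal(tot$either_messages, length(rs$folders[["_all_either"]]))

  # empty retrieval -> all-zero table
  rs0 <- retrieve(mk_clean("nothing here"), mk_lexicon())
  rep0 <- retrieval_report(rs0)
  expect_true(all(rep0$either_instances == 0L))
})

test_that("deliver writes one file per folder member with date_id names", {
  clean <- mk_clean(c("herpes zoster case", "mercury question"))
  rs <- retrieve(clean, mk_lexicon())
  out <- withr::local_tempdir()
  counts <- deliver(rs, clean, out)
  for (k in seq_len(nrow(counts))) {
    expect_length(list.files(file.path(out, counts$folder[k])),
                  counts$n_files[k])
  }
  # same message in two folders: identical name, identical content
  f1 <- list.files(file.path(out, "systemic disease/phrase"))
  f2 <- list.files(file.path(out, "_all_phrase"))
  expect_equal(f1, f2)
  expect_match(f1, "^\\d{8}_1\\.txt$")
})
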