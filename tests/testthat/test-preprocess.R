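test_that("quoted lines are removed, surviving order preserved", {
  body <- "line one\n> quoted a\n> quoted b\nline four\nline five"
  expect_equal(strip_reply_content(body),
               "line one\nline four\nline five")

  # identity when nothing matches
  plain <- "no quoting here\njust prose"
  expect_equal(strip_reply_content(plain), plain)

  # a body that is entirely one quoted block vanishes
  expect_equal(strip_reply_content("> a\n> b\n> c"), "")
})

test_that("forwarded blocks are cut to the end of the message", {
  body <- "keep me\n-----Original Message-----\nfrom elsewhere\nmore noise"
  expect_equal(strip_reply_content(body), "keep me")
  body2 <- "keep\nOn Tuesday somebody wrote:\n> old text"
  expect_equal(strip_reply_content(body2), "keep")
})

test_that("signature and notice boilerplate is stripped and logged", {
  body <- "real content here\n--\nDr. X, DDS\nwww.example.com"
  out <- strip_boilerplate(body)
  expect_equal(out$text, "real content here")
  expect_equal(out$removal_log$rule, "signature_delim")
  expect_equal(out$removal_log$n_lines, 3L)

  # trailing signature-like lines without a delimiter (heuristic)
  body2 <- "real content here\nDr. Somebody, DDS\nwww.practice-site.com"
  out2 <- strip_boilerplate(body2)
  expect_equal(out2$text, "real content here")
  expect_true("signature_heuristic" %in% out2$removal_log$rule)

  # nothing enabled matches -> unchanged, empty log
  out3 <- strip_boilerplate("ordinary text only")
  expect_equal(out3$text, "ordinary text only")
  expect_equal(nrow(out3$removal_log), 0L)

  # a body that is only a virus notice becomes empty
  out4 <- strip_boilerplate("No virus found in this outgoing message. Checked by AVG.")
  expect_equal(out4$text, "")
  expect_equal(out4$removal_log$rule, "virus_notice")
})

test_that("noise groups are individually switchable", {
  rules <- noise_rules(disable = "quoted_reply")
  body <- "a\n> still here\nb"
  expect_equal(strip_reply_content(body, rules), body)
})

test_that("deidentification replaces whole words only, case-insensitively", {
  expect_equal(deidentify("saw Smith in Pittsburgh",
                          names = "smith", places = "pittsburgh"),
               "saw xx in xx")
  # whole-word rule: embedded matches untouched
  expect_equal(deidentify("smithing tools", names = "smith"), "smithing tools")
  # empty lists are the identity
  expect_equal(deidentify("anything at all"), "anything at all")
})

test_that("clean_message composes the stages and is idempotent", {
  raw <- list(id = 1L, date = as.POSIXct("2008-05-01", tz = "UTC"),
              body = paste(
                "Genuine   clinical question here.",
                "> quoted reply line",
                "On Monday somebody wrote:",
                "Second real    sentence.",
                "--",
                "Dr. X, DDS", sep = "\n"))
  cm <- clean_message(raw)
  expect_equal(cm$text,
               "Genuine clinical question here.\nSecond real sentence.")
  expect_true(all(c("reply_content", "signature_delim") %in%
                    cm$removal_log$rule))

  # idempotence: cleaning the cleaned text changes nothing
  again <- clean_message(list(id = 1L, date = raw$date, body = cm$text))
  expect_identical(again$text, cm$text)

  # empty body -> empty text
  expect_equal(clean_message(list(id = 2L, date = raw$date, body = ""))$text, "")
})

test_that("a quoted signature is consumed by the reply rule, not the signature rule", {
  raw <- list(id = 1L, date = as.POSIXct("2008-05-01", tz = "UTC"),
              body = "Real content\n> --\n> Dr. Quoted, DDS\nMore content")
  cm <- clean_message(raw)
  expect_equal(cm$text, "Real content\nMore content")
})

test_that("cleaning introduces no new characters beyond placeholders and whitespace", {
  raw_chars <- function(x) unique(strsplit(x, "")[[1]])
  body <- "Dr Fulano saw a Patient > in Springfield today"
  cleaned <- clean_message(list(id = 1L, date = Sys.time(), body = body),
                           names = "fulano", places = "springfield")$text
  extra <- setdiff(raw_chars(cleaned), c(raw_chars(body), "x", " ", "\n"))
  expect_length(extra, 0L)
})

test_that("on synthetic corpora planted noise vanishes and planted content survives", {
  cfg <- sim_config(
    seed = 42, n_messages = 40, n_subscribers = 30, n_posting = 15,
    group_sizes = c(top = 2, mid = 3), group_shares = c(top = 0.5, mid = 0.25),
    noise_probs = c(quoted_reply = 1, signature = 1, advertisement = 1,
                    virus_notice = 1, client_notice = 1, image_ref = 1,
                    forwarded_block = 0),
    plantings = list(
      list(category = "systemic disease", words = c("herpes", "zoster"),
           n = 10, gaps = c(1, 20)),
      list(category = "systemic disease", words = "mercury",
           kind = "keyword", n = 8)))
  g <- generate_corpus(cfg)
  cl <- clean_corpus(g$corpus)

  for (k in seq_len(nrow(g$manifest$plantings))) {
    id <- g$manifest$plantings$id[k]
    expect_true(grepl(g$manifest$plantings$text[k],
                      cl$text[cl$id == id], fixed = TRUE),
                info = sprintf("planting %d retained", k))
  }
  for (k in seq_len(nrow(g$manifest$noise))) {
    id <- g$manifest$noise$id[k]
    blk <- strsplit(g$manifest$noise$text[k], "\n")[[1]]
    marker <- blk[which.max(nchar(blk))]   # most distinctive line
    expect_false(grepl(marker, cl$text[cl$id == id], fixed = TRUE),
                 info = sprintf("noise %s removed", g$manifest$noise$class[k]))
  }
})
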