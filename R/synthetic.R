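#' Configuration for the synthetic mailing-list generator
#'
#' The defaults emulate the structure of a year of traffic on a ~450
#' subscriber practitioners' mailing list: 14,576 messages posted between
#' 2008-04-18 and 2009-05-28 by 245 of the subscribers, with heavily skewed
#' participation (a core group of 21 authors posting 50% of the messages, a
#' middle group of 29 posting 25%, the remainder 25%). Bodies mix filler
#' prose with planted clinical phrases/keywords at controlled character
#' gaps and noise blocks drawn from the default cleaning pattern families,
#' so every pipeline stage can be tested against a ground-truth manifest.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_messages Number of messages.
#' @param n_subscribers Total list size (posting + passive).
#' @param n_posting Number of authors who post at least once.
#' @param group_sizes Named integer vector `c(top = ..., mid = ...)`: sizes
#'   of the core and middle participation groups (the rest of the posting
#'   authors form the peripheral group).
#' @param group_shares Named numeric vector `c(top = ..., mid = ...)`:
#'   message shares of those groups; the peripheral group gets the rest.
#' @param date_start,date_end Corpus date span (parseable dates).
#' @param noise_probs Named probabilities per noise class. Recognised names:
#'   `quoted_reply`, `forwarded_block`, `signature`, `advertisement`,
#'   `virus_notice`, `client_notice`, `image_ref`.
#' @param plantings A list of planting plans, each a list with `category`,
#'   `words` (character vector: 2-3 words for a phrase, 1 for a keyword),
#'   `kind` (`"phrase"` or `"keyword"`), `n` (message quota), and for
#'   phrases `gaps` (numeric vector recycled over instances; a value per
#'   instance, applied to every word pair, or a list of per-pair vectors).
#'   Gaps above the retrieval bound are deliberate non-retrievable cases.
#' @param filler_vocab Innocuous filler words; must stay disjoint from
#'   planted clinical vocabulary so the manifest is exact ground truth.
#' @param mean_sentences Mean filler sentences per message.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_messages = 14576L,
                       n_subscribers = 450L,
                       n_posting = 245L,
                       group_sizes = c(top = 21L, mid = 29L),
                       group_shares = c(top = 0.50, mid = 0.25),
                       date_start = "2008-04-18",
                       date_end = "2009-05-28",
                       noise_probs = c(quoted_reply = 0.30,
                                       forwarded_block = 0.05,
                                       signature = 0.40,
                                       advertisement = 0.10,
                                       virus_notice = 0.08,
                                       client_notice = 0.05,
                                       image_ref = 0.05),
                       plantings = list(),
                       filler_vocab = default_filler_vocab(),
                       mean_sentences = 4) {
  assert_that(n_messages >= 0, "n_messages must be >= 0")
  assert_that(n_posting <= n_subscribers,
              "n_posting cannot exceed n_subscribers")
  assert_that(n_messages == 0 || n_posting <= n_messages,
              "infeasible: more posting authors than messages")
  assert_that(sum(group_sizes) <= n_posting,
              "participation groups exceed posting authors")
  assert_that(all(group_shares >= 0) && sum(group_shares) <= 1,
              "group shares must be probabilities summing to <= 1")
  assert_that(all(noise_probs >= 0 & noise_probs <= 1),
              "noise probabilities must be in [0, 1]")
  for (p in plantings) {
    assert_that(!is.null(p$category) && !is.null(p$words) && !is.null(p$n),
                "each planting needs category, words, n")
    assert_that(p$n <= n_messages,
                sprintf("infeasible quota: %d plantings of '%s' in %d messages",
                        p$n, paste(p$words, collapse = " "), n_messages))
    kind <- p$kind %||% if (length(p$words) > 1L) "phrase" else "keyword"
    assert_that(kind %in% c("phrase", "keyword"), "kind must be phrase/keyword")
    if (kind == "phrase")
      assert_that(length(p$words) %in% 2:3, "phrase plantings need 2-3 words")
  }
  structure(list(
    seed = as.integer(seed), n_messages = as.integer(n_messages),
    n_subscribers = as.integer(n_subscribers),
    n_posting = as.integer(n_posting),
    group_sizes = group_sizes, group_shares = group_shares,
    date_start = as.POSIXct(paste(date_start, "00:00:00"), tz = "UTC"),
    date_end = as.POSIXct(paste(date_end, "23:59:59"), tz = "UTC"),
    noise_probs = noise_probs, plantings = plantings,
    filler_vocab = filler_vocab, mean_sentences = mean_sentences
  ), class = "sim_config")
}

#' Default innocuous filler vocabulary
#'
#' Everyday words used for synthetic filler prose; deliberately disjoint
#' from any clinical vocabulary a test would plant.
#'
#' @return Character vector.
#' @export
default_filler_vocab <- function() {
  c("morning", "coffee", "window", "garden", "travel", "holiday", "weather",
    "weekend", "picture", "family", "evening", "dinner", "meeting",
    "schedule", "journey", "airport", "vacation", "birthday", "kitchen",
    "painting", "concert", "library", "bicycle", "mountain", "station",
    "village", "market", "ticket", "summer", "winter", "autumn", "spring",
    "sunshine", "reading", "writing", "football", "baseball", "theater",
    "museum", "river", "forest", "island", "harbor", "castle", "bridge",
    "lantern", "orchard", "meadow", "valley", "thunder", "breeze", "sunset",
    "sunrise", "pebble", "willow", "maple", "cedar", "tulip", "orchid",
    "sparrow", "falcon", "salmon", "antique", "pottery", "quilt", "recipe",
    "barbecue", "campfire", "snowfall", "rainbow")
}

# largest-remainder rounding of nonnegative weights to integers summing to
# `total`, with an optional per-cell minimum of 1.
lr_round <- function(weights, total, min_one = FALSE) {
  n <- length(weights)
  if (n == 0L || total <= 0L) return(rep(0L, n))
  base <- if (min_one) rep(1L, n) else rep(0L, n)
  rest <- total - sum(base)
  assert_that(rest >= 0, "infeasible allocation: total below minimum")
  raw <- weights / sum(weights) * rest
  out <- floor(raw)
  left <- rest - sum(out)
  if (left > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  as.integer(base + out)
}

# message counts per posting author: group totals by configured shares, then
# geometric decay within each group. The decay ratio is chosen per group so
# that the largest member gets about twice the smallest (r^(n-1) = 0.5);
# with the default group structure this keeps the count ranges of adjacent
# groups disjoint, so the top-k authors by realized count are exactly the
# configured core group and the calibrated share is hit by construction.
author_message_counts <- function(config) {
  n_top <- as.integer(config$group_sizes[["top"]])
  n_mid <- as.integer(config$group_sizes[["mid"]])
  n_rest <- config$n_posting - n_top - n_mid
  shares <- c(config$group_shares[["top"]], config$group_shares[["mid"]],
              1 - sum(config$group_shares))
  totals <- lr_round(shares, config$n_messages)
  geo <- function(n) {
    if (n == 0L) return(numeric())
    r <- if (n > 1L) 0.5^(1 / (n - 1L)) else 1
    r^(seq_len(n) - 1)
  }
  counts <- c(
    lr_round(geo(n_top), totals[1], min_one = n_top > 0 && totals[1] >= n_top),
    lr_round(geo(n_mid), totals[2], min_one = n_mid > 0 && totals[2] >= n_mid),
    lr_round(geo(n_rest), totals[3], min_one = n_rest > 0 && totals[3] >= n_rest)
  )
  sort(counts, decreasing = TRUE)
}

sep_for_gap <- function(g) {
  g <- max(1L, as.integer(g))
  if (g == 1L) " " else paste0(" ", strrep("-", g - 2L), " ")
}

planted_text <- function(words, gaps) {
  if (length(words) == 1L) return(words)
  gaps <- as.integer(pmax(1L, gaps))
  out <- words[1]
  for (k in seq_len(length(words) - 1L))
    out <- paste0(out, sep_for_gap(gaps[k]), words[k + 1L])
  out
}

filler_sentence <- function(vocab) {
  n <- sample(5:10, 1)
  w <- sample(vocab, n, replace = TRUE)
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste0(paste(w, collapse = " "), ".")
}

noise_block <- function(class, vocab) {
  switch(class,
    quoted_reply = c(
      "On Monday the practice manager wrote:",
      paste0("> ", filler_sentence(vocab)),
      paste0("> ", filler_sentence(vocab))),
    forwarded_block = c(
      "-----Original Message-----",
      filler_sentence(vocab),
      filler_sentence(vocab)),
    signature = c(
      "--",
      "Dr. Example Name, DDS",
      "www.example-practice.com"),
    advertisement = "Visit our sponsor for a special offer today.",
    virus_notice = "No virus found in this outgoing message. Checked by AVG.",
    client_notice = "Sent from my iPhone",
    image_ref = "[image: radiograph.jpg]"
  )
}

#' Generate a seeded synthetic mailing-list corpus with manifest
#'
#' Builds a corpus with skewed per-author posting counts calibrated to the
#' configured participation shares, filler prose bodies, planted clinical
#' items at specified character gaps, and noise blocks drawn verbatim from
#' the default cleaning pattern families. All randomness comes from
#' `config$seed`: identical configurations give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param mbox Optional path: write the corpus as an mbox file.
#' @return A list: `corpus` (a `mail_corpus` tibble, ids in date order,
#'   identical to what [read_mailbox()] returns on the written mbox) and
#'   `manifest` (list of tibbles `messages`, `plantings`, `noise`; every
#'   planted item is locatable verbatim in the raw body).
#' @export
generate_corpus <- function(config, mbox = NULL) {
  set.seed(config$seed)
  n <- config$n_messages
  empty_manifest <- list(
    messages = tibble::tibble(id = integer(), date = as.POSIXct(character(), tz = "UTC"),
                              author = character()),
    plantings = tibble::tibble(id = integer(), category = character(),
                               kind = character(), words = character(),
                               gaps = list(), text = character()),
    noise = tibble::tibble(id = integer(), class = character(),
                           text = character())
  )
  if (n == 0L) {
    corpus <- as_mail_corpus(empty_raw_messages())
    if (!is.null(mbox)) file.create(mbox)
    return(list(corpus = corpus, manifest = empty_manifest))
  }

  counts <- author_message_counts(config)
  authors <- sprintf("author%03d", seq_len(config$n_posting))
  author_of <- sample(rep(authors, counts))
  dates <- sort(config$date_start +
                  round(stats::runif(n) * as.numeric(difftime(
                    config$date_end, config$date_start, units = "secs"))))

  # expand planting plans into per-instance assignments
  plant_rows <- list()
  for (p in config$plantings) {
    kind <- p$kind %||% if (length(p$words) > 1L) "phrase" else "keyword"
    ids <- sample(n, p$n)
    gaps_plan <- p$gaps %||% 1L
    for (j in seq_len(p$n)) {
      g <- if (is.list(gaps_plan)) gaps_plan[[(j - 1L) %% length(gaps_plan) + 1L]]
           else gaps_plan[(j - 1L) %% length(gaps_plan) + 1L]
      g <- rep(as.integer(g), length.out = max(1L, length(p$words) - 1L))
      if (kind == "keyword") g <- integer()
      plant_rows[[length(plant_rows) + 1L]] <- tibble::tibble(
        id = ids[j], category = p$category, kind = kind,
        words = paste(tolower(p$words), collapse = " "),
        gaps = list(pmax(1L, g)),
        text = if (kind == "phrase") planted_text(tolower(p$words), g)
               else paste0("Considering ", tolower(p$words), " further.")
      )
    }
  }
  plantings <- if (length(plant_rows)) dplyr::bind_rows(plant_rows)
               else empty_manifest$plantings

  noise_rows <- list()
  bodies <- character(n)
  for (i in seq_len(n)) {
    n_sent <- 1L + stats::rpois(1, max(0, config$mean_sentences - 1))
    lines <- vapply(seq_len(n_sent), function(k)
      filler_sentence(config$filler_vocab), character(1))

    my_plants <- plantings$text[plantings$id == i]
    for (pt in my_plants) {
      pos <- sample(0:length(lines), 1)
      lines <- append(lines, pt, after = pos)
    }

    draw <- stats::runif(length(config$noise_probs)) < config$noise_probs
    classes <- names(config$noise_probs)[draw]
    # line-level noise anywhere; signature / forwarded block only at the end
    tail_classes <- intersect(classes, c("signature", "forwarded_block"))
    mid_classes <- setdiff(classes, tail_classes)
    for (cl in mid_classes) {
      blk <- noise_block(cl, config$filler_vocab)
      pos <- sample(0:length(lines), 1)
      lines <- append(lines, blk, after = pos)
      noise_rows[[length(noise_rows) + 1L]] <- tibble::tibble(
        id = i, class = cl, text = paste(blk, collapse = "\n"))
    }
    for (cl in c("signature", "forwarded_block")) {
      if (cl %in% tail_classes) {
        blk <- noise_block(cl, config$filler_vocab)
        lines <- c(lines, blk)
        noise_rows[[length(noise_rows) + 1L]] <- tibble::tibble(
          id = i, class = cl, text = paste(blk, collapse = "\n"))
      }
    }
    bodies[i] <- paste(lines, collapse = "\n")
  }

  subjects <- vapply(seq_len(n), function(i)
    paste("Re:", paste(sample(config$filler_vocab, 2), collapse = " ")),
    character(1))

  raw <- tibble::tibble(date = dates, author = author_of,
                        subject = subjects, body = bodies)
  corpus <- as_mail_corpus(raw)

  manifest <- list(
    messages = corpus[, c("id", "date", "author")],
    plantings = plantings[order(plantings$id), , drop = FALSE],
    noise = if (length(noise_rows)) dplyr::bind_rows(noise_rows)
            else empty_manifest$noise
  )

  if (!is.null(mbox)) write_mbox(corpus, mbox)
  list(corpus = corpus, manifest = manifest)
}

#' Write a corpus as an mbox file
#'
#' RFC-2822 date headers are formatted with explicit English month/day
#' tables, independent of the locale.
#'
#' @param corpus A `mail_corpus` tibble.
#' @param path Output file.
#' @export
write_mbox <- function(corpus, path) {
  wd <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  mo <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
          "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    lt <- as.POSIXlt(corpus$date[i], tz = "UTC")
    dstr <- sprintf("%s, %02d %s %d %02d:%02d:%02d +0000",
                    wd[lt$wday + 1], lt$mday, mo[lt$mon + 1],
                    lt$year + 1900, lt$hour, lt$min, as.integer(lt$sec))
    block <- paste0(
      "From ", corpus$author[i], " ", dstr, "\n",
      "Date: ", dstr, "\n",
      "From: ", corpus$author[i], "\n",
      "Subject: ", corpus$subject[i], "\n\n",
      corpus$body[i], "\n\n")
    writeChar(enc2utf8(block), con, eos = NULL, useBytes = TRUE)
  }
  invisible(path)
}

#' Score a retrieval run against the generator manifest
#'
#' Recall is the fraction of retrievable plantings (phrase plantings with
#' every gap within `max_gap`, plus all keyword plantings) whose message was
#' retrieved for the planted category/kind/query; precision counts match
#' instances not traceable to a planting as false positives (per message,
#' category, kind and query, excess matches beyond the planted count are
#' false positives). Vacuous cases score 1.
#'
#' @param set A [retrieve()] result produced from the generated corpus.
#' @param manifest The [generate_corpus()] manifest.
#' @param max_gap The retrieval proximity bound the run used.
#' @return A list: `recall`, `precision`, `detail` (per-category tibble with
#'   `planted`, `retrievable`, `retrieved`, `false_pos`).
#' @export
score_against_manifest <- function(set, manifest, max_gap = set$max_gap) {
  pl <- manifest$plantings
  assert_that(all(set$matches$id %in% manifest$messages$id) ||
                nrow(set$matches) == 0L,
              "id mismatch between retrieval and manifest")
  if (nrow(pl)) {
    pl$retrievable <- vapply(seq_len(nrow(pl)), function(k)
      pl$kind[k] == "keyword" || all(pl$gaps[[k]] <= max_gap), logical(1))
  } else {
    pl$retrievable <- logical()
  }

  m <- set$matches
  mkey <- if (nrow(m)) paste(m$id, m$category, m$kind, m$query, sep = "\r")
          else character()
  pkey <- if (nrow(pl)) paste(pl$id, pl$category, pl$kind, pl$words, sep = "\r")
          else character()

  pl$retrieved <- pkey %in% mkey
  retrievable <- pl[pl$retrievable, , drop = FALSE]
  recall <- if (nrow(retrievable) == 0L) 1
            else mean(retrievable$retrieved)

  # instance-level precision with per-key planted quotas (retrievable only)
  quota <- table(pkey[pl$retrievable])
  mtab <- table(mkey)
  matched_quota <- as.integer(quota[match(names(mtab), names(quota))])
  matched_quota[is.na(matched_quota)] <- 0L
  tp <- sum(pmin(as.integer(mtab), matched_quota))
  fp <- sum(as.integer(mtab)) - tp
  precision <- if (nrow(m) == 0L) 1 else tp / nrow(m)

  cats <- sort(unique(c(pl$category, m$category)))
  detail <- dplyr::bind_rows(lapply(cats, function(cc) {
    sel <- pl$category == cc
    tibble::tibble(
      category = cc,
      planted = sum(sel),
      retrievable = sum(sel & pl$retrievable),
      retrieved = sum(sel & pl$retrievable & pl$retrieved),
      false_pos = {
        msel <- m$category == cc
        k <- table(mkey[msel])
        q <- as.integer(quota[match(names(k), names(quota))])
        q[is.na(q)] <- 0L
        sum(as.integer(k)) - sum(pmin(as.integer(k), q))
      })
  }))
  list(recall = recall, precision = precision, detail = detail)
}
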