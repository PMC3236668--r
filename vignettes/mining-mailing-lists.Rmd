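---
title: "Mining clinical topics from mailing-list email: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining clinical topics from mailing-list email: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinicolloc)
```

## The problem

Professional mailing lists behave like virtual communities of practice: a
small core of members generates most of the traffic, and the messages mix
genuine clinical discussion with chatter, quoted replies, signatures,
advertisements and other noise. Researchers who want to study the clinical
content of such a list — for example, to understand practitioners' real
information needs — face a corpus of many thousands of messages of which
only a small fraction is relevant, and labor-intensive qualitative analysis
can only handle a few hundred.

`clinicolloc` implements a workflow for that situation: clean and
deidentify the messages, discover the content-bearing vocabulary and the
collocations (word pairs and triples that co-occur more than chance
predicts), let domain experts classify the useful phrases into a category
lexicon, and then use the phrases and their embedded keywords as proximity
search strings to retrieve and deliver a manageable, deduplicated set of
messages per category.

## Cleaning and deidentification

Email noise is removed in two passes. `strip_reply_content()` drops quoted
lines (leading `>` or `|`), attribution lines ("On ... wrote:"), and
everything from a forwarded-message marker onward. `strip_boilerplate()`
removes signature blocks (from a `--` delimiter line to the end, plus a
trailing-run heuristic for undelimited signatures containing credential,
phone, or URL tokens), advertisements and footers, virus/spam-free notices,
mail-client notices, and embedded-image placeholders.

The exact patterns of the noise in any given list are idiosyncratic, so the
pattern set ships as an editable plain-text file
(`system.file("extdata", "noise_patterns.txt", package = "clinicolloc")`),
one tab-separated `group`/`regex` entry per line, and every group can be
switched off independently. The shipped defaults cover the noise classes
typical of practitioner mailing lists.

Two properties are enforced by construction and checked in the tests:

* **Idempotence.** `clean_message()` normalizes whitespace *before* pattern
  matching and removes whole lines only, so cleaning a cleaned message is a
  no-op. The trailing-signature heuristic is applied to a fixed point (and
  refuses to remove runs longer than six lines) for the same reason.
* **Conservatism.** Cleaning introduces no characters that were not in the
  input, other than the deidentification placeholder and whitespace.

Deidentification replaces whole-word, case-insensitive occurrences of
listed names and gazetteer places with the placeholder `xx`. The
placeholder is deliberately shorter than the four-character token filter
below, so deidentification can never pollute the downstream vocabulary.
Word boundaries are letter/non-letter transitions throughout the package:
`smith` never touches `smithing`, and digits do not glue words together.

## Token filtering

Tokens are maximal runs of letter characters, lowercased; digits and
hyphens split tokens (`x-ray` tokenizes as `x`, `ray`). Filtering follows
the two-stage scheme of the study the package reimplements, reading its
strict inequalities literally:

1. **Stage 1:** keep alphabetic tokens of length ≥ 4 ("length > 3") and
   delete stopwords. The shipped default stoplist is the classic 127-word
   English function-word list; it is a plain file and replaceable.
2. **Content filter:** keep tokens of length ≥ 6 with corpus-wide
   frequency ≥ 8 ("length > 5 and frequency > 7"). Frequency is computed
   over the merged, date-sorted corpus stream, not per message, because the
   filter is meant to find the vocabulary of the whole community.

The distinct surviving types are the community's content vocabulary. No
stemming or spelling correction is applied — surface forms are what the
downstream phrase search uses.

## Collocations and PMI

Bigrams and trigrams are contiguous windows over the content stream. By
default windows do not cross message boundaries (`span_messages = FALSE`):
a window spanning the end of one email and the start of the next is
linguistically spurious. The merged-file behaviour is available via the
flag for fidelity with concatenated-corpus processing.

Pointwise mutual information in bits compares the observed window
probability with the independence prediction:

* bigram: `log2( (c12 / W) / ((c1 / T)(c2 / T)) )`
* trigram: `log2( (c123 / W) / ((c1 / T)(c2 / T)(c3 / T)) )`

where `W` is the number of windows and `T` the unigram token total. The
product-of-unigrams denominator for trigrams is the convention of the
standard NLP toolkits; unigram probabilities use the content-stream total
and window probabilities use the window total, an explicit, testable
convention. The test suite checks `pmi()` against an independent
brute-force enumeration of windows on streams of up to 200 tokens.

`top_collocations()` scores every n-gram with count ≥ `min_count`
(default 2 — PMI at count 1 maximally rewards hapax noise) and returns the
top `k_per_type` (default 300) of each type, sorted by PMI descending,
count descending, then words ascending so that ranking is fully
deterministic.

Counts worth knowing: an n-gram table reports both its number of distinct
n-gram types (`n_distinct`) and its window total (`window_total`); corpus
summaries of "how many bigrams/trigrams" can mean either, and the two
readings differ.

## Concordance

`kwic()` renders fixed-width keyword-in-context lines for a target word,
in corpus date order. The left context receives
`floor((width - nchar(target)) / 2)` characters; edges are space-padded so
every line is exactly `width` characters. Defaults (width 80, 25 lines)
follow the common toolkit conventions.

## The lexicon and the keyword rule

Classifying discovered phrases into clinical categories is a human,
consensus-based step; the package treats the resulting scheme as input. A
lexicon is a YAML file mapping categories (optionally with subcategories)
to 2-3-word phrases and keywords; `validate_lexicon()` cross-checks it
against the discovered collocations and tallies it category by category.

A *keyword* is a word occurring at least twice across all word slots of
the selected collocations, where variants count as one class. Two kinds of
equivalence exist: morphological variants (plaque/plaques) are auto-merged
by a simple -s/-es suffix rule (switchable off), while closely related
terms (cardiac/myocardial) cannot be inferred mechanically and live only
in a user-supplied `equivalence_map()`. Each qualifying class emits its
lexicographically first member as the representative keyword.

## Proximity retrieval

Phrases are compiled into order-free proximity queries: all words of the
phrase, in any order, with at most `max_gap` characters between
consecutive matched words. The default bound of 100 characters comes from
the study's calibration: discovered phrases were found in raw messages with
up to ~78 characters between words, and 100 is the conservative round
bound. Keywords are searched as whole words; keywords adjacent inside a
phrase are additionally searched as the order-preserving concatenated
string.

Design choices that matter here:

* **Gap semantics.** The gap is the count of characters strictly between
  the end of one matched word and the start of the next, whitespace and
  punctuation included; this inclusive count drives matching. A secondary
  count that excludes whitespace and punctuation is recorded on each match
  because gap ranges are often reported on that scale.
* **Instances.** Matching scans left to right; an instance consumes its
  word occurrences, and overlapping candidate windows count once. The
  implementation enumerates all valid windows and selects them greedily by
  earliest end, which both finds an instance whenever one exists and keeps
  counts deterministic.
* **No stemming in retrieval.** `plaques` does not match the keyword
  `plaque` unless both are listed — variant search strings are explicit.
* **Retrieval runs on cleaned text**, not on the NLP-filtered token
  stream: the filters exist to *discover* phrases, while retrieval must
  see the message as a reader would.

Retrieved messages are binned per category and per match kind, folders are
deduplicated, aggregate folders (`_all_phrase`, `_all_keyword`,
`_all_either`) are unions, and `deliver()` writes each message once per
folder as `YYYYMMDD_<id>.txt` so that filenames sort chronologically and
identify the message. In the summary table, instance totals are sums
across categories while message totals are deduplicated unions — the same
message may legitimately appear in several categories.

## The synthetic corpus: what it emulates and what it does not

The study corpus behind this workflow is private, so the package ships a
seeded generator whose defaults reproduce the *structural* conditions of
that corpus: 14,576 messages posted between 2008-04-18 and 2009-05-28 by
245 of about 450 subscribers, with a core group of 21 authors holding 50%
of the traffic, a middle group of 29 holding 25%, and the periphery the
rest. Group totals are allocated exactly (largest-remainder rounding) and
decay geometrically within groups with a max/min ratio of about 2, which
keeps adjacent groups' count ranges disjoint — so the calibrated top-share
holds by construction, and the realized share of the top 5% of the list
lands within a point or two of 50%.

Bodies are filler prose from an innocuous vocabulary deliberately disjoint
from anything a test plants, plus planted clinical phrases at exact
character gaps (including deliberate beyond-bound gaps) and noise blocks
drawn verbatim from the default cleaning pattern families. The manifest
records every planted item and noise block, making recall and precision
exactly measurable: with cleaning enabled and plantings outside noise
blocks, end-to-end retrieval scores 100% on both.

A planted "gap" below 1 is not emitted: zero characters between two words
concatenates them into a single token, which whole-word matching can never
see. The generator's minimum separator is a single space (an inclusive gap
of 1, equivalent to an exclusive gap of 0).

What the generator does *not* emulate: realistic dental discourse, quoted
news excerpts with high clinical-phrase density, misspellings and
idiosyncratic style, or MIME structure. Passing tests on synthetic corpora
therefore demonstrate the mechanics of cleaning, discovery and retrieval —
not robustness to the full messiness of real email.

## Numerical and reporting conventions

* Percentages use exact integer rational arithmetic with half-up rounding
  (`percent()`), because the printed values this package reproduces
  (36.32, 19.02, 2.02, 54.4, 2.1) are all half-up; banker's rounding
  disagrees on exact halves.
* Corpus identifiers are assigned 1..N in date order with ties broken by
  mailbox order (stable sort); undated messages go to the end, flagged,
  never dropped.
* Date parsing accepts RFC-2822 and ISO-8601 headers with explicit month
  tables, independent of the locale.
* Degenerate inputs are defined: an empty mailbox is an empty corpus, an
  absent concordance target is an empty result, an empty collocation set
  yields no keywords, and an empty retrieval yields an all-zero report.

## Problem sizes used by the tests

The test suite and the acceptance script exercise the pipeline end to end
on a 2,000-message planted corpus (≥ 200 retrievable planted instances
across three categories) and calibrate participation on a full-scale
14,576-message synthetic corpus; both sizes were chosen as the smallest
that exercise every mechanism at realistic skew. PMI and the keyword rule
are verified against brute-force oracles on streams of ≤ 200 tokens, where
exhaustive enumeration is trivially correct.

## Known limitations

* The noise pattern defaults approximate the documented noise classes; a
  new list will need pattern-file tuning, which is why the file is
  editable and every group switchable.
* Retrieval is boolean — no ranking or relevance scoring.
* Only the first text part of a message is used; attachments, HTML and
  multipart MIME are out of scope.
* The keyword suffix rule is deliberately simple (-s/-es); irregular
  variants belong in the equivalence map.
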