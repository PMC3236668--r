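Package: clinicolloc
Title: Mining Clinically Relevant Messages from Mailing-List Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for discovering clinical topics in noisy email
    corpora such as professional mailing lists. Provides mailbox ingestion
    with date-ordered identifiers, configurable noise stripping (quoted
    replies, forwarded blocks, signatures, advertisements, virus notices)
    and list-based deidentification, two-stage token filtering to isolate
    content-bearing vocabulary, bigram/trigram collocation ranking by
    pointwise mutual information, keyword-in-context concordances,
    category lexicons with a keyword-extraction rule, order-free proximity
    retrieval of messages by phrase and keyword with folder delivery and
    summary reporting, plus a seeded synthetic mailing-list generator with
    a ground-truth manifest for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    tibble,
    dplyr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
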