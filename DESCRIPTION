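Package: traitscreen
Title: Distributional Trait Scoring and Ranked Screening of Text Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores plain-text documents against short lists of seed words
    ("trait vectors") describing psychological dimensions, using a
    count-based distributional semantic space (windowed co-occurrence,
    positive pointwise mutual information, optional truncated SVD, cosine
    similarity) built from a background corpus. Documents are represented by
    their most frequent nouns, verbs and adjectives; groups are compared per
    trait with a Mann-Whitney U test whose p-value comes from Monte-Carlo
    label permutation; and documents are ranked by classifier-predicted
    class probability to measure how far down a ranked list a reader must go
    to recover every flagged document. Includes a synthetic corpus generator
    with planted co-occurrence structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    rpart,
    stats,
    tools,
    utils
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
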