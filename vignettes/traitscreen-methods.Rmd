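---
title: "traitscreen: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{traitscreen: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It is written for a reader who wants to audit
the method, not just run it.

## The model

`traitscreen` operationalizes a count-based vector-space model of word
meaning and layers a screening procedure on top of it.

**Semantic space.** A word's meaning is represented by the company it
keeps: for a background corpus, we count how often each pair of
(lowercased) word types co-occurs within a symmetric window of `window`
tokens, never across document boundaries, with no distance decay inside
the window. Co-occurrences of a word type with itself are not counted, so
the matrix diagonal is zero. Raw counts overweight frequent words, so by
default the matrix is reweighted with positive pointwise mutual
information,

$$w_{ij} = \max\!\left(0,\; \log_2 \frac{c_{ij}\,T}{r_i\,r_j}\right),$$

where $r_i$ is the row sum and $T$ the grand total: a cell is positive
exactly when the pair co-occurs more than chance expects. An optional
truncated SVD (left singular vectors scaled by singular values) densifies
the rows; at full rank it preserves all cosines, which is one of the unit
tests. Word similarity is the cosine of the rows. The construction is
fully deterministic — no randomized decomposition is used — so a seed
affects nothing in this stage.

*Assumptions.* The background corpus is large enough that association
weights are stable for the words that matter (the trait seeds and the
documents' frequent content words), and the scored documents use words in
distributionally similar ways to the background corpus. Nothing in the
model handles negation, syntax or word order beyond the window.

**Document representation.** Each document is reduced to its `k = 10` most
frequent nouns, verbs and adjectives (at most 30 words). Part of speech
comes from a pluggable tagger contract — any function that fills the `pos`
column of a token table without reordering it. The package ships only a
deterministic dictionary tagger; a statistical tagger can be plugged in,
but tests and simulations use the dictionary so results are bit-for-bit
reproducible. Frequency ties at the cut are broken alphabetically (the
choice is arbitrary; determinism is what matters). A word type occurring
under two POS tags is counted independently per category; words are not
lemmatized, and a word appearing in several categories is not
deduplicated across them — both choices keep the representation a pure
function of surface frequencies.

**Trait scoring.** The 13 built-in trait vectors are short seed-word lists
(four DSM/Millon-derived personality dimensions — depressive, paranoid,
narcissistic, schizoid/schizotypal — and nine facets of vengeful behavior).
A document's score on a trait is, by default, the cosine between the
unweighted centroid of its in-vocabulary representation words and the
centroid of the trait's in-vocabulary seeds. How to aggregate a word *set*
against a word *set* is genuinely open; the centroid is scale-free and
robust to the representation's length, and `mode = "mean_pairwise"` (the
average of all pairwise cosines) is provided as the natural alternative.
The two coincide for single-word sets, which is tested. A
frequency-weighted centroid sits behind `weight_freq = TRUE`.

Out-of-vocabulary words are dropped and counted in an OOV report. A cell
where the usable representation or the trait becomes empty is `NA`
(an explicit `ts_undefined_score` condition at the single-document level),
never a silent zero — silent zeros would masquerade as "maximally
dissimilar" and bias every downstream group comparison.

**Group comparison.** Per trait, positive and comparison scores are
compared with the Mann–Whitney $U$ statistic ($U$ of the positive group;
pairs with ties count ½, so $U(x,y) + U(y,x) = n_1 n_2$ exactly). The
p-value is obtained by Monte-Carlo label permutation — resampling group
assignments without replacement, the exact null of exchangeability — with
the add-one estimator $p = (b+1)/(m+1)$, which can never return zero. The
default $m$ is 10{,}000. Sidedness is not obvious for a screening
instrument, so the default is two-sided by doubling the smaller tail
(capped at 1); one-sided alternatives are available. No multiple-testing
correction is applied across the 13 traits by default — the 13 scores are
treated as 13 separate instruments — but `adjust = "BH"` adds
Benjamini–Hochberg adjusted p-values for users who want a corrected view.

**Ranking and screening.** The 13 scores are the features of three
classifiers: binary logistic regression (`glm`), a classification tree,
and k-nearest-neighbors, plus a mean-of-ranks ensemble. Documents are
ranked by predicted positive-class probability (descending; probability
ties broken by document id so output tables are reproducible), and the
screening metric is *steps-to-identify-all*: the maximum rank among
positive documents. Its random-ranking baseline is the order-statistic
expectation $m(N+1)/(m+1)$, verified in tests against simulation.

## Design choices that were genuinely open

- **Tree model.** The classic screening literature this package follows
  used a CHAID tree (chi-square multiway splits). No maintained open
  implementation is assumed, and CHAID's multiway splits target
  categorical predictors, while the features here are 13 continuous
  scores. The package substitutes a CART-style binary tree (`rpart`) with
  cost-complexity pruning selected by 10-fold cross-validation, with
  `minsplit = 4` / `minbucket = 2` so that a rare positive class (six
  documents in thousands) can occupy a leaf at all. This is a documented
  substitution, not an emulation.
- **KNN probabilities.** Scores are standardized to zero mean and unit
  variance, and a document's probability is the positive fraction among
  its `k = 5` nearest training neighbors by Euclidean distance, with the
  document itself excluded from its own neighborhood when scoring the
  training set. The scorer is written directly on the distance matrix
  (rather than through a voting interface) because the ranking needs the
  exact neighbor class fraction with deterministic distance tie-breaks;
  it is cross-checked against `class::knn.cv` votes in a unit test.
- **In-sample vs cross-validated ranking.** The default `"insample"` mode
  fits on the full labeled collection and ranks that same collection —
  the realistic triage setup when the collection is fixed, but one that
  flatters the metrics, since the models have seen the positives they are
  asked to surface. `mode = "cv"` produces stratified out-of-fold
  probabilities and is the honest choice for any claim about future data.
  Outputs record which mode produced them.
- **Imbalance.** With six positives among thousands, logistic regression
  offers `class_weighting = "balanced"`, off by default: re-weighting
  changes probability calibration but mostly preserves ranking, and the
  default mirrors the plain fit.
- **Undefined cells before modeling.** `NA` score cells are imputed with
  the per-trait *comparison-group* median: deterministic and rank-safe
  (an undefined cell is treated as "typical of the background", never as
  evidence either way).
- **Mean-of-ranks ensemble.** Implemented literally: average each
  document's ranks across models, then re-rank the averages (ties by
  document id). Published tables of this procedure do not always allow
  the averaging to be reconstructed — component ranks and the combined
  order can disagree — so the package fixes the literal reading and
  documents it here.
- **Seeds.** Every stochastic stage takes a seed; a pipeline run uses a
  single master seed from which per-stage seeds are derived by hashing
  the stage name, so any stage can be reproduced in isolation. All seeded
  code restores the caller's RNG state.

## The synthetic-data generator

The generator defines a fully synthetic language: abstract content words
(`nounaa`, `verbab`, `adjac`, …), frequent function words (`fwaa`, …,
tagged OTHER), and the 31 lexicon seed words with a fixed POS assignment.
Each trait owns a *neighborhood* of content words (disjoint across traits
when the vocabulary allows; shared by all seeds of the trait, which is
what makes those seeds' vectors similar). Documents are unigram samples in
which every emitted seed word pulls neighborhood words into the following
`window` slots with probability `follow_prob = 0.85` — first-order
dependence only, which suffices because the semantic-space stage measures
nothing beyond windowed pair counts. Positive documents then have a
fraction θ of their content-word positions replaced by draws from the
target trait's pool (its neighborhoods plus its seeds); θ = 0 is the
exchangeable null, θ = 1 makes every positive content word pool-drawn.

What this emulates: trait seed words with coherent co-occurrence
neighborhoods in the background corpus, and positive documents lexically
tilted toward one trait — the two statistical premises the scoring method
rests on. What it does not emulate: natural syntax, topic drift,
demographic or stylistic variation, polysemy, or any adversarial behavior
(a writer avoiding trait vocabulary). Passing tests on this generator
therefore show the pipeline is *correct and calibrated under its own
premises*, not that real collections separate this cleanly; on real data
the enrichment is far weaker and unknown.

Default scales, chosen once as desk-scale but statistically meaningful:
`tiny` (50-word vocabulary, 30 background documents, 3 + 12 labeled) for
unit tests; `small` (500 / 300, 10 + 90) for integration; `paper_shaped`
(500 / 300, 6 positives + 2000 comparisons, θ = 0.8, 100-token documents)
for screening-metric tests — the same 6-positive class as the motivating
study against a comparison corpus reduced from 6056 to 2000 documents.

## Numerical and degenerate-input conventions

- PPMI cells with observed count below chance clamp to 0; a weighted
  matrix that is entirely zero is an error, not a silent empty space.
- A word with no co-occurrences has a zero vector; cosine with a zero
  vector is defined as 0 (keeps batch scoring total), while an
  out-of-vocabulary query raises a typed error carrying the word.
- Equality tolerances in oracle tests: cosine and PPMI against brute
  force at 1e-10; full-rank SVD cosine preservation at 1e-8; similarity
  symmetry at 1e-12.
- Tokens are maximal runs of letters with internal apostrophes; digits
  and punctuation separate. Matching is on lowercased forms throughout.
  Files must be valid UTF-8; decoding errors abort rather than corrupt
  frequencies.
- The Monte-Carlo $U$ comparison uses an epsilon of 1e-9 when counting
  exceedances, so midrank arithmetic noise cannot flip a tie.
- Empty groups, single-class labels, empty corpora and empty score tables
  are hard errors with named offenders; undefined score *cells* degrade
  gracefully (`NA` + OOV report) because a single odd document must not
  abort a batch over thousands.

## Problem sizes used by the test suite

The suite's heavier checks run at sizes chosen to balance statistical
resolution against desk-scale runtimes: null calibration uses 200
generator replicates (vocabulary 300, 150 background documents, 5 + 100
labeled, 499 permutations per test) for the rejection rate and the first
100 of them for the screening-steps null; signal recovery uses 20
replicates of the `paper_shaped` bundle with 10,000-permutation tests.
The acceptance script runs one `paper_shaped` replicate at the seed it is
given.

## Known limitations

- The semantic space is count-based and window-local; it cannot
  distinguish "not lonely" from "lonely".
- The 30-word representation discards all but the most frequent content
  words; short documents are represented by very few words, and a
  document with no tagged nouns/verbs/adjectives is unscorable (`NA`).
- Trait scores are relative to the background corpus: changing the
  background changes every score. Scores are not calibrated against any
  clinical instrument, and no threshold on them has diagnostic meaning.
- The in-sample screening metric quantifies triage efficiency on the
  collection at hand; it is not an estimate of out-of-sample detection
  performance (use `mode = "cv"` for that, and expect weaker numbers).
- With six positives, every statistic is fragile: permutation p-values
  are exact-in-law but the scientific conclusion rests on six documents.
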