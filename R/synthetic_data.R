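# POS assignment for the built-in seed words (pain/misery/agony are nouns,
# the rest adjectives).
seed_word_pos <- function(words) {
  nouns <- c("pain", "misery", "agony")
  stats::setNames(ifelse(words %in% nouns, "NOUN", "ADJ"), words)
}

# Deterministic base-26 letter suffixes: 1 -> "aa", 2 -> "ab", ...
letter_suffix <- function(i) {
  hi <- (i - 1L) %/% 676L; mid <- ((i - 1L) %/% 26L) %% 26L
  lo <- (i - 1L) %% 26L
  paste0(ifelse(hi > 0L, letters[hi], ""), letters[mid + 1L],
         letters[lo + 1L])
}

#' Synthetic-corpus generator configuration
#'
#' Defines a fully synthetic language in which every stage of the pipeline
#' is testable: an abstract vocabulary with a known POS assignment, trait
#' seed words embedded in it, and per-seed "neighborhoods" — context words
#' that preferentially follow a seed word within the co-occurrence window,
#' so that seeds sharing a neighborhood acquire similar vectors. Positive
#' documents can be tilted toward a chosen trait's neighborhood vocabulary
#' by the enrichment dial `enrichment_theta` (0 = exchangeable null, 1 =
#' every content word drawn from the trait's pool).
#'
#' `make_generator_config()` builds a complete configuration: abstract
#' content words (`noun…`, `verb…`, `adj…`), frequent function words
#' (`fw…`, tagged OTHER), the lexicon's seed words, and one neighborhood
#' per trait (shared by that trait's seeds, disjoint across traits when
#' the vocabulary is large enough, so off-trait specificity is testable).
#'
#' @param vocab_size Total vocabulary size, seed words included.
#' @param n_background_docs Background corpus size (documents).
#' @param doc_length Tokens per document.
#' @param n_positive,n_comparison Labeled corpus composition.
#' @param enrichment_theta Enrichment level in `[0, 1]`.
#' @param lexicon Trait lexicon whose seeds are planted
#'   (default [builtin_lexicon()]).
#' @param neighborhood_size Context words per trait neighborhood.
#' @param window Span (tokens) over which a seed word pulls its
#'   neighborhood words in behind it.
#' @param follow_prob Probability that each of the `window` slots after a
#'   seed occurrence is overwritten with a neighborhood draw.
#' @param seed Integer seed driving every random choice.
#' @return An object of class `ts_generator_config`.
#' @export
make_generator_config <- function(vocab_size = 500L, n_background_docs = 300L,
                                  doc_length = 100L, n_positive = 6L,
                                  n_comparison = 100L, enrichment_theta = 0.5,
                                  lexicon = builtin_lexicon(),
                                  neighborhood_size = 6L, window = 3L,
                                  follow_prob = 0.85, seed = 1L) {
  stopifnot(enrichment_theta >= 0, enrichment_theta <= 1,
            n_background_docs >= 1L, doc_length >= 4L)
  seeds <- unique(unlist(lapply(lexicon, function(t) t$seed_words)))
  n_content <- vocab_size - length(seeds)
  if (n_content < 10L)
    stop("vocab_size too small to hold the seed words plus content words")
  n_fw <- max(4L, round(0.1 * n_content))
  n_rest <- n_content - n_fw
  n_noun <- ceiling(n_rest / 3); n_verb <- ceiling((n_rest - n_noun) / 2)
  n_adj <- n_rest - n_noun - n_verb
  # Letter-only suffixes: the tokenizer treats digits as separators, so
  # vocabulary words must be pure letter runs to survive round-tripping.
  content <- c(paste0("noun", letter_suffix(seq_len(n_noun))),
               paste0("verb", letter_suffix(seq_len(n_verb))),
               paste0("adj", letter_suffix(seq_len(n_adj))))
  fw <- paste0("fw", letter_suffix(seq_len(n_fw)))
  pos_dictionary <- c(
    stats::setNames(rep(c("NOUN", "VERB", "ADJ"), c(n_noun, n_verb, n_adj)),
                    content),
    stats::setNames(rep("OTHER", n_fw), fw),
    seed_word_pos(seeds))

  # One neighborhood per trait, shared by its seeds; disjoint across traits
  # when the content vocabulary allows, otherwise sampled with overlap.
  neigh <- with_seed(derive_seed(seed, "neighborhoods"), {
    pool <- sample(content)
    out <- list()
    need <- neighborhood_size * length(lexicon)
    for (i in seq_along(lexicon)) {
      words <- if (need <= length(content))
        pool[((i - 1) * neighborhood_size + 1):(i * neighborhood_size)]
      else sample(content, neighborhood_size)
      for (s in lexicon[[i]]$seed_words) out[[s]] <- words
    }
    out
  })
  # A seed in several traits keeps the neighborhood of the last trait
  # listing it; overlap across traits is allowed by design.
  structure(list(vocab_size = as.integer(vocab_size),
                 n_background_docs = as.integer(n_background_docs),
                 doc_length = as.integer(doc_length),
                 n_positive = as.integer(n_positive),
                 n_comparison = as.integer(n_comparison),
                 enrichment_theta = enrichment_theta,
                 lexicon = lexicon,
                 trait_neighborhoods = neigh,
                 pos_dictionary = pos_dictionary,
                 vocabulary = names(pos_dictionary),
                 window = as.integer(window),
                 follow_prob = follow_prob,
                 seed = as.integer(seed)),
            class = "ts_generator_config")
}

# Unigram sampling weights: function words frequent, seed words slightly
# boosted so co-occurrence counts accumulate at realistic corpus sizes.
unigram_weights <- function(config) {
  pos <- config$pos_dictionary
  w <- ifelse(pos == "OTHER", 6, 1)
  w[names(pos) %in% names(config$trait_neighborhoods)] <- 3
  stats::setNames(w, names(pos))
}

# One document as a token vector: unigram draws, then each seed-word
# occurrence pulls neighborhood words into the following window slots.
gen_tokens <- function(config, weights) {
  n <- config$doc_length
  toks <- sample(config$vocabulary, n, replace = TRUE, prob = weights)
  neigh <- config$trait_neighborhoods
  if (length(neigh) > 0L) {
    sp <- which(toks %in% names(neigh))
    for (p in sp) {
      hood <- neigh[[toks[p]]]
      if (length(hood) == 0L) next
      for (o in seq_len(min(config$window, n - p)))
        if (stats::runif(1) < config$follow_prob)
          toks[p + o] <- hood[sample.int(length(hood), 1L)]
    }
  }
  toks
}

check_neighborhoods <- function(config) {
  all_words <- unlist(config$trait_neighborhoods, use.names = FALSE)
  bad <- setdiff(c(all_words, names(config$trait_neighborhoods)),
                 config$vocabulary)
  if (length(bad) > 0L)
    stop("trait neighborhood references out-of-vocabulary word(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
}

#' Generate a synthetic background corpus
#'
#' Documents are sampled token-by-token from the configured unigram
#' distribution; whenever a trait seed word is emitted, the following
#' `window` token slots are overwritten, each with probability
#' `follow_prob`, by draws from that seed's neighborhood. First-order
#' dependence only: the semantic-space stage measures windowed pair counts,
#' so first-order structure is all that is needed to plant co-occurrence
#' signal. Deterministic given `config$seed`.
#'
#' @param config A [make_generator_config()].
#' @return A `ts_corpus` of `n_background_docs` documents.
#' @export
generate_background <- function(config) {
  check_neighborhoods(config)
  weights <- unigram_weights(config)
  docs <- with_seed(derive_seed(config$seed, "background"), {
    lapply(seq_len(config$n_background_docs), function(i)
      ts_document(sprintf("bg%05d", i),
                  paste(gen_tokens(config, weights), collapse = " ")))
  })
  ts_corpus(docs)
}

#' Generate a labeled synthetic corpus with trait enrichment
#'
#' Comparison documents follow exactly the background process. Positive
#' documents are generated the same way, after which a fraction
#' `enrichment_theta` of their content-word positions (tokens tagged NOUN,
#' VERB or ADJ) is replaced by draws from the target trait's pool — the
#' union of its seeds' neighborhoods and the seed words themselves. At
#' `theta = 0` the classes are exchangeable; at `theta = 1` every content
#' word of a positive document comes from the pool.
#'
#' @param config A [make_generator_config()].
#' @param trait Name of the target trait (must be in `config$lexicon`).
#' @return A labeled `ts_corpus` of `n_positive + n_comparison` documents
#'   (positives first).
#' @export
generate_labeled <- function(config, trait = "Revengeful") {
  check_neighborhoods(config)
  if (!trait %in% names(config$lexicon))
    stop("trait '", trait, "' is not in the configured lexicon")
  if (config$n_positive < 1L) stop("n_positive must be >= 1")
  weights <- unigram_weights(config)
  seeds <- config$lexicon[[trait]]$seed_words
  pool <- unique(c(unlist(config$trait_neighborhoods[seeds],
                          use.names = FALSE), seeds))
  theta <- config$enrichment_theta
  pos_of <- config$pos_dictionary

  docs <- with_seed(derive_seed(config$seed, paste0("labeled:", trait)), {
    make_doc <- function(id, positive) {
      toks <- gen_tokens(config, weights)
      if (positive && theta > 0) {
        content <- which(pos_of[toks] %in% c("NOUN", "VERB", "ADJ"))
        swap <- content[stats::runif(length(content)) < theta]
        if (length(swap) > 0L)
          toks[swap] <- pool[sample.int(length(pool), length(swap),
                                        replace = TRUE)]
      }
      ts_document(id, paste(toks, collapse = " "),
                  label = if (positive) "positive" else "comparison")
    }
    c(lapply(seq_len(config$n_positive), function(i)
        make_doc(sprintf("pos%03d", i), TRUE)),
      lapply(seq_len(config$n_comparison), function(i)
        make_doc(sprintf("cmp%05d", i), FALSE)))
  })
  ts_corpus(docs)
}

#' Ready-made synthetic bundles at three scales
#'
#' `"tiny"` (50-word vocabulary, 30 background documents) is for unit
#' tests; `"small"` (500 / 300) for integration tests; `"paper_shaped"`
#' keeps the 6-positive class of the motivating screening problem against
#' 2000 comparison documents, a reduced-scale version of a 6-versus-6056
#' collection. The tiny vocabulary is dominated by the 31 seed words, so
#' its trait neighborhoods overlap; the larger scales keep them disjoint.
#'
#' @param size `"tiny"`, `"small"` or `"paper_shaped"`.
#' @param seed Integer seed.
#' @param enrichment_theta Enrichment of the labeled positives (defaults:
#'   0.5 for tiny/small, 0.8 for paper_shaped).
#' @param trait Target trait for the labeled corpus.
#' @return A list of class `ts_bundle`: `background` (`ts_corpus`),
#'   `labeled` (labeled `ts_corpus`), `truth` (the
#'   `ts_generator_config` used).
#' @export
make_fixture_bundle <- function(size = c("tiny", "small", "paper_shaped"),
                                seed = 1L, enrichment_theta = NULL,
                                trait = "Revengeful") {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = make_generator_config(
      vocab_size = 50L, n_background_docs = 30L, doc_length = 60L,
      n_positive = 3L, n_comparison = 12L, neighborhood_size = 2L,
      enrichment_theta = if (is.null(enrichment_theta)) 0.5
                         else enrichment_theta,
      seed = seed),
    small = make_generator_config(
      vocab_size = 500L, n_background_docs = 300L, doc_length = 80L,
      n_positive = 10L, n_comparison = 90L,
      enrichment_theta = if (is.null(enrichment_theta)) 0.5
                         else enrichment_theta,
      seed = seed),
    paper_shaped = make_generator_config(
      vocab_size = 500L, n_background_docs = 300L, doc_length = 100L,
      n_positive = 6L, n_comparison = 2000L,
      enrichment_theta = if (is.null(enrichment_theta)) 0.8
                         else enrichment_theta,
      seed = seed))
  structure(list(background = generate_background(cfg),
                 labeled = generate_labeled(cfg, trait = trait),
                 truth = cfg),
            class = "ts_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes `background/` and `labeled/` corpus directories, the labels CSV
#' and a `truth.json` echo of the generator configuration (neighborhoods
#' included), the on-disk layout consumed by [run_pipeline()].
#'
#' @param bundle A `ts_bundle`.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_corpus(bundle$background, file.path(directory, "background"))
  write_corpus(bundle$labeled, file.path(directory, "labeled"))
  cfg <- bundle$truth
  jsonlite::write_json(
    list(vocab_size = cfg$vocab_size,
         n_background_docs = cfg$n_background_docs,
         doc_length = cfg$doc_length, n_positive = cfg$n_positive,
         n_comparison = cfg$n_comparison,
         enrichment_theta = cfg$enrichment_theta,
         trait_neighborhoods = cfg$trait_neighborhoods,
         pos_dictionary = as.list(cfg$pos_dictionary),
         window = cfg$window, follow_prob = cfg$follow_prob,
         seed = cfg$seed),
    file.path(directory, "truth.json"), auto_unbox = TRUE)
  invisible(directory)
}
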