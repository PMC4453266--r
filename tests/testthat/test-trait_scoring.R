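test_that("the built-in lexicon holds the 13 fixed trait vectors", {
  lex <- builtin_lexicon()
  expect_length(lex, 13L)
  expect_equal(names(lex),
               c("DEP", "PPD", "NPD", "SCHYZO", "Hopeless", "Lonely",
                 "Helpless", "Pain", "Revengeful", "Chaotic", "Unsafe",
                 "Abandoned", "Humiliated"))
  expect_equal(lex$NPD$seed_words,
               c("arrogant", "manipulative", "egocentric", "insensitive"))
  expect_equal(lex$DEP$seed_words,
               c("sad", "lonely", "hopeless", "worthless"))
  expect_equal(lex$Revengeful$seed_words,
               c("revengeful", "vengeful", "vindictive"))
  # cross-trait seed overlap is allowed
  has_lonely <- vapply(lex, function(t) "lonely" %in% t$seed_words,
                       logical(1))
  expect_equal(sum(has_lonely), 3L)
  # every seed list is non-empty, unique, lowercase
  for (t in lex) {
    expect_gte(length(t$seed_words), 1L)
    expect_false(anyDuplicated(t$seed_words) > 0)
    expect_equal(t$seed_words, tolower(t$seed_words))
  }
})

test_that("custom lexica load from trait,word CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trait,word", "Gloom,dark", "Gloom,dim", "Calm,still"), f)
  lex <- read_lexicon(f)
  expect_length(lex, 2L)
  expect_equal(lex$Gloom$seed_words, c("dark", "dim"))
})

scoring_fixture <- local({
  # planted corpus: revengeful seeds share contexts; 'calm' lives elsewhere
  texts <- c(rep("revengeful wrath fury", 4), rep("vengeful wrath fury", 4),
             rep("vindictive wrath fury", 4), rep("calm breeze lake", 6),
             rep("still breeze lake", 6))
  names(texts) <- paste0("d", seq_along(texts))
  space <- build_space(corpus_from_texts(texts),
                       space_config(window = 2, weighting = "raw",
                                    min_count = 1))
  tagger <- dictionary_tagger(c(revengeful = "ADJ", vengeful = "ADJ",
                                vindictive = "ADJ", calm = "ADJ",
                                still = "ADJ", wrath = "NOUN",
                                fury = "NOUN", breeze = "NOUN",
                                lake = "NOUN"))
  list(space = space, tagger = tagger)
})

test_that("a representation equal to the seed words scores exactly 1", {
  fx <- scoring_fixture
  rep_seed <- extract_representation(tag_tokens(
    tokenize("revengeful vengeful vindictive"), fx$tagger), "r")
  tr <- builtin_lexicon()$Revengeful
  expect_equal(score_text(fx$space, rep_seed, tr), 1)
})

test_that("orthogonal representations score 0; scores stay in [-1, 1]", {
  fx <- scoring_fixture
  rep_calm <- extract_representation(tag_tokens(
    tokenize("calm lake breeze"), fx$tagger), "c")
  s <- score_text(fx$space, rep_calm, builtin_lexicon()$Revengeful)
  expect_equal(s, 0)
  rep_mix <- extract_representation(tag_tokens(
    tokenize("calm wrath revengeful lake"), fx$tagger), "m")
  s2 <- score_text(fx$space, rep_mix, builtin_lexicon()$Revengeful)
  expect_true(s2 >= -1 && s2 <= 1)
})

test_that("centroid and mean_pairwise agree on single-word vs single-word", {
  fx <- scoring_fixture
  rep1 <- extract_representation(tag_tokens(tokenize("wrath"), fx$tagger),
                                 "w")
  tr <- trait_vector("Fury", "fury")
  expect_equal(score_text(fx$space, rep1, tr, mode = "centroid"),
               score_text(fx$space, rep1, tr, mode = "mean_pairwise"),
               tolerance = 1e-12)
})

test_that("OOV handling: dropped seeds are counted, never silently zeroed", {
  fx <- scoring_fixture
  rep1 <- extract_representation(tag_tokens(tokenize("wrath fury"),
                                            fx$tagger), "w")
  ghost_trait <- trait_vector("Ghost", c("spectral", "phantom"))
  err <- tryCatch(score_text(fx$space, rep1, ghost_trait),
                  condition = identity)
  expect_s3_class(err, "ts_undefined_score")

  part <- trait_vector("Part", c("revengeful", "phantom"))
  expect_no_error(score_text(fx$space, rep1, part))

  lex <- structure(list(Revengeful = builtin_lexicon()$Revengeful,
                        Ghost = ghost_trait),
                   class = "ts_lexicon")
  sm <- score_corpus(fx$space, list(rep1), lexicon = lex)
  expect_true(is.na(sm$scores[1, "Ghost"]))
  expect_false(is.na(sm$scores[1, "Revengeful"]))
  expect_equal(sm$oov[1, "Ghost"], 2L, ignore_attr = TRUE)
})

test_that("score_corpus yields 13 deterministic scores per document", {
  bundle <- make_fixture_bundle("tiny", seed = 4)
  space <- build_space(bundle$background, space_config(min_count = 1))
  tagger <- dictionary_tagger(bundle$truth$pos_dictionary)
  reps <- represent_corpus(bundle$labeled, tagger)
  labs <- stats::setNames(corpus_labels(bundle$labeled),
                          corpus_ids(bundle$labeled))
  s1 <- score_corpus(space, reps, labels = labs)
  s2 <- score_corpus(space, reps, labels = labs)
  expect_equal(dim(s1$scores), c(bundle$labeled$n_docs, 13L))
  expect_identical(s1$scores, s2$scores)
  defined <- s1$scores[!is.na(s1$scores)]
  expect_true(all(defined >= -1 - 1e-12 & defined <= 1 + 1e-12))

  # a document with an all-OTHER representation yields an NA row,
  # and the batch still completes
  blank <- extract_representation(
    tag_tokens(tokenize("zz qq"), dictionary_tagger(c(zz = "OTHER"))), "bl")
  s3 <- score_corpus(space, c(reps, list(blank)), labels = labs)
  expect_true(all(is.na(s3$scores["bl", ])))
  expect_false(anyNA(s3$scores[1, ]))
})

test_that("mean target-trait score rises with enrichment theta", {
  thetas <- c(0, 0.25, 0.5, 1.0)
  means <- numeric(length(thetas))
  space <- NULL
  for (i in seq_along(thetas)) {
    cfg <- make_generator_config(vocab_size = 300, n_background_docs = 150,
                                 doc_length = 60, n_positive = 50,
                                 n_comparison = 1,
                                 enrichment_theta = thetas[i], seed = 77)
    if (is.null(space))  # same seed -> same background and neighborhoods
      space <- build_space(generate_background(cfg), space_config())
    lab <- generate_labeled(cfg, "Revengeful")
    reps <- represent_corpus(lab, dictionary_tagger(cfg$pos_dictionary))
    sc <- score_corpus(space, reps,
                       labels = stats::setNames(corpus_labels(lab),
                                                corpus_ids(lab)))
    means[i] <- mean(sc$scores[sc$labels == "positive", "Revengeful"],
                     na.rm = TRUE)
  }
  expect_true(all(diff(means) > 0))
})

test_that("enrichment toward one trait is specific to that trait", {
  cfg <- make_generator_config(vocab_size = 300, n_background_docs = 150,
                               doc_length = 60, n_positive = 20,
                               n_comparison = 50, enrichment_theta = 0.8,
                               seed = 19)
  space <- build_space(generate_background(cfg), space_config())
  lab <- generate_labeled(cfg, "Revengeful")
  sc <- score_corpus(space, represent_corpus(lab,
                       dictionary_tagger(cfg$pos_dictionary)),
                     labels = stats::setNames(corpus_labels(lab),
                                              corpus_ids(lab)))
  delta <- function(tr) {
    mean(sc$scores[sc$labels == "positive", tr], na.rm = TRUE) -
      mean(sc$scores[sc$labels == "comparison", tr], na.rm = TRUE)
  }
  expect_gt(delta("Revengeful"), delta("Chaotic"))
  expect_gt(delta("Revengeful"), 0)
})
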