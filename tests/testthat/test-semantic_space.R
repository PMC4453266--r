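test_that("windowed co-occurrence matches hand enumeration", {
  corp <- corpus_from_texts(c(d = "sad lonely sad"))
  cooc <- build_cooccurrence(corp, space_config(window = 1, min_count = 0))
  expect_equal(cooc$counts["sad", "lonely"], 2)
  expect_equal(cooc$counts["sad", "sad"], 0)
  expect_equal(cooc$counts["lonely", "lonely"], 0)
})

test_that("windows never cross document boundaries", {
  corp <- corpus_from_texts(c(d1 = "a b", d2 = "c d"))
  cooc <- build_cooccurrence(corp, space_config(window = 3, min_count = 0))
  expect_equal(cooc$counts["b", "c"], 0)
  expect_equal(cooc$counts["a", "b"], 1)
})

test_that("co-occurrence agrees with the brute-force oracle and is symmetric", {
  for (s in 1:5) {
    set.seed(100 + s)
    vocab <- letters[1:8]
    texts <- vapply(1:4, function(i)
      paste(sample(vocab, 30, replace = TRUE), collapse = " "), character(1))
    names(texts) <- paste0("d", 1:4)
    corp <- corpus_from_texts(texts)
    w <- sample(1:4, 1)
    cooc <- build_cooccurrence(corp, space_config(window = w, min_count = 0))
    oracle <- bf_cooccurrence(corpus_token_lists(corp), w)
    got <- as.matrix(cooc$counts)[rownames(oracle), colnames(oracle)]
    expect_equal(got, oracle, ignore_attr = TRUE)
    expect_equal(as.matrix(cooc$counts), t(as.matrix(cooc$counts)))
  }
})

test_that("min_count prunes the vocabulary after counting", {
  corp <- corpus_from_texts(c(d = "a a b a b c"))
  cooc <- build_cooccurrence(corp, space_config(window = 1, min_count = 2))
  expect_setequal(cooc$vocabulary, c("a", "b"))
  expect_error(build_cooccurrence(corp, space_config(window = 1,
                                                     min_count = 10)),
               "empty")
})

test_that("PPMI matches its closed form; raw is the identity", {
  cooc <- structure(list(vocabulary = c("x", "y"),
                         counts = Matrix::Matrix(matrix(c(0, 4, 4, 0), 2,
                           dimnames = list(c("x", "y"), c("x", "y"))))),
                    class = "ts_cooc")
  w <- weight_cooccurrence(cooc, "ppmi")
  # T = 8, r = (4, 4): log2(4 * 8 / 16) = 1 for both off-diagonal cells
  expect_equal(w["x", "y"], 1)
  expect_equal(w["y", "x"], 1)
  expect_equal(as.matrix(weight_cooccurrence(cooc, "raw")),
               as.matrix(cooc$counts))

  # observed below chance expectation clamps to zero
  m <- matrix(c(0, 1, 8, 1, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cooc2 <- structure(list(vocabulary = rownames(m),
                          counts = Matrix::Matrix(m)), class = "ts_cooc")
  w2 <- weight_cooccurrence(cooc2, "ppmi")
  expect_equal(w2["a", "b"], 0)  # 1 * 34 < 9 * 9
  expect_true(all(as.matrix(w2) >= 0))
})

test_that("PPMI and cosine agree with brute force to 1e-10", {
  bundle <- make_fixture_bundle("tiny", seed = 3)
  space <- build_space(bundle$background, space_config(min_count = 1))
  expect_lte(length(space$vocabulary), 60)

  cooc <- build_cooccurrence(bundle$background, space_config(min_count = 1))
  oracle_w <- bf_ppmi(as.matrix(cooc$counts))
  expect_equal(as.matrix(weight_cooccurrence(cooc, "ppmi")), oracle_w,
               tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(42)
  words <- sample(space$vocabulary, 12)
  for (a in words[1:6]) for (b in words[7:12]) {
    ora <- bf_cosine(oracle_w[a, ], oracle_w[b, ])
    expect_equal(similarity(space, a, b), ora, tolerance = 1e-10)
  }
})

test_that("similarity is symmetric, bounded, and 1 on the diagonal", {
  space <- build_space(corpus_from_texts(
    c(d = "sad lonely pain sad misery lonely pain sad")),
    space_config(window = 2, min_count = 1))
  for (a in space$vocabulary) for (b in space$vocabulary) {
    s <- similarity(space, a, b)
    expect_lte(abs(s), 1 + 1e-12)
    expect_equal(s, similarity(space, b, a), tolerance = 1e-12)
  }
  expect_equal(similarity(space, "sad", "sad"), 1)
})

test_that("zero-norm vectors yield similarity 0, OOV raises a typed error", {
  # 'solo' occurs alone in its document: no co-occurrences, zero vector
  space <- build_space(corpus_from_texts(c(d1 = "a b a b", d2 = "solo")),
                       space_config(window = 1, min_count = 1))
  expect_equal(similarity(space, "solo", "a"), 0)

  err <- tryCatch(similarity(space, "ghost", "a"), condition = identity)
  expect_s3_class(err, "ts_oov_error")
  expect_equal(err$word, "ghost")
})

test_that("raw-weighted coordinates reproduce planted co-occurrence counts", {
  # depressed next to anxious six times and to angry three times
  texts <- c(rep("depressed anxious", 6), rep("depressed angry", 3))
  names(texts) <- paste0("d", seq_along(texts))
  space <- build_space(corpus_from_texts(texts),
                       space_config(window = 1, weighting = "raw",
                                    min_count = 0))
  v <- space$vectors["depressed", ]
  expect_equal(unname(v[c("anxious", "angry")]), c(6, 3))
})

test_that("full-rank SVD preserves pairwise cosines", {
  corp <- corpus_from_texts(
    c(d1 = "a b c d a c", d2 = "b d a e c e", d3 = "e a d b c a"))
  plain <- build_space(corp, space_config(window = 2, min_count = 1))
  k <- length(plain$vocabulary)
  reduced <- build_space(corp, space_config(window = 2, min_count = 1,
                                            svd_dim = k))
  for (a in plain$vocabulary) for (b in plain$vocabulary)
    expect_equal(similarity(reduced, a, b), similarity(plain, a, b),
                 tolerance = 1e-8)
  expect_error(build_space(corp, space_config(min_count = 1,
                                              svd_dim = k + 1)),
               "svd_dim")
})

test_that("scaling all counts leaves raw cosines unchanged", {
  corp <- corpus_from_texts(c(d = "a b c a b d c a"))
  cooc <- build_cooccurrence(corp, space_config(window = 2, min_count = 0))
  w1 <- as.matrix(weight_cooccurrence(cooc, "raw"))
  cooc$counts <- cooc$counts * 7
  w7 <- as.matrix(weight_cooccurrence(cooc, "raw"))
  for (i in 1:nrow(w1)) for (j in 1:nrow(w1))
    expect_equal(bf_cosine(w1[i, ], w1[j, ]), bf_cosine(w7[i, ], w7[j, ]),
                 tolerance = 1e-12)
})

test_that("build_space is deterministic", {
  bundle <- make_fixture_bundle("tiny", seed = 5)
  s1 <- build_space(bundle$background, space_config(min_count = 1))
  s2 <- build_space(bundle$background, space_config(min_count = 1))
  expect_identical(s1$vectors, s2$vectors)
})

test_that("neighbors ranks by similarity with alphabetical tie-break", {
  # x and y have identical co-occurrence profiles (only with 'a')
  corp <- corpus_from_texts(c(d1 = "x a", d2 = "y a", d3 = "x a", d4 = "y a"))
  space <- build_space(corp, space_config(window = 1, weighting = "raw",
                                          min_count = 1))
  nb <- neighbors(space, "a", n = 10)
  expect_equal(nb$word, c("x", "y"))  # tie broken alphabetically
  expect_equal(nb$similarity[1], nb$similarity[2])

  # n larger than vocabulary returns all other words
  expect_equal(nrow(neighbors(space, "x", n = 100)), 2L)
  expect_error(neighbors(space, "ghost"), "vocabulary")
})

test_that("a planted dominant co-occurrence becomes the first neighbor", {
  texts <- c(rep("depressed anxious", 8), rep("depressed angry", 2),
             "calm quiet calm")
  names(texts) <- paste0("d", seq_along(texts))
  space <- build_space(corpus_from_texts(texts),
                       space_config(window = 1, weighting = "raw",
                                    min_count = 0))
  # verify against an exhaustive cosine scan with the oracle
  w <- as.matrix(weight_cooccurrence(
    build_cooccurrence(corpus_from_texts(texts),
                       space_config(window = 1, min_count = 0)), "raw"))
  sims <- vapply(setdiff(rownames(w), "depressed"),
                 function(x) bf_cosine(w["depressed", ], w[x, ]), numeric(1))
  expect_equal(neighbors(space, "depressed", n = 1)$word,
               names(which.max(sims)))
})

test_that("neighbors honours a POS filter", {
  corp <- corpus_from_texts(c(d1 = "sad grief", d2 = "sad weep"))
  space <- build_space(corp, space_config(window = 1, min_count = 1))
  lookup <- c(grief = "NOUN", weep = "VERB", sad = "ADJ")
  nb <- neighbors(space, "sad", n = 5, pos_filter = "NOUN",
                  pos_lookup = lookup)
  expect_equal(nb$word, "grief")
  expect_error(neighbors(space, "sad", pos_filter = "NOUN"), "pos_lookup")
})

test_that("a space round-trips through its serialized form", {
  bundle <- make_fixture_bundle("tiny", seed = 9)
  space <- build_space(bundle$background,
                       space_config(min_count = 1, svd_dim = 10))
  prefix <- file.path(withr::local_tempdir(), "space")
  write_space(space, prefix)
  back <- read_space(prefix)
  expect_equal(back$vocabulary, space$vocabulary)
  expect_equal(back$vectors, space$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$config$svd_dim, 10L)
})
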