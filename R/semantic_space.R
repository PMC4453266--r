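#' Configuration of a distributional semantic space
#'
#' Controls how word vectors are built from a background corpus: a symmetric
#' co-occurrence window of `window` tokens to each side (never crossing
#' document boundaries), an association weighting (`"ppmi"` or `"raw"`
#' counts), an optional truncated-SVD reduction, and a vocabulary floor.
#'
#' @param window Tokens counted to each side of the target (default 3).
#' @param weighting `"ppmi"` (positive pointwise mutual information, the
#'   default) or `"raw"` (unweighted counts).
#' @param svd_dim Dimension of the truncated SVD, or `NULL` (default) to
#'   keep the full weighted co-occurrence rows as vectors.
#' @param min_count Words with corpus frequency below this are dropped from
#'   the vocabulary after counting (default 2).
#' @return An object of class `ts_space_config`.
#' @export
space_config <- function(window = 3L, weighting = c("ppmi", "raw"),
                         svd_dim = NULL, min_count = 2L) {
  weighting <- match.arg(weighting)
  window <- as.integer(window)
  stopifnot(window >= 1L, min_count >= 0L)
  if (!is.null(svd_dim)) {
    svd_dim <- as.integer(svd_dim)
    stopifnot(svd_dim >= 1L)
  }
  structure(list(window = window, weighting = weighting,
                 svd_dim = svd_dim, min_count = as.integer(min_count)),
            class = "ts_space_config")
}

#' Windowed co-occurrence counts over a corpus
#'
#' For every token position `p` and offset `d` in `1..window`, the pair of
#' normalized forms at `(p, p + d)` increments both `counts[i, j]` and
#' `counts[j, i]`, provided both positions lie in the same document. Counts
#' are unweighted by distance within the window. The diagonal is zero:
#' repeated occurrences of the same word type do not co-occur with
#' themselves. After counting, words whose corpus frequency falls below
#' `config$min_count` are dropped from the vocabulary.
#'
#' @param corpus A `ts_corpus`.
#' @param config A [space_config()].
#' @return A list of class `ts_cooc` with elements `vocabulary` (ordered
#'   word list) and `counts` (symmetric sparse matrix,
#'   [Matrix::sparseMatrix()]).
#' @export
build_cooccurrence <- function(corpus, config = space_config()) {
  stopifnot(inherits(corpus, "ts_corpus"), corpus$n_docs >= 1L)
  toks <- lapply(corpus$documents, function(d) tokenize(d$raw_text)$normalized)
  w <- unlist(toks, use.names = FALSE)
  if (length(w) == 0L) stop("corpus contains no tokens")
  docid <- rep.int(seq_along(toks), lengths(toks))

  vocab <- sort(unique(w), method = "radix")
  idx <- match(w, vocab)
  n <- length(idx)
  ii <- integer(0); jj <- integer(0)
  for (d in seq_len(config$window)) {
    if (n <= d) break
    a <- idx[seq_len(n - d)]
    b <- idx[seq_len(n - d) + d]
    same <- docid[seq_len(n - d)] == docid[seq_len(n - d) + d] & a != b
    ii <- c(ii, a[same]); jj <- c(jj, b[same])
  }
  counts <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                                 dims = c(length(vocab), length(vocab)),
                                 dimnames = list(vocab, vocab))

  keep <- tabulate(idx, nbins = length(vocab)) >= config$min_count
  if (!any(keep))
    stop("vocabulary is empty after applying min_count = ", config$min_count)
  structure(list(vocabulary = vocab[keep],
                 counts = counts[keep, keep, drop = FALSE]),
            class = "ts_cooc")
}

#' Association-weight a co-occurrence matrix
#'
#' PPMI weighting replaces each count `c[i, j]` with
#' `max(0, log2(c[i, j] * T / (r[i] * r[j])))`, where `r` are the row sums
#' of the count matrix and `T` its total; cells whose observed count falls
#' below chance expectation are clamped to zero. `"raw"` is the identity.
#'
#' @param cooc A `ts_cooc` from [build_cooccurrence()].
#' @param scheme `"ppmi"` or `"raw"`.
#' @return A sparse weighted matrix with the same dimnames.
#' @export
weight_cooccurrence <- function(cooc, scheme = c("ppmi", "raw")) {
  scheme <- match.arg(scheme)
  counts <- cooc$counts
  total <- sum(counts)
  if (total == 0) stop("co-occurrence matrix is all zero")
  if (scheme == "raw") return(counts)
  r <- Matrix::rowSums(counts)
  w <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  # PPMI on the nonzero cells only; zero counts map to zero weight.
  val <- log2(w@x * total / (r[w@i + 1L] * r[w@j + 1L]))
  w@x <- pmax(0, val)
  Matrix::drop0(methods::as(w, "CsparseMatrix"))
}

#' Build a semantic space from a background corpus
#'
#' Counts windowed co-occurrences, applies the association weighting, and
#' (optionally) reduces the weighted matrix to `svd_dim` dimensions by
#' truncated singular-value decomposition; vectors are then the left
#' singular vectors scaled by the singular values. Without SVD, each word's
#' vector is its weighted co-occurrence row. The whole construction is
#' deterministic: no randomized decomposition is used.
#'
#' @inheritParams build_cooccurrence
#' @return An object of class `ts_space` with elements `vocabulary`,
#'   `vectors` (dense matrix, one row per word) and `config`.
#' @export
build_space <- function(corpus, config = space_config()) {
  cooc <- build_cooccurrence(corpus, config)
  w <- weight_cooccurrence(cooc, config$weighting)
  if (!is.null(config$svd_dim)) {
    k <- config$svd_dim
    if (k > length(cooc$vocabulary))
      stop("svd_dim (", k, ") exceeds vocabulary size (",
           length(cooc$vocabulary), ")")
    dec <- svd(as.matrix(w), nu = k, nv = 0)
    vectors <- dec$u %*% diag(dec$d[seq_len(k)], nrow = k)
    rownames(vectors) <- cooc$vocabulary
  } else {
    vectors <- as.matrix(w)
  }
  structure(list(vocabulary = cooc$vocabulary, vectors = vectors,
                 config = config),
            class = "ts_space")
}

#' @export
print.ts_space <- function(x, ...) {
  cat("<ts_space> ", length(x$vocabulary), " words x ", ncol(x$vectors),
      " dims (", x$config$weighting,
      if (!is.null(x$config$svd_dim)) paste0(", svd ", x$config$svd_dim),
      ", window ", x$config$window, ")\n", sep = "")
  invisible(x)
}

oov_error <- function(word) {
  stop(errorCondition(paste0("word not in vocabulary: ", word),
                      word = word,
                      class = c("ts_oov_error", "error", "condition")))
}

space_vector <- function(space, word) {
  i <- match(word, space$vocabulary)
  if (is.na(i)) oov_error(word)
  space$vectors[i, ]
}

cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Cosine similarity between two vocabulary words
#'
#' Returns the cosine of the two word vectors, in `[-1, 1]`; a zero-norm
#' vector yields 0 rather than an error so that batch scoring stays total.
#' An out-of-vocabulary word raises a condition of class `ts_oov_error`
#' carrying the offending word in its `word` field.
#'
#' @param space A `ts_space`.
#' @param word_a,word_b Words to compare (normalized/lowercase forms).
#' @return A number in `[-1, 1]`.
#' @export
similarity <- function(space, word_a, word_b) {
  cosine(space_vector(space, word_a), space_vector(space, word_b))
}

#' Nearest neighbors of a word in the space
#'
#' Top-`n` other words by descending cosine similarity, ties broken
#' alphabetically. An optional part-of-speech filter restricts candidates
#' via a supplied word-to-POS lookup.
#'
#' @inheritParams similarity
#' @param word Query word.
#' @param n Number of neighbors to return (capped at vocabulary size - 1).
#' @param pos_filter Optional POS category (`"NOUN"`, `"VERB"`, `"ADJ"`,
#'   `"OTHER"`); requires `pos_lookup`.
#' @param pos_lookup Named character vector mapping word to POS category.
#' @return A data frame with columns `word` and `similarity`, ordered by
#'   descending similarity.
#' @export
neighbors <- function(space, word, n = 10L, pos_filter = NULL,
                      pos_lookup = NULL) {
  v <- space_vector(space, word)
  cand <- setdiff(space$vocabulary, word)
  if (!is.null(pos_filter)) {
    if (is.null(pos_lookup))
      stop("pos_filter requires a pos_lookup word -> POS mapping")
    cand <- cand[!is.na(pos_lookup[cand]) & pos_lookup[cand] == pos_filter]
  }
  sims <- vapply(cand, function(w) cosine(v, space_vector(space, w)),
                 numeric(1))
  ord <- order(-sims, cand, method = "radix")
  top <- utils::head(ord, n)
  data.frame(word = cand[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize / load a semantic space
#'
#' A space is stored as three plain files sharing a path prefix:
#' `<prefix>.vocab.txt` (one word per line), `<prefix>.vectors.txt`
#' (whitespace-delimited rows, full precision) and `<prefix>.json` (the
#' configuration echo).
#'
#' @param space A `ts_space`.
#' @param prefix Path prefix for the three files.
#' @return `write_space()` returns `prefix` invisibly; `read_space()` the
#'   reconstructed `ts_space`.
#' @export
write_space <- function(space, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  writeLines(space$vocabulary, paste0(prefix, ".vocab.txt"), useBytes = TRUE)
  utils::write.table(format(space$vectors, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     paste0(prefix, ".vectors.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  cfg <- space$config
  jsonlite::write_json(list(window = cfg$window, weighting = cfg$weighting,
                            svd_dim = cfg$svd_dim, min_count = cfg$min_count),
                       paste0(prefix, ".json"), auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_space
#' @export
read_space <- function(prefix) {
  vocab <- readLines(paste0(prefix, ".vocab.txt"), encoding = "UTF-8")
  vecs <- as.matrix(utils::read.table(paste0(prefix, ".vectors.txt")))
  dimnames(vecs) <- list(vocab, NULL)
  cfg <- jsonlite::read_json(paste0(prefix, ".json"))
  structure(list(vocabulary = vocab, vectors = vecs,
                 config = space_config(window = cfg$window,
                                       weighting = cfg$weighting,
                                       svd_dim = cfg$svd_dim,
                                       min_count = cfg$min_count)),
            class = "ts_space")
}
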