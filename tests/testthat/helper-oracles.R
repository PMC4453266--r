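# Independent brute-force oracles, deliberately written without reusing any
# package internals so they can cross-check the implementation.

# Corpus from a named character vector of texts.
corpus_from_texts <- function(texts, labels = NULL) {
  docs <- lapply(names(texts), function(id)
    ts_document(id, texts[[id]],
                label = if (is.null(labels)) NA_character_
                        else labels[[id]]))
  ts_corpus(docs)
}

# Brute-force windowed co-occurrence counts by nested position loops.
bf_cooccurrence <- function(token_lists, window) {
  vocab <- sort(unique(unlist(token_lists)))
  n <- length(vocab)
  counts <- matrix(0, n, n, dimnames = list(vocab, vocab))
  for (toks in token_lists) {
    for (p in seq_along(toks)) {
      for (d in seq_len(window)) {
        q <- p + d
        if (q > length(toks)) break
        a <- toks[p]; b <- toks[q]
        if (a == b) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts
}

# Brute-force PPMI from a dense count matrix.
bf_ppmi <- function(counts) {
  total <- sum(counts)
  r <- rowSums(counts)
  out <- counts * 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      if (counts[i, j] > 0)
        out[i, j] <- max(0, log2(counts[i, j] * total / (r[i] * r[j])))
  out
}

bf_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Pairwise-count Mann-Whitney U of x, ties 0.5 (direct double loop).
bf_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  u
}

# Exact permutation p-value by full enumeration of group-1 index sets.
bf_exact_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- bf_u(x, y)
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(ix) bf_u(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  pg <- mean(us >= u_obs - eps)
  pl <- mean(us <= u_obs + eps)
  switch(alternative,
         greater = pg, less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

# The generator's configured unigram sampling weights (its own parameters,
# needed as the reference distribution for goodness-of-fit checks).
unigram_weights_for_test <- function(cfg) traitscreen:::unigram_weights(cfg)

# Token vectors of a corpus (normalized), for oracle counting.
corpus_token_lists <- function(corpus) {
  lapply(corpus$documents, function(d) tokenize(d$raw_text)$normalized)
}
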