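#' Trait vectors and the built-in lexicon
#'
#' A trait vector is a short ordered list of lowercase seed words standing
#' for one psychological dimension; a document is scored by the semantic
#' proximity of its representation to those seeds. The built-in lexicon
#' holds the 13 dimensions used throughout the package, in fixed order:
#' four personality-disorder dimensions drawn from DSM/Millon theorizing
#' (depressivity, paranoid, narcissistic and schizoid/schizotypal), and
#' nine facets of vengeful behavior. Seed words may recur across traits
#' (e.g. *lonely*).
#'
#' @param name Trait name.
#' @param seed_words Non-empty character vector of unique seed words
#'   (lowercased internally).
#' @return `trait_vector()` returns a `ts_trait`; `builtin_lexicon()` a
#'   `ts_lexicon`, a named ordered list of 13 `ts_trait` objects.
#' @export
trait_vector <- function(name, seed_words) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seed_words), length(seed_words) >= 1L)
  seed_words <- tolower(seed_words)
  if (anyDuplicated(seed_words))
    stop("duplicate seed words in trait ", name)
  structure(list(name = name, seed_words = seed_words), class = "ts_trait")
}

#' @rdname trait_vector
#' @export
builtin_lexicon <- function() {
  defs <- list(
    DEP        = c("sad", "lonely", "hopeless", "worthless"),
    PPD        = c("suspicious", "hypersensitive", "wronged", "hostile"),
    NPD        = c("arrogant", "manipulative", "egocentric", "insensitive"),
    SCHYZO     = c("detached", "avoidant", "lonely", "indifferent"),
    Hopeless   = c("hopeless", "desperate"),
    Lonely     = c("lonely", "lonesome"),
    Helpless   = c("helpless", "defenseless"),
    Pain       = c("pain", "misery", "agony"),
    Revengeful = c("revengeful", "vengeful", "vindictive"),
    Chaotic    = c("chaotic", "disordered"),
    Unsafe     = c("unsafe", "insecure"),
    Abandoned  = c("abandoned", "deserted"),
    Humiliated = c("humiliated", "shamed"))
  lex <- mapply(trait_vector, names(defs), defs, SIMPLIFY = FALSE)
  structure(lex, class = "ts_lexicon")
}

#' Load a custom lexicon from CSV
#'
#' Supports alternative psychological theorizations: a two-column CSV
#' (`trait,word`) defines one trait per distinct `trait` value, in first
#' appearance order.
#'
#' @param path CSV file with columns `trait`, `word`.
#' @return A `ts_lexicon`.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("trait", "word") %in% names(tab)))
    stop("lexicon CSV must have columns trait,word")
  traits <- unique(tab$trait)
  lex <- lapply(traits, function(tr)
    trait_vector(tr, tab$word[tab$trait == tr]))
  names(lex) <- traits
  structure(lex, class = "ts_lexicon")
}

#' @export
print.ts_lexicon <- function(x, ...) {
  cat("<ts_lexicon> ", length(x), " traits: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

undefined_score_error <- function(msg) {
  stop(errorCondition(msg, class = c("ts_undefined_score", "error",
                                     "condition")))
}

#' Similarity of one document representation to one trait vector
#'
#' The default `"centroid"` mode takes the cosine between the mean vector
#' of the representation's in-vocabulary words and the mean vector of the
#' trait's in-vocabulary seed words. `"mean_pairwise"` averages the cosine
#' over every (representation word, seed word) pair. Out-of-vocabulary
#' words are dropped; if the usable representation or the trait becomes
#' empty, a condition of class `ts_undefined_score` is raised — never a
#' silent zero, which would bias group comparisons.
#'
#' @param space A `ts_space`.
#' @param rep A `ts_representation`.
#' @param trait A `ts_trait`.
#' @param mode `"centroid"` (default) or `"mean_pairwise"`.
#' @param weight_freq If `TRUE`, representation words enter the centroid
#'   weighted by their within-document frequency (default `FALSE`,
#'   unweighted).
#' @return A number in `[-1, 1]`.
#' @export
score_text <- function(space, rep, trait,
                       mode = c("centroid", "mean_pairwise"),
                       weight_freq = FALSE) {
  mode <- match.arg(mode)
  words <- representation_words(rep)
  ri <- match(words$word, space$vocabulary)
  keep <- !is.na(ri)
  if (!any(keep))
    undefined_score_error(paste0("document '", rep$doc_id,
                                 "': no representation word in vocabulary"))
  si <- match(trait$seed_words, space$vocabulary)
  si <- si[!is.na(si)]
  if (length(si) == 0L)
    undefined_score_error(paste0("trait '", trait$name,
                                 "': all seed words out of vocabulary"))
  R <- space$vectors[ri[keep], , drop = FALSE]
  S <- space$vectors[si, , drop = FALSE]
  if (mode == "centroid") {
    wts <- if (weight_freq) words$freq[keep] else rep(1, sum(keep))
    cosine(colSums(R * wts) / sum(wts), colMeans(S))
  } else {
    sims <- outer(seq_len(nrow(R)), seq_len(nrow(S)),
                  Vectorize(function(i, j) cosine(R[i, ], S[j, ])))
    mean(sims)
  }
}

#' Score a corpus against a trait lexicon
#'
#' Produces one row per document and one column per trait, in lexicon
#' order. A cell whose score is undefined (empty usable representation, or
#' every seed word out of vocabulary) is `NA`; the batch always completes.
#' An `oov` matrix of the same shape counts, per cell, the trait seed
#' words missing from the space.
#'
#' @param space A `ts_space`.
#' @param reps A list of `ts_representation` (see [represent_corpus()]).
#' @param lexicon A `ts_lexicon` (default [builtin_lexicon()]).
#' @param labels Optional named character vector doc_id -> label, attached
#'   to the result.
#' @inheritParams score_text
#' @return An object of class `ts_scores`: list with `scores` (numeric
#'   matrix, docs x traits), `labels`, `oov` (integer matrix) and `mode`.
#' @export
score_corpus <- function(space, reps, lexicon = builtin_lexicon(),
                         labels = NULL, mode = c("centroid", "mean_pairwise"),
                         weight_freq = FALSE) {
  mode <- match.arg(mode)
  ids <- vapply(reps, function(r) r$doc_id, character(1))
  scores <- matrix(NA_real_, nrow = length(reps), ncol = length(lexicon),
                   dimnames = list(ids, names(lexicon)))
  oov <- matrix(0L, nrow = length(reps), ncol = length(lexicon),
                dimnames = dimnames(scores))
  seed_oov <- vapply(lexicon, function(tr)
    sum(is.na(match(tr$seed_words, space$vocabulary))), integer(1))
  for (i in seq_along(reps)) {
    for (j in seq_along(lexicon)) {
      oov[i, j] <- seed_oov[j]
      scores[i, j] <- tryCatch(
        score_text(space, reps[[i]], lexicon[[j]], mode = mode,
                   weight_freq = weight_freq),
        ts_undefined_score = function(e) NA_real_)
    }
  }
  labs <- if (is.null(labels)) rep(NA_character_, length(ids))
          else unname(labels[ids])
  structure(list(scores = scores, labels = stats::setNames(labs, ids),
                 oov = oov, mode = mode),
            class = "ts_scores")
}

#' @export
print.ts_scores <- function(x, ...) {
  cat("<ts_scores> ", nrow(x$scores), " documents x ", ncol(x$scores),
      " traits (mode ", x$mode, ", ", sum(is.na(x$scores)),
      " undefined cells)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ts_scores <- function(x, ...) {
  data.frame(doc_id = rownames(x$scores),
             label = unname(x$labels),
             as.data.frame(x$scores),
             stringsAsFactors = FALSE, row.names = NULL,
             check.names = FALSE)
}

#' Read a scores CSV back into a `ts_scores` object
#'
#' @param path A CSV written by [write_scores()].
#' @return A `ts_scores` (with an all-zero `oov` matrix: the report is not
#'   serialized in the CSV).
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(doc_id = "character",
                                       label = "character"))
  m <- as.matrix(df[, setdiff(names(df), c("doc_id", "label")), drop = FALSE])
  rownames(m) <- df$doc_id
  structure(list(scores = m,
                 labels = stats::setNames(df$label, df$doc_id),
                 oov = matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m)),
                 mode = "unknown"),
            class = "ts_scores")
}
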