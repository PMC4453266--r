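#' Dictionary-based part-of-speech tagger
#'
#' The package does not bundle a statistical tagger; any function mapping a
#' token table to a token table that fills the `pos` column with one of
#' `NOUN`, `VERB`, `ADJ`, `OTHER` (leaving length and order untouched) can
#' be plugged in. `dictionary_tagger()` builds the deterministic reference
#' implementation of that contract: a lookup in a word-to-POS dictionary,
#' with unknown words tagged `OTHER`. The synthetic-data generator emits
#' such a dictionary for its vocabulary, so tests and simulations are fully
#' reproducible.
#'
#' @param dictionary Named character vector mapping normalized word to one
#'   of `"NOUN"`, `"VERB"`, `"ADJ"`, `"OTHER"`.
#' @return A tagger function `function(tokens) tokens`.
#' @examples
#' tagger <- dictionary_tagger(c(sad = "ADJ"))
#' tag_tokens(tokenize("sad story"), tagger)$pos  # "ADJ" "OTHER"
#' @export
dictionary_tagger <- function(dictionary) {
  stopifnot(is.character(dictionary), !is.null(names(dictionary)))
  bad <- setdiff(unique(dictionary), c("NOUN", "VERB", "ADJ", "OTHER"))
  if (length(bad) > 0L)
    stop("invalid POS categories in dictionary: ", paste(bad, collapse = ", "))
  force(dictionary)
  function(tokens) {
    pos <- unname(dictionary[tokens$normalized])
    tokens$pos <- ifelse(is.na(pos), "OTHER", pos)
    tokens
  }
}

#' Apply a tagger to a token table
#'
#' Runs `tagger` and enforces its contract: same number of tokens, same
#' order (surface forms and positions unchanged), `pos` filled with a valid
#' category.
#'
#' @param tokens A token data frame from [tokenize()].
#' @param tagger A tagger function (see [dictionary_tagger()]).
#' @return The tagged token data frame.
#' @export
tag_tokens <- function(tokens, tagger) {
  out <- tagger(tokens)
  if (!is.data.frame(out) || nrow(out) != nrow(tokens))
    stop("tagger violated its contract: output length ", nrow(out),
         " != input length ", nrow(tokens))
  if (!identical(out$surface, tokens$surface) ||
      !identical(out$position, tokens$position))
    stop("tagger violated its contract: token order or surfaces changed")
  if (!all(out$pos %in% c("NOUN", "VERB", "ADJ", "OTHER")))
    stop("tagger produced invalid POS categories")
  out
}

#' POS-filtered frequency representation of a document
#'
#' Reduces a tagged document to the `k` most frequent nouns, `k` most
#' frequent verbs and `k` most frequent adjectives (by normalized form),
#' 30 words in total at the default `k = 10` for a document rich enough in
#' all three categories. Ties at the frequency boundary are broken
#' alphabetically; categories with fewer than `k` distinct words keep all
#' of them. Other POS categories are discarded. A word occurring under two
#' categories is counted independently in each.
#'
#' @param tokens A tagged token data frame (see [tag_tokens()]).
#' @param doc_id Document identifier carried into the result.
#' @param k Words kept per category (default 10).
#' @return An object of class `ts_representation`: a list with `doc_id` and
#'   data frames `nouns`, `verbs`, `adjectives` (columns `word`, `freq`,
#'   non-increasing in `freq`).
#' @export
extract_representation <- function(tokens, doc_id = "", k = 10L) {
  stopifnot(k >= 1L)
  top_k <- function(category) {
    words <- tokens$normalized[tokens$pos == category]
    if (length(words) == 0L)
      return(data.frame(word = character(0), freq = integer(0)))
    tab <- table(words)
    df <- data.frame(word = names(tab), freq = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$freq, df$word, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, k)
  }
  structure(list(doc_id = doc_id,
                 nouns = top_k("NOUN"),
                 verbs = top_k("VERB"),
                 adjectives = top_k("ADJ")),
            class = "ts_representation")
}

#' @export
print.ts_representation <- function(x, ...) {
  cat("<ts_representation> ", x$doc_id, ": ",
      nrow(x$nouns), " nouns, ", nrow(x$verbs), " verbs, ",
      nrow(x$adjectives), " adjectives\n", sep = "")
  invisible(x)
}

#' Words and frequencies of a representation, flattened
#'
#' @param rep A `ts_representation`.
#' @return A data frame with columns `word`, `freq` over all three
#'   categories (a word present in two categories appears twice).
#' @export
representation_words <- function(rep) {
  out <- rbind(rep$nouns, rep$verbs, rep$adjectives)
  rownames(out) <- NULL
  out
}

#' Represent every document of a corpus
#'
#' Convenience wrapper: tokenize, tag and extract the representation of
#' each document.
#'
#' @param corpus A `ts_corpus`.
#' @param tagger A tagger function (see [dictionary_tagger()]).
#' @param k Words kept per POS category.
#' @return A named list of `ts_representation`, in corpus order.
#' @export
represent_corpus <- function(corpus, tagger, k = 10L) {
  reps <- lapply(corpus$documents, function(d) {
    extract_representation(tag_tokens(tokenize(d$raw_text), tagger),
                           doc_id = d$doc_id, k = k)
  })
  names(reps) <- corpus_ids(corpus)
  reps
}

#' Write representations to JSON
#'
#' @param reps A list of `ts_representation` (see [represent_corpus()]).
#' @param out_path Output JSON path.
#' @return `out_path`, invisibly.
#' @export
write_representations <- function(reps, out_path) {
  payload <- lapply(reps, function(r)
    list(doc_id = r$doc_id, nouns = r$nouns, verbs = r$verbs,
         adjectives = r$adjectives))
  jsonlite::write_json(payload, out_path, auto_unbox = TRUE, digits = NA)
  invisible(out_path)
}
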