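#' Document and corpus containers
#'
#' A `ts_document` is one unit of text with an identity, an optional group
#' label and free-form metadata. A `ts_corpus` is an ordered list of
#' documents with unique ids.
#'
#' @param doc_id Unique document identifier (string).
#' @param raw_text Document text (UTF-8 string, non-empty after trimming).
#' @param label Optional group label, `"positive"` or `"comparison"`.
#' @param meta Named character vector or list of extra metadata.
#' @return `ts_document()` returns an object of class `ts_document`;
#'   `ts_corpus()` an object of class `ts_corpus` wrapping a list of
#'   documents.
#' @export
ts_document <- function(doc_id, raw_text, label = NA_character_, meta = list()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.character(raw_text) || length(raw_text) != 1L)
    stop("raw_text must be a single string")
  if (!nzchar(trimws(raw_text)))
    stop("document '", doc_id, "' is empty after whitespace stripping")
  if (!is.na(label) && !label %in% c("positive", "comparison"))
    stop("label must be 'positive', 'comparison' or NA")
  structure(list(doc_id = doc_id, raw_text = raw_text,
                 label = label, meta = meta),
            class = "ts_document")
}

#' @param documents List of `ts_document` objects.
#' @rdname ts_document
#' @export
ts_corpus <- function(documents) {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", ids[duplicated(ids)][1L])
  structure(list(documents = documents, n_docs = length(documents)),
            class = "ts_corpus")
}

#' @export
print.ts_corpus <- function(x, ...) {
  labs <- corpus_labels(x)
  cat("<ts_corpus> ", x$n_docs, " documents",
      if (any(!is.na(labs)))
        sprintf(" (%d positive / %d comparison)",
                sum(labs == "positive", na.rm = TRUE),
                sum(labs == "comparison", na.rm = TRUE)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.ts_corpus <- function(x) x$n_docs

#' Document ids and labels of a corpus
#'
#' @param corpus A `ts_corpus`.
#' @return A character vector, one element per document (labels may be `NA`).
#' @export
corpus_ids <- function(corpus) {
  vapply(corpus$documents, function(d) d$doc_id, character(1))
}

#' @rdname corpus_ids
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$documents, function(d) d$label, character(1))
}

#' Load a corpus from a directory of plain-text files
#'
#' Reads every `.txt` file in `directory_path` as UTF-8 (decoding errors are
#' fatal: silently corrupted text would corrupt downstream frequencies), one
#' file per document, `doc_id` = file stem. Documents are ordered
#' lexicographically by id (C locale) so runs are reproducible across
#' machines. An optional labels table (CSV with columns `doc_id,label`)
#' attaches group labels; an id in the table with no matching file is an
#' error.
#'
#' @param directory_path Directory containing at least one `.txt` file.
#' @param labels_table Optional path to a `doc_id,label` CSV.
#' @return A `ts_corpus`.
#' @export
load_corpus <- function(directory_path, labels_table = NULL) {
  files <- list.files(directory_path, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no .txt files found in ", directory_path)
  ids <- tools::file_path_sans_ext(basename(files))
  ord <- order(ids, method = "radix")  # C-locale lexicographic
  files <- files[ord]; ids <- ids[ord]

  labels <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(labels_table)) {
    tab <- utils::read.csv(labels_table, colClasses = "character")
    if (!all(c("doc_id", "label") %in% names(tab)))
      stop("labels table must have columns doc_id,label")
    missing <- setdiff(tab$doc_id, ids)
    if (length(missing) > 0L)
      stop("labels table names doc_id(s) not present in directory: ",
           paste(missing, collapse = ", "))
    labels[tab$doc_id] <- tab$label
  }

  docs <- mapply(function(f, id) {
    txt <- read_utf8(f)
    ts_document(id, txt, label = labels[[id]])
  }, files, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  ts_corpus(docs)
}

# Strict UTF-8 read: invalid bytes abort rather than pass through.
read_utf8 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validEnc(txt))
    stop("file is not valid UTF-8: ", path)
  txt
}

#' Tokenize raw text
#'
#' Tokens are maximal runs of letters with optional internal apostrophes;
#' digits, punctuation and whitespace separate. The normalized form is the
#' lowercased surface form; part of speech is initialized to `"OTHER"` until
#' a tagger runs.
#'
#' @param raw_text A string (may be empty).
#' @return A data frame with columns `surface`, `normalized`, `pos`,
#'   `position` (0-based), one row per token.
#' @examples
#' tokenize("I am SAD.")$normalized  # "i" "am" "sad"
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  m <- gregexpr("\\p{L}+(?:['’]\\p{L}+)*", raw_text, perl = TRUE)
  surf <- regmatches(raw_text, m)[[1L]]
  data.frame(surface = surf,
             normalized = tolower(surf),
             pos = rep("OTHER", length(surf)),
             position = seq_along(surf) - 1L,
             stringsAsFactors = FALSE)
}

#' Write a trait score matrix to CSV
#'
#' Writes the matrix produced by [score_corpus()] as a CSV with header
#' `doc_id,label,<trait columns>` in fixed lexicon order, rows sorted by
#' `doc_id`, floats rendered with full precision so re-writing the same
#' table is byte-identical. Undefined cells are written as `NA`.
#'
#' @param table A `ts_scores` object (see [score_corpus()]).
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_scores <- function(table, out_path) {
  stopifnot(inherits(table, "ts_scores"))
  df <- as.data.frame(table)
  if (nrow(df) == 0L) stop("score table is empty")
  df <- df[order(df$doc_id, method = "radix"), , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 9, format = "g"))
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(out_path)
}

#' Write a corpus to a directory of text files (plus optional labels CSV)
#'
#' Inverse of [load_corpus()]: one `<doc_id>.txt` per document; labels, if
#' any are present, go to `labels.csv` in the same directory.
#'
#' @param corpus A `ts_corpus`.
#' @param directory_path Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, directory_path) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (d in corpus$documents)
    writeLines(d$raw_text, file.path(directory_path, paste0(d$doc_id, ".txt")),
               useBytes = TRUE)
  labs <- corpus_labels(corpus)
  if (any(!is.na(labs))) {
    utils::write.csv(
      data.frame(doc_id = corpus_ids(corpus)[!is.na(labs)],
                 label = labs[!is.na(labs)]),
      file.path(directory_path, "labels.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(directory_path)
}

# Timestamped log line on stderr; used by the pipeline stages.
ts_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
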