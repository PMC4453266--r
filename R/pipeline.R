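#' Configuration for a full pipeline run
#'
#' Bundles paths and stage parameters for [run_pipeline()]: where the
#' background and labeled corpora live, how the space is built, how
#' documents are tagged and scored, and which ranking models run. A single
#' master seed is propagated to every stochastic stage as a stage-name
#' derived seed, so stages are independently reproducible.
#'
#' @param background_dir Directory of background `.txt` files.
#' @param labeled_dir Directory of labeled `.txt` files.
#' @param labels_csv CSV `doc_id,label` for the labeled corpus (default
#'   `labels.csv` inside `labeled_dir`).
#' @param out_dir Run output directory.
#' @param space A [space_config()].
#' @param tagger A tagger function (see [dictionary_tagger()]); if `NULL`,
#'   `pos_dictionary_json` must point to a word-to-POS JSON map from which
#'   a dictionary tagger is built.
#' @param pos_dictionary_json Optional path to a JSON object mapping word
#'   to POS category.
#' @param lexicon Trait lexicon (default [builtin_lexicon()]).
#' @param mode Scoring mode, `"centroid"` or `"mean_pairwise"`.
#' @param k Words kept per POS category in the representation.
#' @param models Ranking models (subset of BLR, TRE, KNN, MEAN).
#' @param rank_mode `"insample"` or `"cv"`.
#' @param n_permutations Monte-Carlo permutations for the group tests.
#' @param seed Master seed.
#' @return An object of class `ts_run_config`.
#' @export
run_config <- function(background_dir, labeled_dir,
                       labels_csv = file.path(labeled_dir, "labels.csv"),
                       out_dir, space = space_config(), tagger = NULL,
                       pos_dictionary_json = NULL,
                       lexicon = builtin_lexicon(),
                       mode = c("centroid", "mean_pairwise"), k = 10L,
                       models = c("BLR", "TRE", "KNN", "MEAN"),
                       rank_mode = c("insample", "cv"),
                       n_permutations = 10000L, seed = 13L) {
  mode <- match.arg(mode)
  rank_mode <- match.arg(rank_mode)
  if (is.null(tagger)) {
    if (is.null(pos_dictionary_json))
      stop("supply either a tagger function or pos_dictionary_json")
    dict <- unlist(jsonlite::read_json(pos_dictionary_json))
    tagger <- dictionary_tagger(dict)
  }
  for (p in c(background_dir, labeled_dir, labels_csv))
    if (!file.exists(p)) stop("path does not exist: ", p)
  structure(list(background_dir = background_dir, labeled_dir = labeled_dir,
                 labels_csv = labels_csv, out_dir = out_dir, space = space,
                 tagger = tagger, lexicon = lexicon, mode = mode,
                 k = as.integer(k), models = models, rank_mode = rank_mode,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "ts_run_config")
}

run_stage <- function(name, expr) {
  ts_log("stage ", name, " ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full profiling pipeline
#'
#' Orchestrates build-space, represent, score, compare and rank as one
#' logged run. The output directory receives: the serialized space
#' (`space.vocab.txt`, `space.vectors.txt`, `space.json`),
#' `representations.json`, `scores.csv` (plus `oov_report.json`),
#' `mwu.csv`, `ranking.csv`, `manifest.json` (machine-readable config and
#' seed echo) and `summary.txt` (human-readable; every number in it is
#' recomputable from the sibling artifacts). Rerunning with the same
#' configuration reproduces all non-timestamp content; if the space files
#' already exist in `out_dir`, the space stage loads them instead of
#' rebuilding, so deleting downstream artifacts and re-running resumes
#' cheaply.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the screening report is
#'   attached as attribute `"screening"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ts_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  prefix <- file.path(out, "space")
  space <- run_stage("build-space", {
    have <- file.exists(paste0(prefix, c(".vocab.txt", ".vectors.txt",
                                         ".json")))
    if (all(have)) {
      ts_log("space artifacts present; reusing")
      read_space(prefix)
    } else {
      bg <- load_corpus(config$background_dir)
      sp <- build_space(bg, config$space)
      write_space(sp, prefix)
      sp
    }
  })

  labeled <- run_stage("load-labeled",
    load_corpus(config$labeled_dir, config$labels_csv))
  labels <- stats::setNames(corpus_labels(labeled), corpus_ids(labeled))

  reps <- run_stage("represent", {
    r <- represent_corpus(labeled, config$tagger, k = config$k)
    write_representations(r, file.path(out, "representations.json"))
    r
  })

  scores <- run_stage("score", {
    s <- score_corpus(space, reps, lexicon = config$lexicon,
                      labels = labels, mode = config$mode)
    write_scores(s, file.path(out, "scores.csv"))
    jsonlite::write_json(list(mode = s$mode,
                              seed_oov_per_trait = as.list(s$oov[1, ])),
                         file.path(out, "oov_report.json"),
                         auto_unbox = TRUE)
    s
  })

  mwu <- run_stage("compare", {
    tab <- compare_groups(scores, n_permutations = config$n_permutations,
                          seed = derive_seed(config$seed, "compare"))
    utils::write.csv(tab, file.path(out, "mwu.csv"), row.names = FALSE,
                     quote = FALSE)
    tab
  })

  rankings <- run_stage("rank", {
    rk <- rank_documents(scores, models = config$models,
                         mode = config$rank_mode,
                         seed = derive_seed(config$seed, "rank"))
    rows <- do.call(rbind, lapply(rk, function(r) {
      ids <- sort(names(r$ranks), method = "radix")
      data.frame(model = r$model_name, doc_id = ids,
                 probability = if (is.null(r$probabilities)) NA_real_
                               else unname(r$probabilities[ids]),
                 rank = unname(r$ranks[ids]),
                 label = unname(labels[ids]))
    }))
    utils::write.csv(rows, file.path(out, "ranking.csv"), row.names = FALSE,
                     quote = FALSE)
    rk
  })

  n_docs <- labeled$n_docs
  n_pos <- sum(labels == "positive", na.rm = TRUE)
  screening <- screening_report(rankings, n_docs, n_pos)

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("traitscreen")),
         seed = config$seed,
         derived_seeds = list(compare = derive_seed(config$seed, "compare"),
                              rank = derive_seed(config$seed, "rank")),
         space = list(window = config$space$window,
                      weighting = config$space$weighting,
                      svd_dim = config$space$svd_dim,
                      min_count = config$space$min_count),
         mode = config$mode, k = config$k, models = config$models,
         rank_mode = config$rank_mode,
         n_permutations = config$n_permutations,
         n_docs = n_docs, n_positive = n_pos,
         artifacts = c("space.vocab.txt", "space.vectors.txt", "space.json",
                       "representations.json", "scores.csv",
                       "oov_report.json", "mwu.csv", "ranking.csv")),
    file.path(out, "manifest.json"), auto_unbox = TRUE, null = "null")

  sig <- mwu[!is.na(mwu$p_mc) & mwu$p_mc < 0.05, , drop = FALSE]
  summary_lines <- c(
    paste0("run completed at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("documents scored: %d (%d positive, %d comparison)",
            n_docs, n_pos, n_docs - n_pos),
    sprintf("traits with Monte-Carlo p < 0.05: %s",
            if (nrow(sig) > 0) paste(sig$trait, collapse = ", ") else "none"),
    "screening (steps to recover all positives, fraction of collection):",
    sprintf("  %-4s steps=%d (%.2f%%, random baseline %.1f)",
            screening$model, screening$steps, screening$fraction_pct,
            screening$random_baseline_steps))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  ts_log("run complete: ", out)

  structure(invisible(out), screening = screening)
}
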