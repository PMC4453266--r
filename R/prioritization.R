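#' Classifier specification for the ranking procedure
#'
#' Three model families rank documents by predicted probability of the
#' positive class: binary logistic regression (`"logistic"`, BLR), a
#' classification tree with cost-complexity pruning selected by
#' cross-validation (`"tree"`, TRE; a CART-style stand-in for chi-square
#' multiway trees, whose algorithm has no maintained open implementation),
#' and k-nearest-neighbors (`"knn"`, KNN) on standardized features.
#'
#' @param kind `"logistic"`, `"tree"` or `"knn"`.
#' @param cv_folds Cross-validation folds for tree pruning and for
#'   out-of-fold prediction (default 10).
#' @param k_neighbors Neighbors for KNN (default 5).
#' @param class_weighting `"none"` (default) or `"balanced"` (logistic
#'   only: weights inversely proportional to class frequency).
#' @param seed Integer seed driving fold assignment and tree
#'   cross-validation.
#' @return An object of class `ts_model_spec`.
#' @export
model_spec <- function(kind = c("logistic", "tree", "knn"), cv_folds = 10L,
                       k_neighbors = 5L, class_weighting = c("none", "balanced"),
                       seed = 1L) {
  kind <- match.arg(kind)
  class_weighting <- match.arg(class_weighting)
  stopifnot(cv_folds >= 2L, k_neighbors >= 1L)
  structure(list(kind = kind, cv_folds = as.integer(cv_folds),
                 k_neighbors = as.integer(k_neighbors),
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "ts_model_spec")
}

# Impute undefined cells with the per-trait comparison-group median
# (falling back to the overall column median, then 0 for an all-NA column).
impute_scores <- function(m, labs) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (!any(nas)) next
    fill <- stats::median(m[labs == "comparison", j], na.rm = TRUE)
    if (is.na(fill)) fill <- stats::median(m[, j], na.rm = TRUE)
    if (is.na(fill)) fill <- 0
    m[nas, j] <- fill
  }
  m
}

fit_logistic <- function(xtr, ytr, xte, weighting) {
  df <- data.frame(.y = ytr, xtr, check.names = TRUE)
  w <- if (weighting == "balanced") {
    n <- length(ytr)
    ifelse(ytr == 1, n / (2 * sum(ytr == 1)), n / (2 * sum(ytr == 0)))
  } else rep(1, length(ytr))
  fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                     data = df, weights = w))
  nd <- data.frame(xte, check.names = TRUE)
  unname(suppressWarnings(stats::predict(fit, newdata = nd,
                                         type = "response")))
}

fit_tree <- function(xtr, ytr, xte, cv_folds, seed) {
  df <- data.frame(.y = factor(ytr, levels = c(0, 1)), xtr,
                   check.names = TRUE)
  # Small minbucket so rare-class leaves are reachable under heavy
  # imbalance; the CV-selected complexity penalty guards against overgrowth.
  fit <- with_seed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = 4L, minbucket = 2L,
                                   cp = 1e-4, xval = cv_folds)))
  cptab <- fit$cptable
  if (!is.null(cptab) && "xerror" %in% colnames(cptab)) {
    best <- cptab[which.min(cptab[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best)
  }
  nd <- data.frame(xte, check.names = TRUE)
  p <- stats::predict(fit, newdata = nd, type = "prob")
  unname(p[, "1"])
}

fit_knn <- function(xtr, ytr, xte, k, self_excluded) {
  # Neighbor class fraction over the k nearest training points by
  # Euclidean distance on standardized features; when scoring the training
  # set itself, each point's own row is excluded from its neighborhood.
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  zte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  d2 <- outer(rowSums(zte^2), rep(1, nrow(ztr))) +
    outer(rep(1, nrow(zte)), rowSums(ztr^2)) - 2 * zte %*% t(ztr)
  vapply(seq_len(nrow(zte)), function(i) {
    di <- d2[i, ]
    if (self_excluded) di[i] <- Inf
    nn <- order(di, method = "radix")[seq_len(min(k, sum(is.finite(di))))]
    mean(ytr[nn])
  }, numeric(1))
}

# Class-stratified fold assignment, deterministic given seed.
assign_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  })
  folds
}

#' Predicted positive-class probabilities for every document
#'
#' Fits the requested classifier on the trait score matrix (independent
#' variables) against the positive/comparison labels, and returns the
#' predicted probability of the positive class per document. The default
#' `"insample"` mode fits on all documents and scores those same documents
#' — the classic screening setup, which rank-orders the very collection it
#' was fit on and therefore flatters the ranking; `"cv"` produces honest
#' out-of-fold probabilities instead and is recommended for any
#' generalization claim. Undefined score cells are imputed with the
#' per-trait comparison-group median before fitting. Deterministic given
#' `spec$seed`.
#'
#' @param scores A `ts_scores` with labels, or a numeric matrix.
#' @param labels Optional doc_id -> label vector overriding stored labels.
#' @param spec A [model_spec()].
#' @param mode `"insample"` (default) or `"cv"`.
#' @return A named numeric vector of probabilities in `[0, 1]`, one per
#'   document.
#' @export
fit_and_score <- function(scores, labels = NULL, spec = model_spec(),
                          mode = c("insample", "cv")) {
  mode <- match.arg(mode)
  m <- if (inherits(scores, "ts_scores")) scores$scores else scores
  labs <- if (!is.null(labels)) unname(labels[rownames(m)])
          else unname(scores$labels)
  if (length(unique(stats::na.omit(labs))) < 2L)
    stop("both classes must be present in the labels")
  y <- as.integer(labs == "positive")
  x <- impute_scores(m, labs)

  predict_with <- function(xtr, ytr, xte, self_excluded) {
    switch(spec$kind,
           logistic = fit_logistic(xtr, ytr, xte, spec$class_weighting),
           tree = fit_tree(xtr, ytr, xte, spec$cv_folds, spec$seed),
           knn = fit_knn(xtr, ytr, xte, spec$k_neighbors, self_excluded))
  }

  if (mode == "insample") {
    p <- predict_with(x, y, x, self_excluded = TRUE)
  } else {
    folds <- assign_folds(y, spec$cv_folds, spec$seed)
    p <- numeric(length(y))
    for (f in seq_len(spec$cv_folds)) {
      te <- folds == f
      if (!any(te)) next
      p[te] <- predict_with(x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE], self_excluded = FALSE)
    }
  }
  stats::setNames(pmin(1, pmax(0, p)), rownames(m))
}

#' Rank documents by descending probability
#'
#' Rank 1 is the most suspicious document (highest probability); ties are
#' broken by ascending `doc_id` so ranked outputs are reproducible
#' run-to-run. The result is always a permutation of `1..N`.
#'
#' @param probabilities Named numeric vector (names = doc ids).
#' @return A named integer vector of ranks.
#' @export
rank_descending <- function(probabilities) {
  stopifnot(!is.null(names(probabilities)))
  ord <- order(-probabilities, names(probabilities), method = "radix")
  ranks <- integer(length(probabilities))
  ranks[ord] <- seq_along(probabilities)
  stats::setNames(ranks, names(probabilities))
}

#' Steps needed to recover every positive document from a ranked list
#'
#' Reading documents from rank 1 downward, this is the list length at
#' which the last positive document is reached: the maximum rank among
#' positive-labeled documents.
#'
#' @param ranks Named integer rank vector (see [rank_descending()]).
#' @param labels doc_id -> label vector (or a vector aligned with `ranks`).
#' @return An integer.
#' @export
steps_to_identify_all <- function(ranks, labels) {
  labs <- if (!is.null(names(labels))) unname(labels[names(ranks)])
          else labels
  pos <- which(labs == "positive")
  if (length(pos) == 0L) stop("no positive documents among the ranks")
  max(ranks[pos])
}

#' Combine rankings by mean of ranks
#'
#' Averages each document's ranks over the input rankings, then re-ranks
#' ascending (smallest mean rank first), ties broken by `doc_id`.
#'
#' @param rank_lists List of >= 1 named rank vectors covering the same
#'   document set.
#' @return A named integer vector of combined ranks.
#' @export
mean_rank_ensemble <- function(rank_lists) {
  stopifnot(length(rank_lists) >= 1L)
  ids <- sort(names(rank_lists[[1L]]), method = "radix")
  for (rl in rank_lists)
    if (!identical(sort(names(rl), method = "radix"), ids))
      stop("rank lists cover different document sets")
  means <- rowMeans(vapply(rank_lists, function(rl) rl[ids],
                           numeric(length(ids))))
  ord <- order(means, ids, method = "radix")
  ranks <- integer(length(ids))
  ranks[ord] <- seq_along(ids)
  stats::setNames(ranks, ids)
}

#' Expected steps under a random ranking
#'
#' With `m` positives uniformly placed among `N` documents, the expected
#' maximum positive rank is `m (N + 1) / (m + 1)` (the largest of `m`
#' discrete uniform order statistics) — the baseline any useful screening
#' procedure must beat.
#'
#' @param m Number of positive documents.
#' @param n_docs Total number of documents.
#' @return Expected steps (numeric).
#' @export
random_baseline_steps <- function(m, n_docs) {
  m * (n_docs + 1) / (m + 1)
}

#' Run the full ranking procedure
#'
#' Fits the requested models, ranks documents per model, optionally adds
#' the mean-of-ranks ensemble, and attaches the screening metrics.
#'
#' @param scores A `ts_scores` with labels, or numeric matrix.
#' @param labels Optional doc_id -> label override.
#' @param models Character subset of `c("BLR", "TRE", "KNN", "MEAN")`.
#'   `"MEAN"` combines whichever other models are requested.
#' @param mode `"insample"` or `"cv"` (see [fit_and_score()]).
#' @param seed Integer master seed; each model uses a derived seed.
#' @param k_neighbors,cv_folds Passed to [model_spec()].
#' @return A list of class `ts_ranking_set`: one element per model, each a
#'   `ts_ranking` with fields `model_name`, `probabilities` (`NULL` for
#'   MEAN), `ranks`, `steps_to_identify_all`, `screening_fraction_pct`.
#' @export
rank_documents <- function(scores, labels = NULL,
                           models = c("BLR", "TRE", "KNN", "MEAN"),
                           mode = c("insample", "cv"), seed = 1L,
                           k_neighbors = 5L, cv_folds = 10L) {
  mode <- match.arg(mode)
  models <- match.arg(models, several.ok = TRUE)
  m <- if (inherits(scores, "ts_scores")) scores$scores else scores
  labs <- if (!is.null(labels)) labels
          else scores$labels
  kinds <- c(BLR = "logistic", TRE = "tree", KNN = "knn")
  base_models <- intersect(models, names(kinds))
  if ("MEAN" %in% models && length(base_models) == 0L)
    stop("MEAN requires at least one base model")

  n <- nrow(m)
  out <- list()
  for (mod in base_models) {
    spec <- model_spec(kinds[[mod]], cv_folds = cv_folds,
                       k_neighbors = k_neighbors,
                       seed = derive_seed(seed, mod))
    p <- fit_and_score(scores, labels = labs, spec = spec, mode = mode)
    r <- rank_descending(p)
    steps <- steps_to_identify_all(r, labs)
    out[[mod]] <- structure(list(model_name = mod, probabilities = p,
                                 ranks = r, steps_to_identify_all = steps,
                                 screening_fraction_pct = 100 * steps / n),
                            class = "ts_ranking")
  }
  if ("MEAN" %in% models) {
    r <- mean_rank_ensemble(lapply(out, function(o) o$ranks))
    steps <- steps_to_identify_all(r, labs)
    out[["MEAN"]] <- structure(list(model_name = "MEAN", probabilities = NULL,
                                    ranks = r, steps_to_identify_all = steps,
                                    screening_fraction_pct = 100 * steps / n),
                               class = "ts_ranking")
  }
  structure(out, class = "ts_ranking_set")
}

#' Screening summary across models
#'
#' One row per ranking: steps to recover all positives, the corresponding
#' fraction of the collection (exact and rounded to the nearest whole
#' percent), and the closed-form random-ranking baseline.
#'
#' @param results A `ts_ranking_set` (or list of `ts_ranking`).
#' @param n_docs Total number of documents ranked.
#' @param n_positives Number of positive documents (for the baseline).
#' @return A data frame with columns `model`, `steps`, `fraction_pct`,
#'   `fraction_rounded_pct`, `random_baseline_steps`.
#' @export
screening_report <- function(results, n_docs, n_positives) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    steps <- r$steps_to_identify_all
    data.frame(model = r$model_name, steps = steps,
               fraction_pct = 100 * steps / n_docs,
               fraction_rounded_pct = round(100 * steps / n_docs),
               random_baseline_steps = random_baseline_steps(n_positives,
                                                             n_docs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
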