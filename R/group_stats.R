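# Evaluate expr with a temporarily fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific 31-bit seed from a master seed and a stage name,
# so pipeline stages are independently reproducible.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483647)
}

mwu_u <- function(x, y) {
  # U of group x: number of (xi, yj) pairs with xi > yj, ties counting 0.5.
  # Midrank identity: U = R1 - n1 (n1 + 1) / 2.
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U with a Monte-Carlo permutation p-value
#'
#' The statistic is the pair count `U = sum over (xi, yj) of [xi > yj]`,
#' ties contributing 0.5, for group `x` ("greater" means `x` tends larger).
#' The p-value is estimated by randomly re-assigning the pooled values to
#' the two groups (permutation without replacement, the exact null of
#' exchangeability) `n_permutations` times and applying the add-one
#' estimator `p = (b + 1) / (m + 1)` for `b` exceedances among `m`
#' permutations, so the estimate is never exactly zero. The two-sided
#' p-value doubles the smaller tail, capped at 1.
#'
#' @param x,y Numeric score vectors for the two groups (non-empty).
#' @param n_permutations Number of Monte-Carlo permutations (default 10000).
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return An object of class `ts_mwu`: list with `U`, `p_mc`, `n1`, `n2`,
#'   `n_permutations`, `seed`, `alternative`.
#' @examples
#' mann_whitney_mc(c(1, 3), c(2, 4), n_permutations = 100, seed = 1)$U  # 1
#' @export
mann_whitney_mc <- function(x, y, n_permutations = 10000L,
                            alternative = c("two_sided", "greater", "less"),
                            seed = 1L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  stopifnot(n_permutations >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- mwu_u(x, y)

  pooled <- c(x, y)
  r <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  u_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
    sum(r[sample.int(n, n1)]) - offset, numeric(1)))

  eps <- 1e-9  # tolerate float fuzz in tie-midrank sums
  p_greater <- (sum(u_perm >= u_obs - eps) + 1) / (n_permutations + 1)
  p_less <- (sum(u_perm <= u_obs + eps) + 1) / (n_permutations + 1)
  p_mc <- switch(alternative,
                 greater = p_greater,
                 less = p_less,
                 two_sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(U = u_obs, p_mc = p_mc, n1 = n1, n2 = n2,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alternative = alternative),
            class = "ts_mwu")
}

#' @export
print.ts_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), Monte-Carlo p = %g (%s, %d permutations)\n",
              x$U, x$n1, x$n2, x$p_mc, x$alternative, x$n_permutations))
  invisible(x)
}

#' Per-trait group comparison of a score matrix
#'
#' Runs [mann_whitney_mc()] for every trait column, positive class as
#' group 1, comparison class as group 2. Undefined score cells are excluded
#' per trait; a trait whose exclusions empty a group yields an `NA` row and
#' the batch continues. No multiple-testing correction is applied by
#' default; `adjust = "BH"` adds a Benjamini-Hochberg adjusted column.
#'
#' @param scores A `ts_scores` with labels, or a plain numeric matrix.
#' @param labels Optional doc_id -> label vector overriding the labels
#'   stored in `scores`.
#' @param n_permutations,alternative,seed Passed to [mann_whitney_mc()];
#'   each trait uses a seed derived from `seed` and its column index.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame with columns `trait`, `U`, `p_mc`, `n1`, `n2` (and
#'   `p_adj` when `adjust = "BH"`), one row per trait in lexicon order.
#' @export
compare_groups <- function(scores, labels = NULL, n_permutations = 10000L,
                           alternative = c("two_sided", "greater", "less"),
                           seed = 1L, adjust = c("none", "BH")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  m <- if (inherits(scores, "ts_scores")) scores$scores else scores
  labs <- if (!is.null(labels)) unname(labels[rownames(m)])
          else unname(scores$labels)
  if (!all(c("positive", "comparison") %in% labs))
    stop("both 'positive' and 'comparison' labels must be present")

  res <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    x <- v[labs == "positive" & !is.na(v)]
    y <- v[labs == "comparison" & !is.na(v)]
    if (length(x) == 0L || length(y) == 0L)
      return(data.frame(trait = colnames(m)[j], U = NA_real_,
                        p_mc = NA_real_, n1 = length(x), n2 = length(y)))
    r <- mann_whitney_mc(x, y, n_permutations = n_permutations,
                         alternative = alternative,
                         seed = derive_seed(seed, colnames(m)[j]))
    data.frame(trait = colnames(m)[j], U = r$U, p_mc = r$p_mc,
               n1 = r$n1, n2 = r$n2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_mc, method = "BH")
  out
}
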