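#' One-way ANOVA F-statistic
#'
#' The ratio of between-group to within-group variance:
#' `F = [sum_g n_g (mean_g - mean)^2 / (G - 1)] /
#'      [sum_g sum_h (x_gh - mean_g)^2 / (n - G)]`.
#' Large values mean the group means differ by more than the
#' within-group scatter explains; the classical one-way ANOVA F.
#'
#' @param groups List of `G >= 2` nonempty numeric vectors, total
#'   `n > G`.
#' @return The F value (>= 0). Zero within-group variance with nonzero
#'   between-group variance yields `Inf` (perfectly separated constant
#'   groups); zero over zero yields `NaN`.
#' @export
#' @examples
#' f_statistic(list(c(1, 2, 3), c(4, 5, 6)))   # 13.5
f_statistic <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 numeric vectors")
  }
  ng <- vapply(groups, length, integer(1))
  if (any(ng == 0)) stop("every group must be nonempty")
  G <- length(groups)
  n <- sum(ng)
  if (n <= G) stop("total sample size must exceed the number of groups")
  means <- vapply(groups, mean, 0)
  grand <- sum(ng * means) / n
  ssb <- sum(ng * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  num <- ssb / (G - 1)
  den <- ssw / (n - G)
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}

#' Rank the 24 features by two-group F-statistic
#'
#' Computes `[f_statistic()]` per feature with the LVH and non-LVH rows
#' as the two groups and sorts descending. Ties (and the sort itself)
#' are stable in canonical feature order. The F value is invariant under
#' per-feature affine rescaling, so ranking needs no prior
#' normalisation.
#'
#' @param x Feature matrix or data frame (numeric columns).
#' @param y Logical labels; both classes must be present.
#' @return Data frame of class `feature_ranking` with columns `feature`
#'   and `F`, sorted by decreasing `F`.
#' @export
rank_features <- function(x, y) {
  x <- as.data.frame(x)
  stopifnot(is.logical(y), length(y) == nrow(x))
  if (length(unique(y)) < 2) stop("both classes must be present")
  fv <- vapply(x, function(col) f_statistic(list(col[y], col[!y])), 0)
  ord <- order(-fv)  # stable: ties keep canonical column order
  out <- data.frame(feature = names(fv)[ord], F = unname(fv[ord]))
  structure(out, class = c("feature_ranking", "data.frame"))
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("F-statistic feature ranking (descending):\n")
  print.data.frame(transform(as.data.frame(x), F = signif(F, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Sequential feature-elimination accuracy curve
#'
#' Ranks features once on the training rows, then for `k = p` down to 1
#' retrains the classifier on the top-`k` features and records held-out
#' accuracy on a fixed test split — the same split for every `k`, so the
#' curve is comparable across `k`. The ranking is fixed at the start
#' (features are excluded sequentially from the bottom); set
#' `rerank = TRUE` to re-rank after each elimination instead.
#'
#' @param x Feature matrix or data frame.
#' @param y Logical labels.
#' @param method Classifier passed to `[lvh_model()]`.
#' @param plan A `[split_plan()]`; its seed fixes both the split and
#'   every refit.
#' @param group Optional grouping for the split (see
#'   `[train_test_split()]`).
#' @param rerank Re-rank on the surviving features at each step.
#' @param ... Extra arguments for `[lvh_model()]`.
#' @return Data frame of class `elimination_curve`: `k`, `accuracy`,
#'   `dropped` (the feature removed *after* that point was measured).
#' @export
elimination_curve <- function(x, y, method = "tree", plan = split_plan(),
                              group = NULL, rerank = FALSE, ...) {
  x <- as.data.frame(x)
  stopifnot(is.logical(y), length(y) == nrow(x))
  sp <- train_test_split(nrow(x), plan, group = group)
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  xte <- x[sp$test, , drop = FALSE]; yte <- y[sp$test]
  active <- rank_features(xtr, ytr)$feature  # best first
  rows <- list()
  for (k in rev(seq_along(active))) {
    if (rerank && length(active) > k) {
      active <- rank_features(xtr[, active[seq_len(k + 1)], drop = FALSE],
                              ytr)$feature
    }
    keep <- active[seq_len(k)]
    fit <- tryCatch(
      lvh_model(xtr[, keep, drop = FALSE], ytr, method = method,
                seed = plan$seed, ...),
      error = function(e) stop("model fit failed at k = ", k, ": ",
                               conditionMessage(e)))
    acc <- evaluate_model(fit, xte[, keep, drop = FALSE], yte)$accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, accuracy = acc, dropped = active[k])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("elimination_curve", "data.frame"))
}

#' @export
plot.elimination_curve <- function(x, ...) {
  plot(x$k, x$accuracy, type = "b", xlab = "number of features",
       ylab = "held-out accuracy", ...)
  invisible(x)
}
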