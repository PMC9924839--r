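#' Binary node entropy in bits
#'
#' The impurity used by the entropy decision tree:
#' `-p log2(p) - q log2(q)` with `q = 1 - p` and the convention
#' `0 * log2(0) = 0`. A pure node (`p` = 0 or 1) scores 0 (ideal split);
#' a half-and-half node scores 1 (least informative). Symmetric in
#' `p <-> q`, range `[0, 1]`.
#'
#' @param p Fraction of positive cases in the node, in `[0, 1]`.
#'   Vectorised.
#' @return Entropy in bits.
#' @export
#' @examples
#' node_entropy(c(0, 0.5, 1))   # 0 1 0
#' node_entropy(0.25)           # 0.8112781
node_entropy <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]")
  }
  q <- 1 - p
  plog <- ifelse(p == 0, 0, p * log2(p))
  qlog <- ifelse(q == 0, 0, q * log2(q))
  -plog - qlog + 0  # + 0 normalises IEEE -0 at the endpoints
}

#' Confusion-matrix report for a binary LVH classifier
#'
#' LVH is the positive class. Metrics follow the usual identities:
#' accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`. A ratio with a zero
#' denominator is reported as `NA`, never as 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return List of class `model_report` with the counts and four metrics.
#' @export
#' @examples
#' model_report(tp = 29, fn = 1, tn = 28, fp = 2)
model_report <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  ), class = "model_report")
}

# report from predicted/actual logical vectors
model_report_from <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  model_report(tp = sum(predicted & actual),
               fp = sum(predicted & !actual),
               tn = sum(!predicted & !actual),
               fn = sum(!predicted & actual))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy=%s precision=%s sensitivity=%s specificity=%s\n",
              format(x$accuracy, digits = 4), format(x$precision, digits = 4),
              format(x$sensitivity, digits = 4),
              format(x$specificity, digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.model_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
             accuracy = x$accuracy, precision = x$precision,
             sensitivity = x$sensitivity, specificity = x$specificity)
}

#' Train/test split plan
#'
#' The evaluation protocol: 7:3 case ratio of training to testing data,
#' tenfold cross-validation during training. When `group` is supplied
#' (e.g. subject ids for beat-level rows), the split is grouped so that
#' no subject spans train and test — beat rows of one subject are highly
#' correlated and ungrouped splitting would leak identity information
#' into the test set. An ungrouped split is what you get with
#' `group = NULL`.
#'
#' @param train_fraction Fraction of cases (or groups) used for
#'   training (default 0.7).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return List of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.7, cv_folds = 10, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Split rows into train and test sets
#'
#' @param n Number of rows.
#' @param plan A `[split_plan()]`.
#' @param group Optional grouping vector of length `n` (subject ids);
#'   whole groups are assigned to one side.
#' @return List with integer row indices `train` and `test`.
#' @export
train_test_split <- function(n, plan = split_plan(), group = NULL) {
  with_local_seed(plan$seed, {
    if (is.null(group)) {
      tr <- sort(sample.int(n, round(plan$train_fraction * n)))
    } else {
      stopifnot(length(group) == n)
      g <- unique(group)
      gtr <- sample(g, round(plan$train_fraction * length(g)))
      tr <- which(group %in% gtr)
    }
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' Balance a cohort by down-sampling the majority class
#'
#' Keeps every minority-class case and a seeded uniform random sample of
#' equal size from the majority class (the protocol that pairs each LVH
#' case with one control).
#'
#' @param labels Logical vector (`TRUE` = LVH).
#' @param seed Integer seed.
#' @return Sorted integer indices of the balanced subset.
#' @export
balanced_cohort <- function(labels, seed = 1L) {
  stopifnot(is.logical(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  minority <- if (n_pos <= n_neg) labels else !labels
  keep_min <- which(minority)
  pool <- which(!minority)
  with_local_seed(seed, {
    keep_maj <- sample(pool, length(keep_min))
    sort(c(keep_min, keep_maj))
  })
}

# seeded fold assignment, stratified by label
cv_fold_ids <- function(y, k, seed) {
  with_local_seed(seed, {
    folds <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
}

#' Fit an LVH classifier
#'
#' One front-end for the three classifiers of the detection protocol,
#' all consuming the 24-feature voltage table:
#' \describe{
#'   \item{`"tree"`}{Entropy decision tree. For every depth in
#'     `depth_range` (default 1-25) the mean tenfold cross-validated
#'     accuracy is computed on the training data; the depth with the
#'     highest mean accuracy wins (smallest depth on ties) and the final
#'     tree is refit on all training rows at that depth. Splitting is by
#'     information gain (`[node_entropy()]` impurity) via \pkg{rpart}.}
#'   \item{`"kmeans"`}{k-means++ seeding followed by Lloyd iterations
#'     (`stats::kmeans`), `k = 2` for the binary task; each cluster is
#'     mapped to its majority training label and prediction is by
#'     nearest centroid.}
#'   \item{`"bpn"`}{Back-propagation network: 24 inputs, one hidden
#'     layer of 26 logistic units, one sigmoid output, binary
#'     cross-entropy loss, mini-batch gradient descent, 400 epochs.
#'     Features are z-scored with statistics fitted on the training rows
#'     (stored in the model and re-applied at prediction). Optionally
#'     reports tenfold CV accuracy during training.}
#' }
#'
#' @param x Feature matrix or data frame (rows = cases, 24 columns for
#'   the canonical table; any numeric columns are accepted).
#' @param y Logical labels (`TRUE` = LVH) of length `nrow(x)`.
#' @param method `"tree"`, `"kmeans"`, or `"bpn"`.
#' @param seed Integer seed governing every stochastic step; (data,
#'   seed) determines the fit bit-exactly.
#' @param depth_range Candidate tree depths (tree only).
#' @param cv_folds Cross-validation folds for depth selection / CV
#'   accuracy (default 10; set `0` to skip CV for kmeans/bpn).
#' @param k Number of clusters (kmeans only, default 2).
#' @param hidden,epochs,learning_rate,batch_size BPN hyperparameters
#'   (defaults 26, 400, 0.01, 32).
#' @return An object of class `c("lvh_<method>", "lvh_model")` with at
#'   least `method`, `feature_names`, `seed`, and method-specific fields
#'   (`depth`, `cv_accuracy`; `centers`, `cluster_labels`; `weights`,
#'   `zscore`).
#' @seealso [predict.lvh_model()], [evaluate_model()]
#' @export
#' @examples
#' tab <- synth_feature_table(40, effect_size = 3, seed = 1)
#' fit <- lvh_model(tab$x, tab$y, method = "tree", seed = 1)
#' fit
lvh_model <- function(x, y, method = c("tree", "kmeans", "bpn"), seed = 1L,
                      depth_range = 1:25, cv_folds = 10, k = 2,
                      hidden = 26, epochs = 400, learning_rate = 0.01,
                      batch_size = 32) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(is.logical(y), length(y) == nrow(x), !anyNA(x), !anyNA(y))
  fit <- switch(method,
    tree = fit_tree(x, y, depth_range, cv_folds, seed),
    kmeans = fit_kmeans_classifier(x, y, k, seed),
    bpn = fit_bpn(x, y, hidden, epochs, learning_rate, batch_size,
                  cv_folds, seed))
  fit$method <- method
  fit$feature_names <- colnames(x)
  fit$seed <- as.integer(seed)
  fit$n_train <- nrow(x)
  class(fit) <- c(paste0("lvh_", method), "lvh_model")
  fit
}

fit_tree <- function(x, y, depth_range, cv_folds, seed) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (min(table(y)) < cv_folds) {
    stop("need at least ", cv_folds, " rows per class for ", cv_folds,
         "-fold cross-validation")
  }
  df <- data.frame(.y = factor(y, levels = c(FALSE, TRUE)), x,
                   check.names = FALSE)
  folds <- cv_fold_ids(y, cv_folds, seed)
  ctrl <- function(d) rpart::rpart.control(maxdepth = d, cp = 0,
                                           minsplit = 2, minbucket = 1,
                                           xval = 0)
  cv_acc <- vapply(depth_range, function(d) {
    acc <- vapply(seq_len(cv_folds), function(k) {
      tr <- df[folds != k, , drop = FALSE]
      te <- df[folds == k, , drop = FALSE]
      m <- rpart::rpart(.y ~ ., data = tr, method = "class",
                        parms = list(split = "information"),
                        control = ctrl(d))
      mean(predict(m, te, type = "class") == te$.y)
    }, 0)
    mean(acc)
  }, 0)
  best <- depth_range[which.max(cv_acc)]  # which.max: smallest on ties
  final <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = "information"),
                        control = ctrl(best))
  list(rpart = final, depth = best,
       cv_accuracy = setNames(cv_acc, depth_range))
}

# k-means++ seeding: first centre uniform, each next centre drawn with
# probability proportional to squared distance from the nearest chosen
# centre (run under the caller's local seed)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

fit_kmeans_classifier <- function(x, y, k, seed) {
  if (k > nrow(x)) stop("k exceeds the number of training rows")
  with_local_seed(seed, {
    init <- kmeanspp_init(x, k)
    km <- if (k == 1) {
      list(centers = matrix(colMeans(x), 1), cluster = rep(1L, nrow(x)))
    } else {
      kmeans(x, centers = init, iter.max = 100, algorithm = "Lloyd")
    }
    # each cluster votes its majority training label
    lab <- vapply(seq_len(k), function(j) {
      members <- y[km$cluster == j]
      if (length(members) == 0) return(NA)
      mean(members) >= 0.5
    }, NA)
    lab[is.na(lab)] <- mean(y) >= 0.5  # empty cluster: global majority
    list(centers = km$centers, cluster_labels = lab, k = k)
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bpn_forward <- function(w, x) {
  h <- sigmoid(sweep(x %*% w$W1, 2, w$b1, "+"))
  o <- sigmoid(as.vector(h %*% w$W2 + w$b2))
  list(h = h, o = o)
}

bpn_train <- function(x, y, hidden, epochs, lr, batch_size) {
  p <- ncol(x); n <- nrow(x)
  glorot <- function(nin, nout) {
    matrix(runif(nin * nout, -sqrt(6 / (nin + nout)), sqrt(6 / (nin + nout))),
           nin, nout)
  }
  w <- list(W1 = glorot(p, hidden), b1 = numeric(hidden),
            W2 = glorot(hidden, 1), b2 = 0)
  yt <- as.numeric(y)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      fw <- bpn_forward(w, xb)
      # BCE + sigmoid output: delta = o - y
      delta_o <- fw$o - yt[idx]
      grad_W2 <- crossprod(fw$h, delta_o) / length(idx)
      grad_b2 <- mean(delta_o)
      delta_h <- (delta_o %*% t(w$W2)) * fw$h * (1 - fw$h)
      grad_W1 <- crossprod(xb, delta_h) / length(idx)
      grad_b1 <- colMeans(delta_h)
      w$W1 <- w$W1 - lr * grad_W1
      w$b1 <- w$b1 - lr * grad_b1
      w$W2 <- w$W2 - lr * grad_W2
      w$b2 <- w$b2 - lr * grad_b2
      if (any(!is.finite(w$W1)) || any(!is.finite(w$W2))) {
        stop("NaN/Inf in BPN weights at epoch ", ep,
             "; try a smaller learning rate")
      }
    }
  }
  w
}

fit_bpn <- function(x, y, hidden, epochs, lr, batch_size, cv_folds, seed) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (cv_folds > 0 && min(table(y)) < cv_folds) {
    stop("need at least ", cv_folds, " rows per class for ", cv_folds,
         "-fold cross-validation (set cv_folds = 0 to skip)")
  }
  zs <- zscore_fit(x)
  xz <- zscore_apply(x, zs)
  cv_accuracy <- NA_real_
  if (cv_folds > 0) {
    folds <- cv_fold_ids(y, cv_folds, seed)
    acc <- vapply(seq_len(cv_folds), function(k) {
      zk <- zscore_fit(x[folds != k, , drop = FALSE])
      with_local_seed(seed + k, {
        wk <- bpn_train(zscore_apply(x[folds != k, , drop = FALSE], zk),
                        y[folds != k], hidden, epochs, lr, batch_size)
      })
      pred <- bpn_forward(wk, zscore_apply(x[folds == k, , drop = FALSE],
                                           zk))$o > 0.5
      mean(pred == y[folds == k])
    }, 0)
    cv_accuracy <- mean(acc)
  }
  w <- with_local_seed(seed, bpn_train(xz, y, hidden, epochs, lr, batch_size))
  list(weights = w, zscore = zs, hidden = hidden, epochs = epochs,
       learning_rate = lr, batch_size = batch_size,
       cv_accuracy = cv_accuracy)
}

#' Predict LVH calls from a fitted classifier
#'
#' @param object An `[lvh_model()]` fit.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param type `"class"` (logical calls) or `"prob"` (BPN only: output
#'   unit activation; tree: positive-class probability; kmeans: 0/1).
#' @param ... Unused.
#' @return Logical vector (or numeric for `type = "prob"`).
#' @export
predict.lvh_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  prob <- switch(object$method,
    tree = {
      df <- data.frame(x, check.names = FALSE)
      unname(predict(object$rpart, df, type = "prob")[, "TRUE"])
    },
    kmeans = {
      d <- vapply(seq_len(nrow(object$centers)), function(j) {
        rowSums(sweep(x, 2, object$centers[j, ])^2)
      }, numeric(nrow(x)))
      d <- matrix(d, nrow = nrow(x))
      as.numeric(object$cluster_labels[max.col(-d, ties.method = "first")])
    },
    bpn = bpn_forward(object$weights, zscore_apply(x, object$zscore))$o)
  if (type == "prob") prob else prob > 0.5
}

#' Evaluate a fitted classifier on labelled test data
#'
#' @param model An `[lvh_model()]` fit.
#' @param x Test feature matrix (nonempty).
#' @param y Logical test labels.
#' @return A `[model_report()]`.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(nrow(as.data.frame(x)) > 0, is.logical(y), !anyNA(y))
  model_report_from(predict(model, x), y)
}

#' @export
print.lvh_model <- function(x, ...) {
  cat(sprintf("LVH classifier (%s), %d features, %d training rows, seed %d\n",
              x$method, length(x$feature_names), x$n_train, x$seed))
  if (x$method == "tree") {
    cat(sprintf("  selected depth %d (mean 10-fold CV accuracy %.3f)\n",
                x$depth, max(x$cv_accuracy)))
  }
  if (x$method == "kmeans") {
    cat(sprintf("  k = %d clusters, labels: %s\n", x$k,
                paste(x$cluster_labels, collapse = " ")))
  }
  if (x$method == "bpn") {
    cat(sprintf("  architecture %d-%d-1, %d epochs, lr %g, batch %d%s\n",
                length(x$feature_names), x$hidden, x$epochs,
                x$learning_rate, x$batch_size,
                if (is.finite(x$cv_accuracy))
                  sprintf(", CV accuracy %.3f", x$cv_accuracy) else ""))
  }
  invisible(x)
}

#' @export
summary.lvh_model <- function(object, ...) {
  print(object)
  if (object$method == "tree") {
    cat("\nCV accuracy by depth:\n")
    print(round(object$cv_accuracy, 4))
  }
  invisible(object)
}
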