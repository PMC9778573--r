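#' Built-in classifier backends
#'
#' Each backend is a list with a `fit(x, y)` and a `predict(model, x)`
#' function (`x` a samples-by-features numeric matrix, `y` a factor), the
#' contract [evaluate_panel()] expects, so heavier learners can be plugged
#' in the same way. Shipped backends: `"knn"` (k-nearest neighbour, k = 5),
#' `"tree"` (recursive-partitioning decision tree) and, when the
#' randomForest package is installed, `"forest"`.
#'
#' @param names character vector choosing among `"knn"`, `"tree"`,
#'   `"forest"`.
#' @return named list of backends.
#' @export
builtin_classifiers <- function(names = c("knn", "tree")) {
  all <- list(
    knn = list(
      fit = function(x, y) list(x = x, y = y),
      predict = function(model, x)
        class::knn(model$x, x, model$y, k = min(5L, nrow(model$x)))
    ),
    tree = list(
      fit = function(x, y) {
        d <- data.frame(.y = y, x, check.names = TRUE)
        rpart::rpart(.y ~ ., data = d, method = "class")
      },
      predict = function(model, x) {
        d <- data.frame(x, check.names = TRUE)
        stats::predict(model, newdata = d, type = "class")
      }
    )
  )
  if ("forest" %in% names) {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop_invalid("the 'forest' backend needs the randomForest package")
    all$forest <- list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 200),
      predict = function(model, x) stats::predict(model, x)
    )
  }
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0)
    stop_invalid("unknown classifier backend(s): %s",
                 paste(unknown, collapse = ", "))
  all[names]
}

#' Accuracy, recall and F1 from predicted vs true labels
#'
#' Hand-countable definitions on the 2x2 confusion table:
#' `accuracy = (TP + TN) / N`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`, `F1` their harmonic mean (0 when the
#' denominator vanishes).
#'
#' @param truth,pred vectors of class labels.
#' @param positive the positive class label.
#' @return named numeric vector `accuracy`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  acc <- mean(truth == pred)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = acc, recall = recall, f1 = f1)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every fold contains both classes. Pure function of
# (labels, n_folds, seed).
stratified_folds <- function(labels, n_folds, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated classification performance of a gene panel
#'
#' Restricts the expression matrix to the panel genes and measures, by
#' seeded stratified k-fold cross-validation, how well each classifier
#' backend separates the two label classes. Folding, training/test
#' splitting and the metrics are native; the learners are pluggable.
#'
#' @param expr an [expression_dataset()] or a samples-by-genes setup via
#'   `matrix` + `labels` (see Details). Matrix rows are genes.
#' @param labels binary labels per sample (defaults to
#'   `expr$sample_labels`); e.g. case/control or alive/dead.
#' @param panel character vector of panel genes (default: all genes).
#' @param classifiers named list of backends (see [builtin_classifiers()]).
#' @param n_folds number of folds (default 5); reduced with a warning when
#'   the smaller class has fewer members.
#' @param seed integer seed for the fold assignment.
#' @param positive positive class for recall/F1; defaults to `"case"` or
#'   `"dead"` when present, else the first factor level.
#' @return data.frame, one row per classifier: `classifier`, `accuracy`,
#'   `f1`, `recall`, `n_folds` (mean over folds), with the per-fold scores
#'   in `attr(, "fold_scores")`.
#' @export
evaluate_panel <- function(expr, labels = NULL, panel = NULL,
                           classifiers = builtin_classifiers(),
                           n_folds = 5, seed = 1L, positive = NULL) {
  stopifnot(inherits(expr, "ExpressionDataset"))
  if (is.null(labels)) labels <- expr$sample_labels
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) stop_invalid("need exactly 2 label classes")
  if (is.null(panel)) panel <- expr$gene_ids
  panel <- intersect(panel, expr$gene_ids)
  if (length(panel) == 0) stop_invalid("no panel gene is measured")
  x <- t(expr$matrix[panel, , drop = FALSE])
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    n_folds, min_class))
    n_folds <- min_class
  }
  if (n_folds < 2) stop_invalid("need at least 2 usable folds")
  if (is.null(positive)) {
    positive <- intersect(c("case", "dead"), levels(labels))
    positive <- if (length(positive) > 0) positive[1] else levels(labels)[1]
  }
  fold <- stratified_folds(labels, n_folds, seed)
  rows <- lapply(names(classifiers), function(nm) {
    be <- classifiers[[nm]]
    scores <- t(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      model <- be$fit(x[tr, , drop = FALSE], droplevels(labels[tr]))
      pred <- be$predict(model, x[!tr, , drop = FALSE])
      classification_metrics(labels[!tr], pred, positive)
    }, c(accuracy = 0.0, recall = 0.0, f1 = 0.0)))
    agg <- colMeans(scores)
    out <- data.frame(classifier = nm, accuracy = agg[["accuracy"]],
                      f1 = agg[["f1"]], recall = agg[["recall"]],
                      n_folds = n_folds, stringsAsFactors = FALSE)
    attr(out, "fold_scores") <- scores
    out
  })
  fold_scores <- lapply(rows, attr, "fold_scores")
  names(fold_scores) <- names(classifiers)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_scores") <- fold_scores
  out
}
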