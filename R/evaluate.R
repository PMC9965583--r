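#' Confusion counts with severe as the positive class
#'
#' @param truth Factor/vector of true labels; the positive class is the last
#'   factor level (conventionally `"severe"`).
#' @param predicted Predicted labels on the same scale.
#' @return List of class `confusion_counts`: TP, FP, FN, TN.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  t_pos <- to_binary(truth) == 1L
  p_pos <- if (is.factor(predicted) || is.character(predicted)) {
    as.character(predicted) == positive_label(truth)
  } else {
    to_binary(predicted) == 1L
  }
  structure(list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
                 FN = sum(t_pos & !p_pos), TN = sum(!t_pos & !p_pos)),
            class = "confusion_counts")
}

positive_label <- function(truth) {
  if (is.factor(truth)) levels(truth)[nlevels(truth)] else "severe"
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / All; Precision = TP / (TP + FP);
#' Recall = TP / (TP + FN); F-score = 2 * Precision * Recall /
#' (Precision + Recall). An undefined ratio (zero denominator) is reported
#' as 0 with a warning.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/FN/TN).
#' @return Named numeric vector: accuracy, precision, recall, f_score.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion counts")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f <- safe(2 * precision * recall, precision + recall, "F-score")
  c(accuracy = (tp + tn) / total, precision = precision,
    recall = recall, f_score = f)
}

#' Balanced train/test split
#'
#' Randomly draws `n_per_class` records of each class for training; the
#' remainder of the dataset is the test set. This balanced-sampling protocol
#' neutralizes class imbalance during training while testing on the natural
#' class mix.
#'
#' @param data An `ade_data` object (or data frame with the target column).
#' @param n_per_class Records per class in the training set.
#' @param seed Integer seed for reproducible sampling (optional).
#' @param target Target column name when `data` is a plain data frame.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all rows).
#' @export
balanced_split <- function(data, n_per_class, seed = NULL, target = "severity") {
  if (inherits(data, "ade_data")) target <- attr(data, "target")
  y <- data[[target]]
  if (!is.null(seed)) set.seed(seed)
  idx_by_class <- split(seq_along(y), y)
  small <- vapply(idx_by_class, length, integer(1)) < n_per_class
  if (any(small)) {
    stop("class(es) with fewer than n_per_class records: ",
         paste(names(idx_by_class)[small], collapse = ", "))
  }
  exhausted <- vapply(idx_by_class, length, integer(1)) == n_per_class
  if (any(exhausted)) {
    warning("class(es) fully used for training; test set contains no ",
            paste(names(idx_by_class)[exhausted], collapse = ", "), " records")
  }
  train <- sort(unlist(lapply(idx_by_class, sample, size = n_per_class),
                       use.names = FALSE))
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Repeated balanced-split cross-validation
#'
#' The evaluation protocol: each fold draws a fresh balanced training sample
#' (`n_per_class` per class, fold f seeded with `seed + f`) and tests every
#' method on the identical held-out remainder, so methods are compared on
#' the same splits. A standard stratified k-fold mode (`mode = "kfold"`,
#' train = k-1 folds) is also available.
#'
#' @param data An `ade_data` object.
#' @param methods Character vector of weighting methods
#'   (subset of `"none"`, `"chi2"`, `"ig"`, `"kl"`).
#' @param folds Number of folds/repetitions (>= 2 in kfold mode).
#' @param n_per_class Balanced training-sample size per class
#'   (repeated mode).
#' @param seed Base integer seed.
#' @param mode `"repeated"` (default) or `"kfold"`.
#' @param ... Passed to [awlr_fit()].
#' @return Object of class `awlr_cv`: data frame with columns fold, method,
#'   accuracy, precision, recall, f_score; per-fold fitted weights attached
#'   as attribute `"fold_weights"`.
#' @export
cross_validate <- function(data, methods = c("none", "chi2"), folds = 10,
                           n_per_class = NULL, seed = 1,
                           mode = c("repeated", "kfold"), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "ade_data"))
  y <- data[[attr(data, "target")]]
  if (mode == "repeated" && is.null(n_per_class)) {
    n_per_class <- floor(min(table(y)) * 0.7)
  }
  if (mode == "kfold") {
    if (folds < 2) stop("kfold mode needs folds >= 2")
    set.seed(seed)
    fold_id <- integer(length(y))
    for (idx in split(seq_along(y), y)) {
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  rows <- list()
  fold_weights <- list()
  for (f in seq_len(folds)) {
    if (mode == "repeated") {
      sp <- balanced_split(data, n_per_class, seed = seed + f)
    } else {
      sp <- list(train = which(fold_id != f), test = which(fold_id == f))
    }
    train <- subset_ade(data, sp$train)
    test <- as.data.frame(data)[sp$test, , drop = FALSE]
    truth <- test[[attr(data, "target")]]
    for (m in methods) {
      model <- awlr_fit(train, weight_method = m, ...)
      pred <- predict(model, test, type = "class")
      met <- classification_metrics(confusion_counts(truth, pred))
      rows[[length(rows) + 1L]] <- data.frame(fold = f, method = m,
                                              t(met), stringsAsFactors = FALSE)
      if (m != "none") {
        fold_weights[[paste(m, f, sep = ".")]] <- model$weights
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fold_weights = fold_weights,
            class = c("awlr_cv", "data.frame"))
}

#' Per-method summary of a cross-validation report
#'
#' @param object An `awlr_cv` report.
#' @param ... Unused.
#' @return Data frame of median and quartiles per method and metric.
#' @export
summary.awlr_cv <- function(object, ...) {
  metrics <- c("accuracy", "precision", "recall", "f_score")
  out <- do.call(rbind, lapply(split(as.data.frame(object), object$method),
    function(d) {
      do.call(rbind, lapply(metrics, function(m) {
        q <- stats::quantile(d[[m]], c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(method = d$method[1], metric = m,
                   q1 = q[1], median = q[2], q3 = q[3],
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Comparative boxplots of cross-validation metrics
#'
#' One boxplot panel per metric, methods side by side.
#'
#' @param x An `awlr_cv` report.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.awlr_cv <- function(x, ...) {
  metrics <- c("accuracy", "precision", "recall", "f_score")
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  for (m in metrics) {
    graphics::boxplot(stats::as.formula(paste(m, "~ method")),
                      data = as.data.frame(x), main = m, xlab = "",
                      ylab = m, ...)
  }
  invisible(x)
}
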