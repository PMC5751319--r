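#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` Euclidean-nearest training samples.  Distance
#' ties are broken by training-set order (the earlier sample ranks first);
#' a tied vote goes to the class of the best-ranked neighbour among the
#' tied classes — in particular, when the single nearest neighbour's class
#' is among the tied ones, it wins.
#'
#' @param train_x numeric matrix of training samples (one per row).
#' @param train_y factor of training labels.
#' @param query numeric vector (one query) or matrix (one per row).
#' @param k neighbour count, `1 <= k <= nrow(train_x)`.
#' @return factor of predicted labels with the training levels.
#' @export
knn_predict <- function(train_x, train_y, query, k) {
  train_x <- as.matrix(train_x)
  train_y <- as.factor(train_y)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  n <- nrow(train_x)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("k must be between 1 and the number of training samples (", n,
         "); got ", k, call. = FALSE)
  }
  if (ncol(query) != ncol(train_x)) {
    stop("query dimension ", ncol(query), " does not match training ",
         "dimension ", ncol(train_x), call. = FALSE)
  }
  bump_counter("knn_calls")
  d2 <- outer(rowSums(query^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(query, train_x)
  preds <- character(nrow(query))
  for (q in seq_len(nrow(query))) {
    ord <- order(d2[q, ])           # stable: distance ties keep train order
    top <- train_y[ord[seq_len(k)]]
    votes <- table(top)
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) {
      preds[q] <- winners
    } else {
      # earliest-ranked neighbour belonging to a tied class decides
      preds[q] <- as.character(top[match(TRUE, as.character(top) %in% winners)])
    }
  }
  factor(preds, levels = levels(train_y))
}

#' Jackknife (leave-one-out) evaluation of the KDA + KNN pipeline
#'
#' Every sample is held out in turn and predicted from the remaining
#' `N - 1`.  In `strict` mode the KDA model is refitted on each fold's
#' training set (statistically clean, `N` fits); in `fast` mode a single
#' KDA model fitted on all samples provides the projection and only the KNN
#' step is leave-one-out (one fit, the cost profile of a screening run).
#'
#' @param data a [labeled_dataset()].
#' @param s Gaussian scale.
#' @param d retained discriminant dimension.
#' @param k KNN neighbour count (default 20).
#' @param mode `"strict"` (default) or `"fast"`.
#' @param reg ridge passed to [fit_kda()].
#' @return a list of class `jackknife_result`: `counts` (a
#'   `confusion_counts` frame from [confusion_counts()]), `predictions`
#'   (factor of length `N`), `truth`, `mode`, `k`.
#' @export
jackknife <- function(data, s, d, k = 20, mode = c("strict", "fast"),
                      reg = 1e-8) {
  stopifnot(inherits(data, "labeled_dataset"))
  mode <- match.arg(mode)
  n <- nrow(data$x)
  preds <- character(n)
  if (mode == "fast") {
    model <- fit_kda(data, s, d, reg = reg)
    proj <- kda_project(model, data$x)
    for (i in seq_len(n)) {
      preds[i] <- as.character(
        knn_predict(proj[-i, , drop = FALSE], data$labels[-i],
                    proj[i, ], k)
      )
    }
  } else {
    for (i in seq_len(n)) {
      lab_rest <- data$labels[-i]
      lost <- setdiff(levels(data$labels), unique(as.character(lab_rest)))
      if (length(lost)) {
        stop("holding out sample ", i, " removes class '", lost[1],
             "' entirely; jackknife needs every class at least twice",
             call. = FALSE)
      }
      fold <- labeled_dataset(data$x[-i, , drop = FALSE], lab_rest)
      model <- fit_kda(fold, s, d, reg = reg)
      proj_train <- kda_project(model, fold$x)
      proj_test <- kda_project(model, data$x[i, ])
      preds[i] <- as.character(
        knn_predict(proj_train, fold$labels, proj_test, k)
      )
    }
  }
  preds <- factor(preds, levels = levels(data$labels))
  structure(
    list(counts = confusion_counts(data$labels, preds),
         predictions = preds, truth = data$labels, mode = mode, k = k),
    class = "jackknife_result"
  )
}

#' One-vs-rest confusion counts
#'
#' For every class `c`: `TP` = samples of `c` predicted `c`, `FN` = samples
#' of `c` predicted otherwise, `FP` = other samples predicted `c`, `TN` =
#' the rest.  Each row sums to `N`.
#'
#' @param truth factor of true labels.
#' @param pred factor of predicted labels (same levels).
#' @return data frame of class `confusion_counts` with columns `class`,
#'   `TP`, `FN`, `FP`, `TN` and attribute `n` (total samples).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ", call. = FALSE)
  }
  n <- length(truth)
  lv <- levels(truth)
  out <- do.call(rbind, lapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl, na.rm = TRUE)
    fn <- sum(truth == cl & pred != cl, na.rm = TRUE)
    fp <- sum(truth != cl & pred == cl, na.rm = TRUE)
    data.frame(class = cl, TP = tp, FN = fn, FP = fp, TN = n - tp - fn - fp)
  }))
  attr(out, "n") <- n
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Per-class evaluation metrics
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, the Matthews
#' correlation coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, and overall
#' accuracy `Q = sum(TP) / N`.  All reported as proportions; MCC lies in
#' `[-1, 1]`.  A zero denominator makes the corresponding value undefined:
#' it is stored as `NA` and rendered as `"-"`, never as a number.
#'
#' A historically common variant writes specificity as `TN / (TP + FP)`;
#' that form can exceed 1 and is not a specificity, but is available via
#' `spe_variant = "printed"` for comparison experiments.
#'
#' @param counts a [confusion_counts()] frame.
#' @param spe_variant `"standard"` (default) or `"printed"`.
#' @return list of class `eval_report`: `per_class` data frame (`class`,
#'   `Sen`, `Spe`, `MCC`), overall `Q`, and `n`.
#' @export
eval_metrics <- function(counts, spe_variant = c("standard", "printed")) {
  stopifnot(inherits(counts, "confusion_counts"))
  spe_variant <- match.arg(spe_variant)
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  tp <- counts$TP; fn <- counts$FN; fp <- counts$FP; tn <- counts$TN
  sen <- safe_div(tp, tp + fn)
  spe <- if (spe_variant == "standard") {
    safe_div(tn, tn + fp)
  } else {
    safe_div(tn, tp + fp)
  }
  denom <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fn * fp, denom)
  n <- attr(counts, "n")
  structure(
    list(
      per_class = data.frame(class = counts$class, Sen = sen, Spe = spe,
                             MCC = mcc),
      Q = sum(tp) / n,
      n = n
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  df <- x$per_class
  show <- function(v) ifelse(is.na(v), "-", format(round(v, digits)))
  out <- data.frame(class = df$class, Sen = show(df$Sen), Spe = show(df$Spe),
                    MCC = show(df$MCC))
  print(out, row.names = FALSE)
  cat("Overall accuracy Q =", format(round(x$Q, digits)), "on", x$n,
      "samples\n")
  invisible(x)
}
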