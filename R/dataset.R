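#' Labeled dataset container
#'
#' Bundles a numeric feature matrix with a class label per row.  This is the
#' common currency of the package: kernel discriminant fitting, scale
#' selection and jackknife evaluation all consume it.
#'
#' @param x numeric matrix (or coercible data frame), one sample per row.
#' @param labels vector of class labels, one per row of `x`; coerced to
#'   factor.  Empty levels are dropped.
#'
#' @return an object of class `labeled_dataset`: a list with elements
#'   `x` (matrix), `labels` (factor) and `class_sizes` (named integer
#'   vector, one entry per class).
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), each = 5))
#' d$class_sizes
labeled_dataset <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nrow(x) != length(labels)) {
    stop("'x' has ", nrow(x), " rows but ", length(labels), " labels", call. = FALSE)
  }
  if (nrow(x) == 0L) stop("dataset is empty", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  if (nlevels(labels) < 2L) {
    stop("a labeled dataset needs at least 2 classes, got ", nlevels(labels),
         call. = FALSE)
  }
  sizes <- table(labels)
  structure(
    list(
      x = x,
      labels = labels,
      class_sizes = stats::setNames(as.integer(sizes), names(sizes))
    ),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$x), "samples,", ncol(x$x), "features,",
      nlevels(x$labels), "classes\n")
  cat("Class sizes:", paste(names(x$class_sizes), x$class_sizes,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a labeled dataset by row index
#'
#' @param data a [labeled_dataset()].
#' @param i integer or logical row index.
#' @return a `labeled_dataset` restricted to the selected rows.  May error
#'   if the subset drops below two classes.
#' @export
subset_dataset <- function(data, i) {
  stopifnot(inherits(data, "labeled_dataset"))
  labeled_dataset(data$x[i, , drop = FALSE], data$labels[i])
}
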