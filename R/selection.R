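#' Mean u-th-nearest-neighbour radius of a class
#'
#' For every member of the class, the Euclidean distance to its `u`-th
#' nearest neighbour in the full collection (self excluded) is found; the
#' neighbourhood radius `epsilon` is the mean of those distances.
#'
#' @param x numeric matrix of all samples (the neighbour pool), or a
#'   [labeled_dataset()].
#' @param members integer indices of the class members within `x`.
#' @param u neighbour rank, `1 <= u <= N - 1`.
#' @return the radius `epsilon >= 0`.
#' @export
neighborhood_radius <- function(x, members, u) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x)
  u <- as.integer(u)
  if (u < 1L || u > n - 1L) {
    stop("u must be between 1 and N - 1 = ", n - 1L, "; got ", u,
         call. = FALSE)
  }
  if (length(members) == 0L) stop("no class members given", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  du <- vapply(members, function(m) {
    sort(D[m, -m], partial = u)[u]
  }, numeric(1))
  mean(du)
}

#' Select edge and internal samples of a class
#'
#' Implements the centroid/neighbourhood split used to stand in for novel
#' and normal samples when no true novelties exist.  For the chosen class
#' (by default the largest, the convention for forming the training class):
#' the class centroid and each member's distance to it are computed, `m` is
#' the median of those distances, and `epsilon` is the mean `u`-th-neighbour
#' radius ([neighborhood_radius()]).  A member is an *edge* sample if its
#' centroid distance exceeds `m` strictly **and** its `epsilon`-ball (taken
#' over the whole dataset) contains samples of other classes; it is an
#' *internal* sample if its centroid distance is strictly below `m` **and**
#' its `epsilon`-ball is pure.  Members meeting neither rule stay
#' unassigned.  Because the rules hinge on the median distance rather than
#' local tangent planes, a class lying entirely on a sphere still yields a
#' non-degenerate split.
#'
#' @param data a [labeled_dataset()].
#' @param class_index class to split; by default the class with the most
#'   samples (ties to the first such class).
#' @param u neighbour rank for the radius; must satisfy `0 < u < N_i`.
#' @return an object of class `sample_split`: `internal` and `edge` (global
#'   row indices into `data$x`), `class_index`, `class_label`, `epsilon`,
#'   `median_dist`, `centroid` and the member distances `dist`.
#' @export
select_edge_internal <- function(data, class_index = NULL, u = 8) {
  stopifnot(inherits(data, "labeled_dataset"))
  sizes <- data$class_sizes
  if (is.null(class_index)) class_index <- which.max(sizes)
  class_index <- as.integer(class_index)
  lv <- levels(data$labels)
  if (class_index < 1L || class_index > length(lv)) {
    stop("class_index out of range", call. = FALSE)
  }
  members <- which(data$labels == lv[class_index])
  Ni <- length(members)
  u <- as.integer(u)
  if (u < 1L || u >= Ni) {
    stop("u must satisfy 0 < u < N_i = ", Ni, "; got ", u, call. = FALSE)
  }

  eps <- neighborhood_radius(data$x, members, u)
  centroid <- colMeans(data$x[members, , drop = FALSE])
  distj <- sqrt(rowSums(sweep(data$x[members, , drop = FALSE], 2L,
                              centroid)^2))
  m <- stats::median(distj)

  D <- as.matrix(stats::dist(data$x))
  other <- data$labels != lv[class_index]
  has_foreign <- vapply(seq_len(Ni), function(j) {
    g <- members[j]
    inside <- D[g, ] <= eps
    inside[g] <- FALSE
    any(inside & other)
  }, logical(1))

  edge <- members[distj > m & has_foreign]
  internal <- members[distj < m & !has_foreign]
  if (length(edge) == 0L || length(internal) == 0L) {
    stop("the edge/internal split is degenerate (",
         length(edge), " edge, ", length(internal), " internal); ",
         "try a different u", call. = FALSE)
  }
  structure(
    list(
      internal = internal, edge = edge,
      class_index = class_index, class_label = lv[class_index],
      epsilon = eps, median_dist = m, centroid = centroid,
      dist = stats::setNames(distj, members), u = u
    ),
    class = "sample_split"
  )
}

#' @export
print.sample_split <- function(x, ...) {
  cat("Edge/internal split of class '", x$class_label, "': ",
      length(x$edge), " edge, ", length(x$internal), " internal (epsilon = ",
      signif(x$epsilon, 4), ", median dist = ", signif(x$median_dist, 4),
      ", u = ", x$u, ")\n", sep = "")
  invisible(x)
}

#' Scale-selection objective
#'
#' The quantity maximized by the reconstruction-error selector:
#' \deqn{f = \frac{\|RE(\Omega_{ed})\|_\infty - \|RE(\Omega_{in})\|_\infty}
#'                {\mathrm{std}\{RE(\Omega_{in})\}}}
#' with the infinity norm the maximum absolute component and the sample
#' standard deviation (`n - 1` denominator).  A good scale drives the edge
#' samples' reconstruction errors up while keeping the internal samples'
#' errors low and tight.  The objective is invariant to scaling both error
#' vectors by a common positive factor.
#'
#' @param re_edge reconstruction errors of the edge samples (nonempty).
#' @param re_internal reconstruction errors of the internal samples (at
#'   least 2 values, for the standard deviation).
#' @return the objective value, or `NA` with a warning when the internal
#'   spread is exactly zero (the objective is then undefined).
#' @export
kda_objective <- function(re_edge, re_internal) {
  if (length(re_edge) == 0L) stop("no edge reconstruction errors", call. = FALSE)
  if (length(re_internal) < 2L) {
    stop("need at least 2 internal reconstruction errors for the standard ",
         "deviation", call. = FALSE)
  }
  num <- max(abs(re_edge)) - max(abs(re_internal))
  s <- stats::sd(re_internal)
  if (s == 0) {
    warning("internal reconstruction errors have zero spread; ",
            "objective undefined", call. = FALSE)
    return(NA_real_)
  }
  num / s
}

#' Select the Gaussian scale by reconstruction-error contrast
#'
#' The proposed selector: the edge/internal split is computed once from the
#' largest class, then for each candidate scale a KDA model is fitted on
#' the full labeled dataset, reconstruction errors of the edge and internal
#' samples are evaluated, and the candidate maximizing [kda_objective()] is
#' returned.  No classifier is run, which is what makes this cheaper than
#' grid search.  Ties (and they are resolved deterministically) go to the
#' smallest scale.
#'
#' @param data a [labeled_dataset()].
#' @param candidates positive candidate scales; defaults to
#'   `c(0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4)`.
#' @param d retained discriminant dimension, `1 <= d <= C - 1`.
#' @param u neighbour rank for the split (default 8).
#' @param split optionally a precomputed [select_edge_internal()] result.
#' @param reg ridge passed to [fit_kda()].
#' @return an object of class `scale_selection`: `best` (the chosen scale),
#'   `candidates`, `objective` (one value per candidate, `NA` when
#'   undefined), a `diagnostics` data frame (per candidate: max edge RE,
#'   max internal RE, internal RE standard deviation, objective), the
#'   `split`, and `method = "reconstruction"`.
#' @export
select_scale <- function(data, candidates = c(0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4),
                         d, u = 8, split = NULL, reg = 1e-8) {
  stopifnot(inherits(data, "labeled_dataset"))
  candidates <- as.numeric(candidates)
  if (length(candidates) == 0L || any(candidates <= 0)) {
    stop("candidates must be a nonempty set of positive scales", call. = FALSE)
  }
  if (is.null(split)) split <- select_edge_internal(data, u = u)

  diag_rows <- lapply(candidates, function(s) {
    model <- fit_kda(data, s, d, reg = reg)
    re_ed <- reconstruction_error(model, data$x[split$edge, , drop = FALSE])
    re_in <- reconstruction_error(model, data$x[split$internal, , drop = FALSE])
    data.frame(
      scale = s,
      max_re_edge = max(abs(re_ed)),
      max_re_internal = max(abs(re_in)),
      sd_re_internal = stats::sd(re_in),
      objective = suppressWarnings(kda_objective(re_ed, re_in))
    )
  })
  diagnostics <- do.call(rbind, diag_rows)
  f <- diagnostics$objective
  if (all(is.na(f))) {
    stop("the objective is undefined for every candidate scale",
         call. = FALSE)
  }
  if (anyNA(f)) {
    warning(sum(is.na(f)), " candidate(s) with undefined objective ",
            "excluded from the argmax", call. = FALSE)
  }
  top <- which(f == max(f, na.rm = TRUE))
  if (length(top) > 1L) {
    message("objective tie among scales ",
            paste(candidates[top], collapse = ", "),
            "; taking the smallest")
  }
  best <- min(candidates[top])
  structure(
    list(best = best, candidates = candidates, objective = f,
         diagnostics = diagnostics, split = split,
         method = "reconstruction"),
    class = "scale_selection"
  )
}

#' Select the Gaussian scale by grid search over classifier accuracy
#'
#' The conventional baseline: for each candidate scale, fit KDA on the full
#' dataset, project all samples, and measure leave-one-out k-nearest-
#' neighbour accuracy in the reduced space; the scale with the highest
#' accuracy wins (ties to the smallest scale).
#'
#' @param data a [labeled_dataset()].
#' @param candidates positive candidate scales.
#' @param d retained discriminant dimension.
#' @param k KNN neighbour count (default 20).
#' @param reg ridge passed to [fit_kda()].
#' @return a `scale_selection` object with `method = "grid"`; its
#'   `diagnostics` frame holds the per-candidate accuracy (`accuracy`
#'   column), and `objective` mirrors that accuracy.
#' @export
grid_search <- function(data, candidates = c(0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4),
                        d, k = 20, reg = 1e-8) {
  stopifnot(inherits(data, "labeled_dataset"))
  candidates <- as.numeric(candidates)
  if (length(candidates) == 0L || any(candidates <= 0)) {
    stop("candidates must be a nonempty set of positive scales", call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)

  acc <- vapply(candidates, function(s) {
    jk <- jackknife(data, s = s, d = d, k = k, mode = "fast", reg = reg)
    eval_metrics(jk$counts)$Q
  }, numeric(1))
  top <- which(acc == max(acc))
  best <- min(candidates[top])
  structure(
    list(best = best, candidates = candidates, objective = acc,
         diagnostics = data.frame(scale = candidates, accuracy = acc),
         split = NULL, method = "grid"),
    class = "scale_selection"
  )
}

#' @export
print.scale_selection <- function(x, ...) {
  cat("Scale selection (", x$method, "): best s = ", x$best, "\n", sep = "")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
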