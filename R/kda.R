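#' Gaussian kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / s^2)`, the radial similarity used
#' throughout the package.  Always in `(0, 1]` with `K(x, x) = 1`.
#'
#' @param x,y numeric vectors of equal length.
#' @param s scale (bandwidth) parameter, strictly positive.
#' @return a similarity in `(0, 1]`.
#' @export
#' @examples
#' gaussian_kernel(c(1, 0), c(0, 0), 1)  # exp(-1)
gaussian_kernel <- function(x, y, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    stop("scale 's' must be a single positive number", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same dimension (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  exp(-sum((x - y)^2) / s^2)
}

#' Gaussian kernel matrix
#'
#' Pairwise [gaussian_kernel()] similarities; symmetric with unit diagonal.
#'
#' @param x numeric matrix, one sample per row (a [labeled_dataset()] is
#'   also accepted).
#' @param s positive scale parameter.
#' @return `N x N` symmetric matrix.
#' @export
kernel_matrix <- function(x, s) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty sample collection", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    stop("scale 's' must be a single positive number", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  exp(-d2 / s^2)
}

# cross-kernel between rows of a (queries) and rows of b (training)
cross_kernel <- function(a, b, s) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("query dimension ", ncol(a), " does not match training dimension ",
         ncol(b), call. = FALSE)
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-d2 / s^2)
}

#' Fit Gaussian kernel discriminant analysis
#'
#' Kernelized Fisher discriminant analysis.  With `K` the Gaussian kernel
#' matrix of the training samples, the class kernel-mean vectors `M_i`
#' (component `k` being the mean of `K(x_k, .)` over class `i`), the grand
#' mean `M`, and the class blocks `K_i = K[, class i]`, the between- and
#' within-class kernel scatter are
#' \deqn{M = \sum_i N_i (M_i - M)(M_i - M)^T, \quad
#'       L = \sum_i K_i (E - (1/N_i) J) K_i^T,}
#' with `E` the identity and `J` the all-ones matrix.  The discriminant
#' coefficients are the top `d` eigenvectors of `(L + mu I)^{-1} M` (a small
#' ridge `mu` because `L` has rank at most `N - C`), solved as a
#' symmetric-definite generalized eigenproblem via Cholesky.  The
#' coefficient columns are then orthonormalized in the kernel metric
#' (`alpha^T K alpha = I`), which is what makes the reconstruction-error
#' identity `RE(x) = K(x,x) - ||t(x)||^2` exact.
#'
#' @param data a [labeled_dataset()] with `C >= 2` classes.
#' @param s positive Gaussian scale.
#' @param d number of retained discriminants, `1 <= d <= C - 1`.
#' @param reg relative ridge: `mu = reg * trace(L) / N` (floored at 1e-12).
#' @return an object of class `kda`: the training data, `scale`, `alpha`
#'   (`N x d` kernel-orthonormal coefficients), `d`, `eigenvalues` (top `d`,
#'   non-negative), the scatter matrices `between` and `within`, the class
#'   kernel means (`class_means`, one column per class, plus `grand_mean`),
#'   the class blocks `class_blocks`, and the ridge `mu` used.
#' @export
#' @examples
#' d <- make_blobs(3, 8, dim = 3, separation = 6, seed = 1)
#' fit <- fit_kda(d, s = 2, d = 2)
#' fit$eigenvalues
fit_kda <- function(data, s, d, reg = 1e-8) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- nrow(data$x)
  C <- nlevels(data$labels)
  d <- as.integer(d)
  if (d < 1L || d > C - 1L) {
    stop("the number of retained discriminants d must satisfy ",
         "1 <= d <= C - 1 (here C = ", C, ", so d <= ", C - 1L,
         "); got d = ", d, call. = FALSE)
  }
  bump_counter("kda_fits")

  K <- kernel_matrix(data$x, s)
  grand_mean <- rowMeans(K)
  lv <- levels(data$labels)
  class_means <- matrix(0, n, C, dimnames = list(NULL, lv))
  class_blocks <- vector("list", C)
  names(class_blocks) <- lv
  between <- matrix(0, n, n)
  within <- matrix(0, n, n)
  for (i in seq_len(C)) {
    idx <- which(data$labels == lv[i])
    Ni <- length(idx)
    Ki <- K[, idx, drop = FALSE]
    Mi <- rowMeans(Ki)
    class_means[, i] <- Mi
    class_blocks[[i]] <- Ki
    dm <- Mi - grand_mean
    between <- between + Ni * tcrossprod(dm)
    # K_i (E - (1/N_i) J) K_i^T  =  K_i K_i^T - N_i M_i M_i^T
    # (a singleton class contributes exactly zero here)
    within <- within + tcrossprod(Ki) - Ni * tcrossprod(Mi)
  }
  between <- (between + t(between)) / 2
  within <- (within + t(within)) / 2

  mu <- max(reg * sum(diag(within)) / n, 1e-12)
  R <- NULL
  for (attempt in 1:6) {
    R <- tryCatch(chol(within + mu * diag(n)), error = function(e) NULL)
    if (!is.null(R)) break
    mu <- mu * 100
  }
  if (is.null(R)) {
    stop("within-class kernel scatter could not be factorized even after ",
         "ridge inflation; try a larger 'reg'", call. = FALSE)
  }
  Rinv <- backsolve(R, diag(n))
  Cm <- crossprod(Rinv, between %*% Rinv)
  Cm <- (Cm + t(Cm)) / 2
  eig <- eigen(Cm, symmetric = TRUE)
  if (any(!is.finite(eig$values))) {
    stop("eigen-solution is not finite; try a larger 'reg'", call. = FALSE)
  }
  alpha <- Rinv %*% eig$vectors[, seq_len(d), drop = FALSE]
  values <- eig$values[seq_len(d)]

  # orthonormalize alpha in the kernel inner product: alpha^T K alpha = I
  G <- crossprod(alpha, K %*% alpha)
  G <- (G + t(G)) / 2
  Rg <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(Rg)) {
    stop("retained discriminant directions are kernel-degenerate; ",
         "reduce d or use a larger 'reg'", call. = FALSE)
  }
  alpha <- alpha %*% backsolve(Rg, diag(d))
  # deterministic sign: first non-negligible coefficient of each column > 0
  for (k in seq_len(d)) {
    nz <- which(abs(alpha[, k]) > 1e-12)
    if (length(nz) && alpha[nz[1], k] < 0) alpha[, k] <- -alpha[, k]
  }

  structure(
    list(
      train = data, scale = s, alpha = alpha, d = d,
      eigenvalues = values, between = between, within = within,
      class_means = class_means, grand_mean = grand_mean,
      class_blocks = class_blocks, mu = mu
    ),
    class = "kda"
  )
}

#' @export
print.kda <- function(x, ...) {
  cat("Gaussian KDA model: N =", nrow(x$train$x), ", C =",
      nlevels(x$train$labels), ", d =", x$d, ", scale =", x$scale, "\n")
  cat("Leading eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Project samples onto the fitted discriminant subspace
#'
#' Coordinate `k` of a query `x` is `sum_j alpha[j, k] * K(x, x_j)` over the
#' training samples.
#'
#' @param model a fitted [fit_kda()] model.
#' @param newx numeric vector (one sample) or matrix (one per row) in the
#'   training feature dimension.
#' @return numeric matrix of projections, `n x d`.
#' @export
kda_project <- function(model, newx) {
  stopifnot(inherits(model, "kda"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  kx <- cross_kernel(newx, model$train$x, model$scale)
  kx %*% model$alpha
}

#' Kernel reconstruction error
#'
#' Squared distance from the feature-space image of `x` to its projection
#' onto the fitted discriminant subspace.  For the Gaussian kernel
#' `K(x, x) = 1`, and with kernel-orthonormal coefficients this collapses to
#' `RE(x) = 1 - ||t(x)||^2`, which lies in `[0, 1]` by Bessel's inequality.
#' Values are clamped to that interval; a violation beyond `1e-8` triggers
#' a warning (it indicates a numerically degenerate fit).
#'
#' @param model a fitted [fit_kda()] model.
#' @param newx numeric vector or matrix of query samples.
#' @return numeric vector of reconstruction errors in `[0, 1]`.
#' @export
reconstruction_error <- function(model, newx) {
  t_x <- kda_project(model, newx)
  re <- 1 - rowSums(t_x^2)
  viol <- pmax(-re, re - 1, 0)
  if (any(viol > 1e-8)) {
    warning("reconstruction error outside [0, 1] by up to ",
            signif(max(viol), 3), "; clamping", call. = FALSE)
  }
  pmin(pmax(re, 0), 1)
}

#' Serialize a KDA model to JSON
#'
#' Writes the training vectors, labels, scale, coefficients, dimension and
#' eigenvalues, enough to rebuild the model for projection elsewhere.
#'
#' @param model a fitted [fit_kda()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
kda_to_json <- function(model, path) {
  stopifnot(inherits(model, "kda"))
  obj <- list(
    type = "kda",
    scale = model$scale,
    d = model$d,
    eigenvalues = model$eigenvalues,
    labels = as.character(model$train$labels),
    train = model$train$x,
    alpha = model$alpha
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Rebuild a KDA model from its JSON serialization
#'
#' The scatter matrices and class blocks are recomputed from the stored
#' training set, so the result supports projection, reconstruction error
#' and inspection exactly like the original.
#'
#' @param path file written by [kda_to_json()].
#' @return a `kda` model.
#' @export
kda_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "kda") {
    stop("not a serialized KDA model: ", path, call. = FALSE)
  }
  data <- labeled_dataset(obj$train, obj$labels)
  model <- fit_kda(data, s = obj$scale, d = obj$d)
  model$alpha <- matrix(unlist(obj$alpha), nrow(data$x), obj$d)
  model$eigenvalues <- as.numeric(obj$eigenvalues)
  model
}
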