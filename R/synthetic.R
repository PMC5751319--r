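#' Synthetic Gaussian class clouds
#'
#' Draws `n_classes` isotropic Gaussian clusters whose centers are mutually
#' equidistant at the requested separation (centers sit on the scaled
#' vertices of a simplex embedded in the first `n_classes` coordinates).
#' A fixed seed fully determines the output.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class samples per class; scalar or length-`n_classes` vector.
#' @param dim feature dimension; must be >= `n_classes` so that mutually
#'   equidistant centers exist.
#' @param separation Euclidean distance between every pair of class centers.
#' @param noise_sd standard deviation of the isotropic noise around centers.
#' @param seed integer seed.
#' @return a [labeled_dataset()].
#' @export
#' @examples
#' d <- make_blobs(3, 10, dim = 5, separation = 6, seed = 1)
#' table(d$labels)
make_blobs <- function(n_classes, n_per_class, dim = n_classes,
                       separation = 4, noise_sd = 1, seed = 1) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (dim < n_classes) {
    stop("dim must be >= n_classes for equidistant centers", call. = FALSE)
  }
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  if (any(n_per_class < 1L)) stop("n_per_class must be positive", call. = FALSE)
  if (separation < 0 || noise_sd < 0) {
    stop("separation and noise_sd must be non-negative", call. = FALSE)
  }
  # vertices of a regular simplex: scaled unit vectors e_i are pairwise
  # separated by separation when scaled by separation / sqrt(2)
  centers <- matrix(0, n_classes, dim)
  diag(centers) <- separation / sqrt(2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rows <- vector("list", n_classes)
  for (i in seq_len(n_classes)) {
    rows[[i]] <- matrix(stats::rnorm(n_per_class[i] * dim, sd = noise_sd),
                        n_per_class[i], dim, byrow = TRUE)
    rows[[i]] <- sweep(rows[[i]], 2, centers[i, ], "+")
  }
  labeled_dataset(do.call(rbind, rows),
                  rep(paste0("class", seq_len(n_classes)), n_per_class))
}

#' Synthetic concentric shells
#'
#' Each class is sampled uniformly on a sphere (circle when `dim = 2`) of
#' its own radius, plus isotropic Gaussian noise.  With `noise_sd = 0` every
#' point of class `c` has norm exactly `radii[c]`: the degenerate
#' all-on-a-sphere configuration that defeats tangent-plane edge detection.
#' Concentric classes are not linearly separable, which is the regime where
#' kernel discriminant analysis earns its keep.
#'
#' @param n_per_class samples per class; scalar or vector matching `radii`.
#' @param radii strictly increasing positive radii, one per class.
#' @param dim ambient dimension (>= 2).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return a [labeled_dataset()].
#' @export
make_rings <- function(n_per_class, radii, dim = 2, noise_sd = 0.1, seed = 1) {
  radii <- as.numeric(radii)
  if (length(radii) < 2L) stop("need at least 2 radii (classes)", call. = FALSE)
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radii must be positive and strictly increasing", call. = FALSE)
  }
  if (dim < 2L) stop("dim must be >= 2", call. = FALSE)
  n_classes <- length(radii)
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  if (any(n_per_class < 1L)) stop("n_per_class must be positive", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rows <- vector("list", n_classes)
  for (c in seq_len(n_classes)) {
    dirs <- matrix(stats::rnorm(n_per_class[c] * dim), n_per_class[c], dim)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    noise <- matrix(stats::rnorm(n_per_class[c] * dim, sd = noise_sd),
                    n_per_class[c], dim)
    rows[[c]] <- radii[c] * dirs + noise
  }
  labeled_dataset(do.call(rbind, rows),
                  rep(paste0("class", seq_len(n_classes)), n_per_class))
}

#' Two-ring demonstration dataset
#'
#' The package's standard small nonlinear benchmark: two concentric noisy
#' rings of 30 points each (radii 1 and 2, noise 0.2, two dimensions).  The
#' radii are close enough, relative to the neighbourhood radius at the
#' default `u = 8`, that the largest class contains both edge samples (with
#' other-class points inside their epsilon-ball) and internal samples (with
#' pure neighbourhoods), so the scale-selection rule is exercised end to end.
#'
#' @param seed integer seed.
#' @return a [labeled_dataset()] with 60 samples in 2 classes.
#' @export
demo_rings <- function(seed = 1) {
  make_rings(n_per_class = 30, radii = c(1, 2), dim = 2,
             noise_sd = 0.2, seed = seed)
}

#' Synthetic PSSM profile
#'
#' Generates a position-specific scoring matrix with integer log-odds scores
#' drawn uniformly from `score_range`, the typical magnitude of PSI-BLAST
#' output.  The consensus sequence is the row-wise argmax residue (ties go
#' to the earliest column in the canonical order).
#'
#' @param length number of sequence positions `L` (>= 1).
#' @param seed integer seed.
#' @param score_range integer bounds (low, high) of the uniform score draw.
#' @return a [pssm_profile()] with an `L x 20` score matrix and consensus
#'   sequence.
#' @export
#' @examples
#' p <- make_pssm(60, seed = 7)
#' dim(p$scores)
make_pssm <- function(length, seed = 1, score_range = c(-10L, 13L)) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (base::length(score_range) != 2L || score_range[1] > score_range[2]) {
    stop("score_range must be c(low, high) with low <= high", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  scores <- matrix(
    sample(seq.int(score_range[1], score_range[2]), length * 20L,
           replace = TRUE),
    nrow = length, ncol = 20L
  )
  colnames(scores) <- AA_ORDER
  consensus <- AA_ORDER[apply(scores, 1L, which.max)]
  pssm_profile(scores, sequence = paste(consensus, collapse = ""))
}

#' Synthetic localization-style feature dataset
#'
#' Emulates the shape of the bacterial subcellular-localization benchmarks:
#' several location classes of PSSM-derived feature vectors (1000-dim
#' PsePSSM or 220-dim PSSM-S).  Class structure is induced by shifting each
#' class's PSSM scores by a class-specific offset before encoding, a crude
#' but sufficient stand-in for evolutionary signal.  Purely synthetic: it
#' reproduces the dimensions and class counts of real benchmarks, not their
#' biology.
#'
#' @param n_classes number of location classes (4 and 8 mirror the
#'   Gram-positive and Gram-negative benchmark shapes).
#' @param n_per_class proteins per class.
#' @param method `"psepssm"` or `"pssm_s"`.
#' @param length PSSM length `L` for every synthetic protein.
#' @param class_shift per-class score offset controlling separability.
#' @param seed integer seed.
#' @return a [labeled_dataset()] with `n_classes * n_per_class` rows.
#' @export
demo_localization <- function(n_classes = 4, n_per_class = 5,
                              method = c("psepssm", "pssm_s"),
                              length = 60, class_shift = 2, seed = 1) {
  method <- match.arg(method)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  rows <- list()
  labels <- character(0)
  for (cl in seq_len(n_classes)) {
    for (r in seq_len(n_per_class)) {
      p <- make_pssm(length, seed = seed * 10000L + cl * 100L + r)
      p$scores <- p$scores + class_shift * (cl - 1L)
      rows[[base::length(rows) + 1L]] <-
        if (method == "psepssm") pse_pssm(p) else pssm_s(p)
      labels <- c(labels, paste0("loc", cl))
    }
  }
  labeled_dataset(do.call(rbind, rows), labels)
}

# Seed handling: generators set the RNG state themselves and put the caller's
# state back afterwards, so a fixed spec is bitwise reproducible regardless
# of surrounding code.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
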