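#' PsePSSM feature encoding
#'
#' Summarizes an `L x 20` PSSM into the pseudo-PSSM vector: 20 column means
#' followed, for each lag `xi = 1..xi_max`, by 20 lag-`xi` correlation
#' factors, each the mean squared difference between scores `xi` positions
#' apart in the same column.  With the default `xi_max = 49` the result has
#' `20 * (1 + 49) = 1000` components.
#'
#' The zero-lag correlation block is identically zero, so the lag index
#' starts at 1 and the constant block is the plain column mean: this is what
#' makes the stated dimension come out.
#'
#' @param profile a [pssm_profile()].
#' @param xi_max largest lag; must be < `L`.
#' @param normalize if `TRUE`, squash scores through the logistic function
#'   `1 / (1 + exp(-x))` before summarizing (off by default; raw scores are
#'   the reference behaviour).
#' @return named numeric vector of length `20 * (1 + xi_max)`: the mean
#'   block, then one 20-column block per lag.
#' @export
#' @examples
#' p <- make_pssm(60, seed = 1)
#' length(pse_pssm(p))  # 1000
pse_pssm <- function(profile, xi_max = 49, normalize = FALSE) {
  stopifnot(inherits(profile, "pssm_profile"))
  xi_max <- as.integer(xi_max)
  L <- profile$length
  if (xi_max < 1L) stop("xi_max must be >= 1", call. = FALSE)
  if (xi_max >= L) {
    stop("xi_max (", xi_max, ") must be smaller than the sequence length (",
         L, "): use a shorter lag or a longer sequence", call. = FALSE)
  }
  sc <- profile$scores
  if (normalize) sc <- 1 / (1 + exp(-sc))
  aa <- colnames(sc)

  means <- colMeans(sc)
  names(means) <- paste0("mean_", aa)
  blocks <- vector("list", xi_max)
  for (xi in seq_len(xi_max)) {
    d <- sc[seq_len(L - xi), , drop = FALSE] -
      sc[seq.int(xi + 1L, L), , drop = FALSE]
    g <- colSums(d^2) / (L - xi)
    names(g) <- paste0("lag", xi, "_", aa)
    blocks[[xi]] <- g
  }
  c(means, unlist(blocks, use.names = TRUE))
}

#' PSSM-S feature encoding
#'
#' The 220-dimensional composite PSSM summary made of four blocks:
#' \describe{
#'   \item{AAO (20)}{occurrence frequency of each residue in the profile's
#'     consensus sequence (row-wise argmax, ties to the earliest column),
#'     divided by `L`.}
#'   \item{PSSM-AAO (20)}{column sums divided by `L` (per-residue mean
#'     evolutionary score).}
#'   \item{PSSM-SD (80)}{segmented distribution: per column, the normalized
#'     1-based position at which the running sum of absolute scores first
#'     reaches 25% and 50% of the column total, measured from the
#'     N-terminus and from the C-terminus (4 values per column).}
#'   \item{PSSM-SAC (100)}{segmented auto covariance: per column, the
#'     mean-centered auto covariance `(1/(L-g)) * sum_i (M[i] - mean) *
#'     (M[i+g] - mean)` at lags `g = 1..5`.}
#' }
#'
#' @param profile a [pssm_profile()].
#' @param sd_fracs fractions of the absolute-score column total used by the
#'   segmented-distribution block (two values by default, giving 80
#'   components).
#' @param sac_lags number of auto-covariance lags (5 by default, giving 100
#'   components); requires `L > sac_lags`.
#' @param normalize logistic squashing as in [pse_pssm()] (off by default).
#' @return named numeric vector; 220 components under the defaults.
#' @export
pssm_s <- function(profile, sd_fracs = c(0.25, 0.5), sac_lags = 5,
                   normalize = FALSE) {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- profile$length
  sac_lags <- as.integer(sac_lags)
  if (L <= sac_lags) {
    stop("sequence length ", L, " is too short for auto-covariance lags up ",
         "to ", sac_lags, " (need L > ", sac_lags, ")", call. = FALSE)
  }
  sc <- profile$scores
  if (normalize) sc <- 1 / (1 + exp(-sc))
  aa <- colnames(sc)

  # AAO: consensus-residue occurrence frequencies
  consensus <- apply(sc, 1L, which.max)  # ties -> lowest column index
  aao <- tabulate(consensus, nbins = 20L) / L
  names(aao) <- paste0("aao_", aa)

  # PSSM-AAO: per-column mean score
  paao <- colSums(sc) / L
  names(paao) <- paste0("pssm_aao_", aa)

  # PSSM-SD: first positions (normalized) at which the running absolute
  # score mass reaches each fraction, from either terminus
  sd_block <- numeric(0)
  for (from_c in c(FALSE, TRUE)) {
    for (f in sd_fracs) {
      v <- vapply(seq_len(20L), function(j) {
        a <- abs(sc[, j])
        if (from_c) a <- rev(a)
        tot <- sum(a)
        if (tot == 0) return(0)
        min(which(cumsum(a) >= f * tot)) / L
      }, numeric(1))
      side <- if (from_c) "c" else "n"
      names(v) <- paste0("sd_", side, f * 100, "_", aa)
      sd_block <- c(sd_block, v)
    }
  }

  # PSSM-SAC: mean-centered auto covariance per column and lag
  mu <- colMeans(sc)
  centered <- sweep(sc, 2L, mu)
  sac <- numeric(0)
  for (g in seq_len(sac_lags)) {
    v <- colSums(centered[seq_len(L - g), , drop = FALSE] *
                   centered[seq.int(g + 1L, L), , drop = FALSE]) / (L - g)
    names(v) <- paste0("sac_lag", g, "_", aa)
    sac <- c(sac, v)
  }

  c(aao, paao, sd_block, sac)
}

#' Encode a list of PSSM profiles into a feature matrix
#'
#' @param profiles list of [pssm_profile()] objects.
#' @param method `"psepssm"` (1000 features by default) or `"pssm_s"`
#'   (220 features).
#' @param ... passed to [pse_pssm()] or [pssm_s()].
#' @return numeric matrix, one row per profile.
#' @export
extract_features <- function(profiles, method = c("psepssm", "pssm_s"), ...) {
  method <- match.arg(method)
  fn <- switch(method, psepssm = pse_pssm, pssm_s = pssm_s)
  rows <- lapply(profiles, fn, ...)
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    stop("profiles produced feature vectors of differing length", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- names(profiles)
  out
}

#' Write a feature matrix as tab-separated text
#'
#' One row per sample: id, optional label, then the features, with a header
#' row carrying the feature (block) names.
#'
#' @param x numeric matrix of features.
#' @param path output path.
#' @param ids sample identifiers; defaults to rownames or `sample1..N`.
#' @param labels optional class labels, written as a `label` column.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path, ids = NULL, labels = NULL) {
  x <- as.matrix(x)
  if (is.null(ids)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df <- cbind(df, as.data.frame(x, optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path tab-separated file with header; an `id` column, an optional
#'   label column, and numeric feature columns.
#' @param labels_col name of the label column (`"label"` by default); set to
#'   `NULL` to read an unlabeled matrix.
#' @return with labels, a [labeled_dataset()] whose matrix has the ids as
#'   rownames; without, a plain numeric matrix.
#' @export
read_features <- function(path, labels_col = "label") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) {
    stop("feature table has no 'id' column: ", path, call. = FALSE)
  }
  ids <- as.character(df[["id"]])
  labels <- NULL
  drop <- "id"
  if (!is.null(labels_col) && labels_col %in% names(df)) {
    labels <- df[[labels_col]]
    drop <- c(drop, labels_col)
  } else if (!is.null(labels_col)) {
    stop("label column '", labels_col, "' not found in ", path, call. = FALSE)
  }
  x <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  if (is.null(labels)) return(x)
  labeled_dataset(x, labels)
}
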