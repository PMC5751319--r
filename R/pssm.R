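#' Canonical amino-acid column order
#'
#' The 20 standard residues in the order PSI-BLAST prints PSSM columns.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' PSSM profile container
#'
#' A position-specific scoring matrix for one protein: `L` sequence
#' positions by 20 residue columns of real-valued substitution scores.
#'
#' @param scores numeric `L x 20` matrix; column names, if absent, are set
#'   to [AA_ORDER].
#' @param sequence optional string of `L` residue letters.
#' @return an object of class `pssm_profile` with elements `scores`,
#'   `sequence` (or `NULL`) and `length`.
#' @export
pssm_profile <- function(scores, sequence = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) {
    stop("a PSSM has exactly 20 columns, got ", ncol(scores), call. = FALSE)
  }
  if (nrow(scores) < 1L) stop("a PSSM needs at least one row", call. = FALSE)
  if (anyNA(scores)) stop("PSSM scores contain missing values", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- AA_ORDER
  if (!is.null(sequence)) {
    sequence <- as.character(sequence)
    if (nchar(sequence) != nrow(scores)) {
      stop("sequence length ", nchar(sequence), " does not match ",
           nrow(scores), " PSSM rows", call. = FALSE)
    }
  }
  structure(
    list(scores = scores, sequence = sequence, length = nrow(scores)),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile:", x$length, "positions x 20 residues\n")
  if (!is.null(x$sequence)) {
    s <- x$sequence
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat("Sequence:", s, "\n")
  }
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: a couple of header lines, a column
#' header naming the 20 residues (printed twice when the percentage block is
#' present), then one line per position holding the position index, the
#' query residue, 20 integer log-odds scores, optionally 20 more percentage
#' columns and two trailing floats, and footer lines after a blank line.
#' Only the first 20-score block is kept; the residue letters are collected
#' into the consensus/query sequence.  Column order follows the file header.
#'
#' @param path path to the file, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a [pssm_profile()].
#' @export
parse_pssm <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (length(lines) == 0L) stop("empty PSSM input", call. = FALSE)

  # locate the column header: the first line whose tokens are >= 20
  # single-letter residues
  header_at <- NA_integer_
  header_order <- AA_ORDER
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) >= 20L && all(nchar(tok) == 1L) &&
        all(tok %in% c(AA_ORDER, "B", "Z", "X", "*"))) {
      header_at <- i
      header_order <- tok[seq_len(20L)]
      break
    }
  }
  start <- if (is.na(header_at)) 1L else header_at + 1L

  score_rows <- list()
  residues <- character()
  body_started <- FALSE
  for (i in seq.int(start, length(lines))) {
    raw <- trimws(lines[i])
    if (!nzchar(raw)) {
      if (body_started) break  # blank line ends the body; footer follows
      next
    }
    tok <- strsplit(raw, "\\s+")[[1]]
    looks_like_row <- grepl("^[0-9]+$", tok[1]) && length(tok) >= 2L &&
      nchar(tok[2]) == 1L
    if (!looks_like_row) {
      if (body_started) break
      next
    }
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    n_ok <- sum(!is.na(nums))
    # valid widths: 20 (scores only), 40 (+percentages), 42 (+two floats)
    if (n_ok < 20L || anyNA(nums[seq_len(min(20L, length(nums)))])) {
      stop("malformed PSSM row at line ", i, ": expected >= 20 numeric ",
           "scores, found ", n_ok, call. = FALSE)
    }
    body_started <- TRUE
    score_rows[[length(score_rows) + 1L]] <- nums[seq_len(20L)]
    residues[length(residues) + 1L] <- tok[2]
  }
  if (length(score_rows) == 0L) {
    stop("no PSSM body rows found in input", call. = FALSE)
  }
  scores <- do.call(rbind, score_rows)
  colnames(scores) <- header_order
  pssm_profile(scores, sequence = paste(residues, collapse = ""))
}

#' Write a PSSM profile in PSI-BLAST ASCII form
#'
#' Emits the first 20-score block in the `-out_ascii_pssm` layout so that
#' [parse_pssm()] round-trips the scores exactly (scores are written as
#' integers when integral, otherwise with full precision).
#'
#' @param profile a [pssm_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores
  seq_chars <- if (!is.null(profile$sequence)) {
    strsplit(profile$sequence, "")[[1]]
  } else {
    colnames(sc)[apply(sc, 1L, which.max)]
  }
  fmt_num <- function(v) {
    ifelse(v == round(v), format(as.integer(round(v))), format(v, digits = 15))
  }
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and rounded",
    paste0("            ", paste(sprintf("%3s", colnames(sc)), collapse = " "))
  )
  for (i in seq_len(nrow(sc))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, seq_chars[i]),
      paste(sprintf("%3s", fmt_num(sc[i, ])), collapse = " ")
    ))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1337     0.3177")
  writeLines(lines, path)
  invisible(path)
}
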