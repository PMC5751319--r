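# Lightweight call counters used to verify the work budget of the two
# scale-selection routes (the reconstruction-error selector does |S| KDA
# fits and no classifier work; grid search adds a jackknife-KNN pass per
# candidate).

.counters <- new.env(parent = emptyenv())

bump_counter <- function(name) {
  cur <- get0(name, envir = .counters, ifnotfound = 0L)
  assign(name, cur + 1L, envir = .counters)
  invisible(NULL)
}

#' Reset the package's internal call counters
#'
#' Counters track the number of KDA fits (`kda_fits`) and KNN predictions
#' (`knn_calls`) since the last reset; they exist so the cost structure of
#' the selection methods can be asserted rather than timed.
#'
#' @return invisibly, the counter values before the reset.
#' @export
counters_reset <- function() {
  old <- counters_get()
  rm(list = ls(.counters), envir = .counters)
  invisible(old)
}

#' Read the package's internal call counters
#'
#' @return named list with `kda_fits` and `knn_calls`.
#' @export
counters_get <- function() {
  list(
    kda_fits = get0("kda_fits", envir = .counters, ifnotfound = 0L),
    knn_calls = get0("knn_calls", envir = .counters, ifnotfound = 0L)
  )
}
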