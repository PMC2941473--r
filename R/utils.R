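#' @useDynLib minitox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# C-locale (radix) sort: byte-deterministic across platforms/locales.
sort_c <- function(x, decreasing = FALSE) {
  if (length(x) == 0L) return(character(0))
  sort(x, decreasing = decreasing, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

mt_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "mt_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

mt_log <- function(store, event, detail = "") {
  if (!is.null(store)) {
    store$log[[length(store$log) + 1L]] <- list(
      time = Sys.time(), event = event, detail = detail
    )
  }
  invisible(NULL)
}

# Deterministic numeric formatting for serialization (hashes, RDF, reports).
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == 0) v <- 0   # normalize negative zero
    if (v == floor(v) && abs(v) < 1e15) sprintf("%.1f", v)
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}
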