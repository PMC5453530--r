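## Internal helpers shared across modules.

#' Signal a classed error
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and the CLI) can map them onto exit codes without string matching.
#'
#' @param class condition class suffix, e.g. "parameter_error"
#' @param msg message
#' @noRd
svcn_abort <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("svcn_", class), "svcn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered pair ordering: a < b lexicographically
#' @noRd
order_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

#' log(sum(exp(x))) without overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
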