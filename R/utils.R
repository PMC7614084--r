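`%||%` <- function(a, b) if (is.null(a)) b else a

abort_wgdc <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

warn_wgdc <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort_wgdc(msg, ...)
  invisible(TRUE)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' Derive a stream of reproducible sub-seeds from one master seed
#'
#' Used so that independent stochastic stages of a run each get their own seed
#' while the whole run stays reproducible from a single integer. Kept well
#' below .Machine$integer.max.
#'
#' @param seed master seed (single integer).
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  (as.integer(seed) + 77777L * seq_len(n)) %% 2000000011L
}
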