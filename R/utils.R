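#' @keywords internal
#' @useDynLib deepathnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible sub-seed from a root seed and a stream label, so
## that independent random operations never share or perturb each other's
## draws.  Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 69069 + h * 7919) %% 2147483647)
}

dpn_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
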