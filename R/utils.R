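#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dpois optimize pnorm ppois pt rgeom runif sd var
#' @importFrom utils head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib syntnet, .registration = TRUE
NULL

## Condition constructors. Validation errors (bad user input, malformed
## files) are distinguished from runtime errors so the CLI can map them to
## exit code 1 vs 2.
stop_validation <- function(msg, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c("syntnet_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = call)
  )
  stop(cnd)
}

stop_runtime <- function(msg, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c("syntnet_runtime_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = call)
  )
  stop(cnd)
}

warn_syntnet <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Hurwitz zeta  sum_{k>=a} k^(-s)  for s > 1, integer a >= 1.
## Direct sum over the first `terms` values plus an Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a = 1, terms = 10000L) {
  stopifnot(s > 1, a >= 1)
  k <- seq.int(a, a + terms - 1L)
  direct <- sum(k^(-s))
  b <- a + terms                       # tail starts at b
  tail <- b^(1 - s) / (s - 1) + b^(-s) / 2 + s * b^(-s - 1) / 12
  direct + tail
}

## Open a text connection, transparently handling .gz paths.
open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

open_output <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

## NFC-normalize and strip surrounding whitespace; vertex key convention.
normalize_form <- function(x) {
  stringi::stri_trans_nfc(trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
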