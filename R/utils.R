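#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom Matrix sparseMatrix
#' @importFrom graphics lines points abline legend par
#' @importFrom grDevices dev.off
NULL

## Lightweight logging: messages are informational and can be suppressed by
## callers; rejection bookkeeping and unit conversions go through here so that
## every drop or conversion leaves a trace.
smlmz_log <- function(...) {
  message("[smlmz] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## 16-bit camera ceiling used throughout for intensity normalisation.
INT16_MAX <- 65535

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

## Seed handling: generators take an integer seed; NULL means "use the current
## RNG stream". A given seed makes the output bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
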