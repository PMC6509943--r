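#' @keywords internal
#' @useDynLib cnnlda, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards so library calls never disturb user-level RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

## Binary 0/1 check for a numeric matrix.
is_binary <- function(M) all(M == 0 | M == 1)
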