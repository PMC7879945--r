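#' @useDynLib invsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq p.adjust median qlogis plogis rnorm runif rbinom sd var complete.cases
#' @importFrom utils write.table read.table
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All randomness in the package funnels through this helper so that a master
## seed plus fixed per-stage offsets yields bit-reproducible results.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed %% .Machine$integer.max)
  }
  force(expr)
}

## Derive a per-stage / per-condition sub-seed from a master seed.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %%
               (.Machine$integer.max - 1L)) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0
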