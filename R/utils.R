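#' @keywords internal
"_PACKAGE"

#' @useDynLib spade, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats p.adjust rpois runif
#' @importFrom utils head
NULL

## Evaluate `code` under a locally seeded RNG, restoring the caller's RNG state.
## seed = NULL means: use (and advance) the session RNG, the usual R convention.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic stream of sub-seeds (< 2^31) derived from one master seed,
## used to make surrogate loops and per-realization experiments independently
## reproducible and order-invariant.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
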