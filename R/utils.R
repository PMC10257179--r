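# Internal helpers shared across modules.

#' Evaluate an expression under a deterministic RNG substream
#'
#' Derives a child seed from a master seed and a stream index, runs `expr`
#' with that seed, and restores the caller's RNG state afterwards. Substreams
#' are independent of evaluation order, so adding an experiment (a new stream
#' index) never perturbs the draws of earlier ones.
#'
#' @param master_seed integer master seed.
#' @param index non-negative integer stream index.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(master_seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master_seed, index))
  expr
}

# Deterministic integer hash of (seed, index) into [1, 2^31 - 2].
derive_seed <- function(master_seed, index) {
  m <- 2147483647          # 2^31 - 1, prime
  s <- (as.double(master_seed) %% m)
  h <- (s * 48271) %% m    # Lehmer multiplier
  h <- (h + (as.double(index) + 1) * 69621) %% m
  h <- (h * 48271) %% m
  as.integer(h %% (m - 1)) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
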