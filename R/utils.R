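# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# rowsum() drops empty groups; this scatters M's rows summed by idx into a
# fixed n-row result so downstream shapes never depend on group coverage.
segment_sum <- function(M, idx, n) {
  M <- as.matrix(M)
  out <- matrix(0, n, ncol(M))
  rs <- rowsum(M, group = idx, reorder = TRUE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

segment_sum_vec <- function(x, idx, n) {
  as.vector(segment_sum(matrix(x, ncol = 1L), idx, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
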