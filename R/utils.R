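#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never disturb user-level reproducibility.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
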