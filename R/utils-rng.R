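#' Evaluate an expression under a derived random substream
#'
#' All stochastic operations in the package draw from substreams derived from
#' a single user seed by fixed integer offsets, so that each stage is
#' individually reproducible and the whole dataset is byte-identical under a
#' fixed seed.
#'
#' @param seed master integer seed (kept below 2^31 after offsetting).
#' @param offset fixed per-operation offset.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_substream <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000000000L) + as.integer(offset))
  eval.parent(substitute(expr))
}

# fixed substream offsets, one per stochastic operation
.SUBSTREAM <- c(
  families  = 101L,
  contigs   = 202L,
  reads     = 303L,
  orthologs = 404L,
  counts    = 505L,
  bootstrap = 606L,
  coverage  = 707L,
  demo      = 808L
)
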