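# Stage-wise fragment-count simulation for the expression module: Poisson
# counts (the no-replicate setting the exact test assumes) around per-gene
# means, with designated DE genes carrying a configured fold change in the
# designated stages.

#' Simulate a five-stage count matrix with planted differential expression
#'
#' @param genes gene ids (rows).
#' @param mean per-gene expected count (scalar or one per gene), > 0.
#' @param de_genes subset of `genes` carrying the fold change.
#' @param fold fold change applied to `de_genes` in `de_stages`.
#' @param de_stages stage indices receiving the fold change.
#' @param n_stages number of stages (>= 2; default 5, named after shrimp
#'   larval stages).
#' @param lengths per-gene CDS lengths in bp (default: random 500-2500).
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()]) and `truth` (character
#'   vector of DE gene ids).
#' @export
simulate_counts <- function(genes, mean = 500, de_genes = character(0),
                            fold = 8, de_stages = c(3, 4), n_stages = 5,
                            lengths = NULL, seed = 1) {
  if (n_stages < 2) stop("need at least two stages")
  stopifnot(all(mean > 0), fold > 0)
  stopifnot(all(de_genes %in% genes))
  if (length(de_genes) && any(de_stages > n_stages))
    stop("de_stages outside the stage range")
  mean <- rep_len(mean, length(genes))
  stages <- if (n_stages == 5) .STAGES else paste0("stage", seq_len(n_stages))
  with_substream(seed, .SUBSTREAM[["counts"]], {
    if (is.null(lengths))
      lengths <- round(stats::runif(length(genes), 500, 2500))
    mu <- matrix(mean, nrow = length(genes), ncol = n_stages,
                 dimnames = list(genes, stages))
    if (length(de_genes))
      mu[de_genes, de_stages] <- mu[de_genes, de_stages] * fold
    counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                     dimnames = dimnames(mu))
    list(counts = count_matrix(counts, lengths = lengths),
         truth = de_genes)
  })
}
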