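# Uniform-coverage shotgun read simulation.  Per-contig read counts are set
# deterministically to round(depth * length / read_length) so the realised
# mean coverage equals the requested depth up to rounding; start positions
# are uniform and strands random.  Reads are error-free by default; an
# optional uniform per-base error rate exists for robustness checks.

#' Simulate shotgun reads over contigs
#'
#' @param contigs named character vector of contig sequences.
#' @param depth target mean fold coverage (> 0); may be a single value or
#'   one per contig (to emulate coverage-biased contaminants).
#' @param read_length read length in bp (must not exceed the shortest
#'   contig).
#' @param seed integer seed.
#' @param error_rate uniform per-base substitution error rate (default 0).
#' @return named character vector of reads; names encode
#'   `contig|start|strand|index` provenance.
#' @export
simulate_reads <- function(contigs, depth, read_length, seed = 1,
                           error_rate = 0) {
  stopifnot(length(contigs) >= 1, all(depth > 0), read_length > 0)
  if (read_length > min(nchar(contigs)))
    stop("read length exceeds the shortest contig")
  depth <- rep_len(depth, length(contigs))
  with_substream(seed, .SUBSTREAM[["reads"]], {
    out <- list()
    for (ci in seq_along(contigs)) {
      len <- nchar(contigs[[ci]])
      n <- round(depth[ci] * len / read_length)
      if (n == 0) next
      starts <- sample.int(len - read_length + 1L, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      reads <- substring(contigs[[ci]], starts, starts + read_length - 1L)
      rc <- strands == "-"
      if (any(rc)) {
        reads[rc] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[rc])))
      }
      if (error_rate > 0) {
        reads <- vapply(reads, function(r) {
          v <- strsplit(r, "")[[1]]
          hit <- stats::runif(length(v)) < error_rate
          if (any(hit)) {
            v[hit] <- vapply(v[hit], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
          }
          paste(v, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      names(reads) <- sprintf("%s|%d|%s|%d", names(contigs)[ci], starts,
                              strands, seq_len(n))
      out[[ci]] <- reads
    }
    unlist(out)
  })
}
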