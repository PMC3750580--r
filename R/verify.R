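# Genome-integration verification: strict-threshold mapping of candidate
# segments to assembly contigs, a seed-and-extend read aligner enforcing the
# two-mismatch rule, and a coverage-bias test comparing candidate-bearing
# contigs against randomly selected background contigs (a contaminant
# transcript has no genomic contig, and a contaminant contig shows aberrant
# read coverage).

#' Map candidate segments to assembly contigs at strict thresholds
#'
#' Nucleotide local alignment (match +1, mismatch -2, gap open 5 / extend
#' 2); E-values use the nucleotide Karlin-Altschul parameters with the total
#' contig length as database size.  Only hits meeting both thresholds are
#' returned, best hit first within each candidate.
#'
#' @param candidates named character vector of nucleotide candidate
#'   sequences.
#' @param contigs named character vector of contigs.
#' @param max_e maximum E-value (inclusive; default 1e-40).
#' @param min_identity minimum percent identity (inclusive; default 90).
#' @param seed_k nucleotide k-mer pre-screen size (a contig must share a
#'   k-mer with the candidate, on either strand, to be aligned).
#' @return data.frame: `candidate_id`, `contig_id`, `e_value`,
#'   `percent_identity`, `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive), `strand`.
#' @export
map_to_contigs <- function(candidates, contigs, max_e = 1e-40,
                           min_identity = 90, seed_k = 11) {
  if (length(contigs) == 0) stop("empty contig set")
  db <- sum(nchar(contigs))
  ctg_kmers <- lapply(contigs, function(s) unique(.kmers(s, seed_k)))
  rows <- list()
  for (qi in seq_along(candidates)) {
    q <- candidates[[qi]]
    qrc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(q)))
    qk <- unique(c(.kmers(q, seed_k), .kmers(qrc, seed_k)))
    for (ci in seq_along(contigs)) {
      if (!any(qk %in% ctg_kmers[[ci]])) next
      hit_f <- local_align(q, contigs[[ci]], type = "nucleotide")
      hit_r <- local_align(qrc, contigs[[ci]], type = "nucleotide")
      strand <- if (hit_f$score >= hit_r$score) "+" else "-"
      al <- if (strand == "+") hit_f else hit_r
      e <- karlin_altschul_evalue(al$score, nchar(q), db,
                                  type = "nucleotide")
      pid <- 100 * al$matches / al$aln_length
      if (e > max_e || pid < min_identity) next
      rows[[length(rows) + 1]] <- data.frame(
        candidate_id = names(candidates)[qi],
        contig_id = names(contigs)[ci],
        e_value = e, percent_identity = round(pid, 2),
        qstart = al$qstart, qend = al$qend,
        sstart = al$sstart, send = al$send, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate_id = character(0), contig_id = character(0),
               e_value = numeric(0), percent_identity = numeric(0),
               qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  out[order(out$candidate_id, out$e_value), , drop = FALSE]
}

#' Per-contig read coverage under the two-mismatch mapping rule
#'
#' Seed-and-extend: the first `seed_len` bases of each read (and of its
#' reverse complement) must match a contig exactly; each candidate placement
#' is extended over the full read, and placements with more than
#' `max_mismatches` mismatches are discarded.  Each read is assigned to its
#' single best placement (fewest mismatches; ties broken by contig order,
#' then coordinate, then forward strand); unmapped reads are dropped.
#'
#' @param reads named character vector of reads (uniform length).
#' @param contigs named character vector of contigs.
#' @param max_mismatches maximum mismatches per alignment (default 2).
#' @param seed_len exact-match seed length.
#' @return object of class `coverage_profile`: data.frame with `contig_id`,
#'   `length`, `n_reads`, `depth`; attribute `aligned_bases`.
#' @export
compute_coverage <- function(reads, contigs, max_mismatches = 2,
                             seed_len = 20) {
  stopifnot(length(contigs) >= 1)
  clen <- nchar(contigs)
  if (length(reads) == 0) {
    out <- data.frame(contig_id = names(contigs), length = unname(clen),
                      n_reads = 0L, depth = 0)
    attr(out, "aligned_bases") <- 0
    class(out) <- c("coverage_profile", "data.frame")
    return(out)
  }
  rl <- unique(nchar(reads))
  if (length(rl) != 1) stop("reads must have uniform length")
  if (rl > min(clen)) stop("read length exceeds a contig length")
  seed_len <- min(seed_len, rl)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  oriented <- c(reads, rc)  # first half +, second half -
  n <- length(reads)
  seeds <- Biostrings::DNAStringSet(unname(substr(oriented, 1, seed_len)))
  pd <- Biostrings::PDict(seeds)

  raw_reads <- lapply(oriented, charToRaw)
  cand <- list()
  for (ci in seq_along(contigs)) {
    subj <- Biostrings::DNAString(contigs[[ci]])
    m <- Biostrings::matchPDict(pd, subj)
    starts <- Biostrings::startIndex(m)
    ks <- which(lengths(starts) > 0)
    if (!length(ks)) next
    k_vec <- rep(ks, lengths(starts)[ks])
    s_vec <- unlist(starts[ks], use.names = FALSE)
    ok <- s_vec + rl - 1L <= clen[ci]
    k_vec <- k_vec[ok]; s_vec <- s_vec[ok]
    if (!length(k_vec)) next
    raw_ctg <- charToRaw(contigs[[ci]])
    mm <- vapply(seq_along(k_vec), function(i)
      sum(raw_reads[[k_vec[i]]] !=
            raw_ctg[s_vec[i]:(s_vec[i] + rl - 1L)]), integer(1))
    keep <- mm <= max_mismatches
    if (!any(keep)) next
    cand[[length(cand) + 1]] <- data.frame(
      ri = ifelse(k_vec[keep] <= n, k_vec[keep], k_vec[keep] - n),
      fwd = k_vec[keep] <= n, ctg = ci, pos = s_vec[keep], mm = mm[keep])
  }
  best_ctg <- rep(NA_integer_, n)
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd$ri, cd$mm, cd$ctg, cd$pos, !cd$fwd), , drop = FALSE]
    cd <- cd[!duplicated(cd$ri), , drop = FALSE]
    best_ctg[cd$ri] <- cd$ctg
  }
  mapped <- !is.na(best_ctg)
  n_reads <- tabulate(best_ctg[mapped], nbins = length(contigs))
  depth <- n_reads * rl / clen
  out <- data.frame(contig_id = names(contigs), length = unname(clen),
                    n_reads = n_reads, depth = unname(depth),
                    stringsAsFactors = FALSE)
  attr(out, "aligned_bases") <- sum(n_reads) * rl
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Coverage-bias test of target contigs against random background contigs
#'
#' Samples `n_background` background contigs without replacement (seeded)
#' and compares per-contig mean depths with a two-sided Welch two-sample
#' t-test.  The verdict is "consistent" (no contamination signal) when
#' p > alpha.  With zero variance in both groups and equal means, p = 1 by
#' definition.
#'
#' @param target_depths per-contig mean depths of the candidate-bearing
#'   contigs (>= 2 values).
#' @param background_depths per-contig mean depths of all available
#'   background contigs.
#' @param n_background number of background contigs to sample.
#' @param seed integer seed for the background sample.
#' @param alpha significance level.
#' @return object of class `coverage_bias_result`: list with `target_mean`,
#'   `background_mean`, `t`, `df`, `p_value`, `verdict`.
#' @export
coverage_bias_test <- function(target_depths, background_depths,
                               n_background = 1000, seed = 1,
                               alpha = 0.05) {
  if (length(target_depths) < 2) stop("need at least two target contigs")
  if (n_background > length(background_depths))
    stop("n_background exceeds available background contigs")
  bg <- with_substream(seed, .SUBSTREAM[["coverage"]], {
    background_depths[sample.int(length(background_depths), n_background)]
  })
  if (stats::var(target_depths) == 0 && stats::var(bg) == 0) {
    eq <- mean(target_depths) == mean(bg)
    res <- list(target_mean = mean(target_depths),
                background_mean = mean(bg),
                t = 0, df = NA_real_, p_value = if (eq) 1 else 0,
                verdict = if (eq) "consistent" else "biased")
    class(res) <- "coverage_bias_result"
    return(res)
  }
  tt <- stats::t.test(target_depths, bg, var.equal = FALSE)
  res <- list(target_mean = mean(target_depths),
              background_mean = mean(bg),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value,
              verdict = if (tt$p.value > alpha) "consistent" else "biased")
  class(res) <- "coverage_bias_result"
  res
}

#' @export
print.coverage_bias_result <- function(x, ...) {
  cat(sprintf(
    "coverage bias: target %.2f vs background %.2f (t=%.3f, df=%.1f, p=%.3g) -> %s\n",
    x$target_mean, x$background_mean, x$t, x$df, x$p_value, x$verdict))
  invisible(x)
}

#' Screen candidates against the mitochondrial genome (NUMT check)
#'
#' Reuses the contig-mapping machinery at a permissive E cutoff; candidates
#' with zero hits are flagged "not NUMT-like" (not of recent mitochondrial
#' origin).
#'
#' @param candidates named character vector of candidate sequences.
#' @param mito mitochondrial genome sequence (character scalar).
#' @param max_e maximum E-value (default 1e-10).
#' @return list with `hits` (mapping data.frame) and `not_numt_like`
#'   (character vector of candidate ids without mitochondrial similarity).
#' @export
mito_screen <- function(candidates, mito, max_e = 1e-10) {
  stopifnot(is.character(mito), length(mito) == 1)
  hits <- map_to_contigs(candidates, c(mitochondrion = mito),
                         max_e = max_e, min_identity = 0)
  list(hits = hits,
       not_numt_like = setdiff(names(candidates), hits$candidate_id))
}
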