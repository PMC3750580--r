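# Structural analysis of transferred segments: translated (six-frame)
# synteny blocks between a recipient contig and a donor genome, co-transfer
# and lost-intergenic calls against the donor annotation, spliced intron
# detection by transcript-to-genome comparison, and a same-strand/gap operon
# heuristic standing in for a prokaryotic operon database lookup.

# ungapped diagonal block finding between two amino-acid strings:
# shared k-mers seed diagonals; seeds on a diagonal are merged and extended
# outwards while the running BLOSUM62 score stays within `xdrop` of its
# maximum.  Returns 1-based inclusive aa intervals plus score and identity.
.diagonal_blocks <- function(qaa, saa, k = 7, merge_gap = 30, xdrop = 15) {
  if (nchar(qaa) < k || nchar(saa) < k) return(NULL)
  B <- .blosum62()
  qk <- .kmers(qaa, k)
  sk <- .kmers(saa, k)
  sk_idx <- split(seq_along(sk), sk)
  hits <- list()
  for (qpos in seq_along(qk)) {
    sp <- sk_idx[[qk[qpos]]]
    if (!is.null(sp)) hits[[length(hits) + 1]] <- cbind(qpos, sp)
  }
  if (!length(hits)) return(NULL)
  seeds <- do.call(rbind, hits)
  diag <- seeds[, 2] - seeds[, 1]
  qv <- strsplit(qaa, "")[[1]]
  sv <- strsplit(saa, "")[[1]]
  qv[!qv %in% rownames(B)] <- "X"
  sv[!sv %in% rownames(B)] <- "X"
  out <- list()
  for (d in unique(diag)) {
    qp <- sort(unique(seeds[diag == d, 1]))
    # split seed positions into runs with gaps <= merge_gap
    runs <- split(qp, cumsum(c(1, diff(qp) > merge_gap)))
    for (run in runs) {
      qs <- min(run); qe <- max(run) + k - 1L
      # extend left
      while (qs > 1 && qs + d > 1) {
        sc <- B[qv[qs - 1], sv[qs - 1 + d]]
        if (sc <= 0) break
        qs <- qs - 1
      }
      # extend right
      qmax <- min(length(qv), length(sv) - d)
      while (qe < qmax) {
        sc <- B[qv[qe + 1], sv[qe + 1 + d]]
        if (sc <= 0) break
        qe <- qe + 1
      }
      ii <- qs:qe
      score <- sum(B[cbind(qv[ii], sv[ii + d])])
      out[[length(out) + 1]] <- data.frame(
        q_aa_start = qs, q_aa_end = qe, s_aa_start = qs + d,
        s_aa_end = qe + d, score = score,
        identity = 100 * mean(qv[ii] == sv[ii + d]))
    }
  }
  do.call(rbind, out)
}

#' Translated synteny blocks between a contig and a donor genome
#'
#' Compares all six reading frames of the contig against all six frames of
#' the donor sequence; ungapped high-scoring diagonal blocks with E-value at
#' or below `max_e` are reported in contig order, with nucleotide
#' coordinates (0-based half-open) on the forward strands of both sequences.
#' Overlapping blocks on the same frame pair and diagonal are merged by the
#' seeding step itself.
#'
#' @param contig nucleotide contig (character scalar).
#' @param donor nucleotide donor genome sequence (character scalar).
#' @param max_e maximum Karlin-Altschul E-value (default 1e-10; permissive
#'   in view of the long match lengths expected of genuine transfers).
#' @param k amino-acid seed length (blocks require a shared translated
#'   k-mer; default 7).
#' @return data.frame of class `synteny_blocks`: `q_start`, `q_end`,
#'   `s_start`, `s_end` (nucleotide, 0-based half-open, forward strand),
#'   `q_frame`, `s_frame`, `score`, `identity`, `e_value`.
#' @export
compare_segments <- function(contig, donor, max_e = 1e-10, k = 7) {
  if (nchar(contig) < 3) stop("contig shorter than one codon")
  qf <- translate_six_frames(contig)
  sf <- translate_six_frames(donor)
  qlen <- nchar(contig); slen <- nchar(donor)
  rows <- list()
  for (i in seq_len(nrow(qf))) {
    for (j in seq_len(nrow(sf))) {
      bl <- .diagonal_blocks(qf$aa[i], sf$aa[j], k = k)
      if (is.null(bl) || !nrow(bl)) next
      # aa coordinates -> forward-strand nucleotide coordinates
      conv <- function(aa_start, aa_end, frame, offset, nlen) {
        nt_start <- offset + 3 * (aa_start - 1)       # 0-based
        nt_end <- offset + 3 * aa_end                 # half-open
        if (frame > 0) c(nt_start, nt_end)
        else c(nlen - nt_end, nlen - nt_start)
      }
      for (r in seq_len(nrow(bl))) {
        qc <- conv(bl$q_aa_start[r], bl$q_aa_end[r], qf$frame[i],
                   qf$offset[i], qlen)
        sc <- conv(bl$s_aa_start[r], bl$s_aa_end[r], sf$frame[j],
                   sf$offset[j], slen)
        e <- karlin_altschul_evalue(bl$score[r], nchar(qf$aa[i]),
                                    sum(nchar(sf$aa)), type = "protein")
        if (e > max_e) next
        rows[[length(rows) + 1]] <- data.frame(
          q_start = qc[1], q_end = qc[2], s_start = sc[1], s_end = sc[2],
          q_frame = qf$frame[i], s_frame = sf$frame[j],
          score = bl$score[r], identity = round(bl$identity[r], 2),
          e_value = e)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               q_frame = integer(0), s_frame = integer(0),
               score = numeric(0), identity = numeric(0),
               e_value = numeric(0))
  out <- .merge_blocks(out)
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

# merge blocks of the same orientation on (near-)equal nucleotide diagonals
# with overlapping contig intervals: the same homologous region is found in
# both the forward and the reverse-complement frame pairs
.merge_blocks <- function(b, diag_tol = 2) {
  if (nrow(b) < 2) return(b)
  b$orient <- sign(b$q_frame) * sign(b$s_frame)
  b$diag <- b$s_start - b$q_start
  b <- b[order(b$orient, b$diag, b$q_start), , drop = FALSE]
  keep <- b[1, , drop = FALSE]
  for (i in seq_len(nrow(b))[-1]) {
    j <- nrow(keep)
    same <- b$orient[i] == keep$orient[j] &&
      abs(b$diag[i] - keep$diag[j]) <= diag_tol &&
      b$q_start[i] <= keep$q_end[j]
    if (same) {
      if (b$q_end[i] > keep$q_end[j]) {
        keep$q_end[j] <- b$q_end[i]
        keep$s_end[j] <- max(keep$s_end[j], b$s_end[i])
      }
      keep$q_start[j] <- min(keep$q_start[j], b$q_start[i])
      keep$s_start[j] <- min(keep$s_start[j], b$s_start[i])
      keep$score[j] <- max(keep$score[j], b$score[i])
      keep$e_value[j] <- min(keep$e_value[j], b$e_value[i])
      keep$identity[j] <- max(keep$identity[j], b$identity[i])
    } else {
      keep <- rbind(keep, b[i, ])
    }
  }
  keep$orient <- NULL
  keep$diag <- NULL
  keep
}

# fraction of [start, end) covered by blocks' s-intervals
.block_coverage <- function(blocks, start, end) {
  if (!nrow(blocks) || end <= start) return(0)
  cov <- rep(FALSE, end - start)
  for (r in seq_len(nrow(blocks))) {
    lo <- max(blocks$s_start[r], start)
    hi <- min(blocks$s_end[r], end)
    if (hi > lo) cov[(lo - start + 1):(hi - start)] <- TRUE
  }
  mean(cov)
}

#' Summarise a transfer segment against the donor annotation
#'
#' A donor gene counts as co-transferred when at least `min_gene_cov` of its
#' length is covered by synteny blocks; intergenic donor intervals between
#' consecutive co-transferred genes with block coverage below
#' `max_intergenic_cov` are reported as missing from the recipient (the
#' lost-spacer signature of transfer via mature transcripts).
#'
#' @param blocks a `synteny_blocks` data.frame for one contig/donor pair.
#' @param donor_ann donor annotation data.frame (0-based half-open
#'   `start`/`end`, `gene`).
#' @param min_gene_cov co-transfer coverage threshold (default 0.5).
#' @param max_intergenic_cov conservation threshold below which an
#'   intergenic interval counts as missing (default 0.2).
#' @return list of class `transfer_segment_report`: `co_transferred`
#'   (gene names), `missing_intergenic` (data.frame `start`/`end` on the
#'   donor), `total_span` (bp spanned on the contig), `blocks`.
#' @export
summarize_transfer <- function(blocks, donor_ann, min_gene_cov = 0.5,
                               max_intergenic_cov = 0.2) {
  if (!nrow(blocks)) {
    res <- list(co_transferred = character(0),
                missing_intergenic = data.frame(start = integer(0),
                                                end = integer(0)),
                total_span = 0L, blocks = blocks)
    class(res) <- "transfer_segment_report"
    return(res)
  }
  ann <- donor_ann[order(donor_ann$start), , drop = FALSE]
  cov <- vapply(seq_len(nrow(ann)), function(i)
    .block_coverage(blocks, ann$start[i], ann$end[i]), numeric(1))
  co <- ann[cov >= min_gene_cov, , drop = FALSE]
  missing <- data.frame(start = integer(0), end = integer(0))
  if (nrow(co) >= 2) {
    for (i in seq_len(nrow(co) - 1)) {
      lo <- co$end[i]; hi <- co$start[i + 1]
      if (hi <= lo) next
      if (.block_coverage(blocks, lo, hi) < max_intergenic_cov)
        missing <- rbind(missing, data.frame(start = lo, end = hi))
    }
  }
  res <- list(co_transferred = co$gene,
              missing_intergenic = missing,
              total_span = max(blocks$q_end) - min(blocks$q_start),
              blocks = blocks)
  class(res) <- "transfer_segment_report"
  res
}

#' @export
print.transfer_segment_report <- function(x, ...) {
  cat(sprintf(
    "transfer segment: %d block(s), span %d bp, %d co-transferred gene(s)\n",
    nrow(x$blocks), x$total_span, length(x$co_transferred)))
  if (length(x$co_transferred))
    cat("  genes:", paste(x$co_transferred, collapse = ", "), "\n")
  if (nrow(x$missing_intergenic))
    cat(sprintf("  missing intergenic: %s\n",
                paste(sprintf("[%d,%d)", x$missing_intergenic$start,
                              x$missing_intergenic$end), collapse = " ")))
  invisible(x)
}

#' Detect introns by spliced comparison of a transcript to a contig
#'
#' Chains co-linear maximal exact matches (seeded by `min_exon`-mers) of the
#' transcript against the contig; genomic gaps of at least `min_intron`
#' between consecutive chained exons with zero transcript gap are introns.
#' Boundary dinucleotides are reported with a canonical GT..AG flag.
#'
#' @param transcript transcript sequence (character scalar).
#' @param contig genomic contig containing the gene.
#' @param min_intron minimum intron length (default 30; smaller genomic
#'   gaps are treated as alignment gaps, not introns).
#' @param min_exon minimum exact exon seed length (default 20).
#' @param min_chain_cov minimum fraction of the transcript that must be
#'   covered by the exon chain.
#' @return data.frame of class `intron_calls`: `start`, `end` (0-based
#'   half-open on the contig), `length`, `donor_site`, `acceptor_site`,
#'   `canonical`.
#' @export
detect_introns <- function(transcript, contig, min_intron = 30,
                           min_exon = 20, min_chain_cov = 0.8) {
  tn <- nchar(transcript); cn <- nchar(contig)
  if (tn < min_exon) stop("transcript shorter than one exon seed")
  tpos <- 1L       # 1-based transcript cursor
  gcursor <- 0L    # genomic position after the previous exon (1-based end)
  exons <- list()  # per exon: t_start, t_end, g_start, g_end (1-based incl.)
  subj <- Biostrings::DNAString(contig)
  while (tpos + min_exon - 1L <= tn) {
    seedstr <- substr(transcript, tpos, tpos + min_exon - 1L)
    m <- Biostrings::matchPattern(seedstr, subj)
    starts <- Biostrings::start(m)
    starts <- starts[starts > gcursor]
    if (!length(starts)) break
    g <- starts[1]
    # extend the exact match rightwards
    len <- min_exon
    while (tpos + len <= tn && g + len <= cn &&
           substr(transcript, tpos + len, tpos + len) ==
           substr(contig, g + len, g + len))
      len <- len + 1L
    exons[[length(exons) + 1]] <- c(t_start = tpos, t_end = tpos + len - 1L,
                                    g_start = g, g_end = g + len - 1L)
    tpos <- tpos + len
    gcursor <- g + len - 1L
  }
  if (!length(exons)) stop("transcript not mappable to contig")
  ex <- as.data.frame(do.call(rbind, exons))
  covered <- sum(ex$t_end - ex$t_start + 1)
  if (covered < min_chain_cov * tn)
    stop(sprintf("transcript not mappable: chain covers %.0f%% < %.0f%%",
                 100 * covered / tn, 100 * min_chain_cov))
  calls <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), donor_site = character(0),
                      acceptor_site = character(0), canonical = logical(0))
  if (nrow(ex) >= 2) {
    for (i in seq_len(nrow(ex) - 1)) {
      tgap <- ex$t_start[i + 1] - ex$t_end[i] - 1L
      ggap <- ex$g_start[i + 1] - ex$g_end[i] - 1L
      if (tgap == 0L && ggap >= min_intron) {
        s0 <- ex$g_end[i]           # 0-based intron start
        e0 <- ex$g_start[i + 1] - 1L  # half-open end
        don <- substr(contig, s0 + 1, s0 + 2)
        acc <- substr(contig, e0 - 1, e0)
        calls <- rbind(calls, data.frame(
          start = s0, end = e0, length = e0 - s0,
          donor_site = don, acceptor_site = acc,
          canonical = don == "GT" && acc == "AG",
          stringsAsFactors = FALSE))
      }
    }
  }
  class(calls) <- c("intron_calls", "data.frame")
  calls
}

#' Predict operons from an annotation by the same-strand/gap heuristic
#'
#' Maximal runs of same-strand genes on one sequence whose successive
#' intergenic gaps are at most `max_gap` bp, of at least `min_genes` genes.
#' This is a stand-in heuristic for a curated prokaryotic operon database,
#' not a reimplementation of one.
#'
#' @param ann annotation data.frame (0-based half-open, one sequence).
#' @param max_gap maximum intergenic gap within an operon (default 200).
#' @param min_genes minimum operon size (default 2).
#' @return list of data.frames, one per predicted operon (ordered genes).
#' @export
predict_operons <- function(ann, max_gap = 200, min_genes = 2) {
  if (!nrow(ann)) return(list())
  stopifnot(length(unique(ann$seq_id)) == 1)
  ann <- ann[order(ann$start), , drop = FALSE]
  runs <- list()
  cur <- ann[1, , drop = FALSE]
  for (i in seq_len(nrow(ann))[-1]) {
    gap <- ann$start[i] - cur$end[nrow(cur)]
    if (ann$strand[i] == cur$strand[1] && gap <= max_gap) {
      cur <- rbind(cur, ann[i, ])
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- ann[i, , drop = FALSE]
    }
  }
  runs[[length(runs) + 1]] <- cur
  Filter(function(r) nrow(r) >= min_genes, runs)
}
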