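# Planting transfer structures into genomic contigs.  Two structures are
# emitted: a single-gene transfer whose copy in the recipient contig has
# GT..AG introns inserted at recorded positions, and a multi-gene donor
# segment whose intergenic spacers are deleted in the recipient (emulating
# transfer of mature transcripts: coding sequence conserved, non-coding DNA
# lost).  The donor genome carries the same genes WITH spacers plus a GFF3
# annotation.  Host-derived flanking sequence surrounds every insert.

# draw intron insertion points in a transcript of length n such that exons
# stay >= min_exon and left-extension of an exon cannot run into the intron
# (transcript base after the cut must differ from the intron's leading "G")
.intron_positions <- function(transcript, k, min_exon = 20) {
  n <- nchar(transcript)
  if (n < (k + 1) * (min_exon + 5)) stop("transcript too short for introns")
  ok <- FALSE
  for (try in 1:200) {
    pos <- sort(sample(seq(min_exon + 1, n - min_exon), k))
    if (k > 1 && any(diff(pos) < min_exon + 5)) next
    if (any(substring(transcript, pos, pos) == "G")) next
    ok <- TRUE
    break
  }
  if (!ok) stop("could not place introns without splice ambiguity")
  pos  # intron inserted BEFORE transcript position pos (1-based)
}

.make_intron <- function(len) {
  stopifnot(len >= 4)
  paste0("GT", if (len > 4) .random_dna(len - 4) else "", "AG")
}

#' Plant transfer structures into contigs with a matching donor genome
#'
#' @param config a [simulation_config()]; uses `intron_lengths`, `seed`.
#' @param single_gene nucleotide CDS of the single-gene transfer (default: a
#'   fresh random CDS of 60 codons plus enough length for the introns).
#' @param segment_genes named character vector of >= 2 nucleotide CDS for
#'   the multi-gene segment (default: three random genes of 150, 120 and
#'   180 codons).
#' @param flank_len host flanking sequence on each side of every insert.
#' @param spacer_range intergenic spacer lengths in the donor genome.
#' @return list with `contigs` (named character: `ctg_single`, `ctg_multi`),
#'   `transcripts` (the intron-free single-gene transcript), `donor_seq`
#'   (named character, one donor chromosome), `donor_ann` (annotation
#'   data.frame, 0-based half-open) and `truth` (list: `introns` data.frame
#'   with contig coordinates, `co_transferred` gene names, `spacers`
#'   data.frame of deleted donor intervals, `gene_positions` on the contig).
#' @export
plant_contig <- function(config, single_gene = NULL, segment_genes = NULL,
                         flank_len = 500, spacer_range = c(150, 400)) {
  stopifnot(inherits(config, "simulation_config"))
  with_substream(config$seed, .SUBSTREAM[["contigs"]], {
    if (is.null(single_gene))
      single_gene <- .random_cds(60 + 20 * length(config$intron_lengths))
    if (is.null(segment_genes))
      segment_genes <- stats::setNames(
        c(.random_cds(150), .random_cds(120), .random_cds(180)),
        c("donor_gene1", "donor_gene2", "donor_gene3"))
    stopifnot(length(segment_genes) >= 2)

    # --- single-gene transfer with introns -------------------------------
    ilens <- config$intron_lengths
    tr <- single_gene
    introns <- data.frame(transcript_pos = integer(0), start = integer(0),
                          end = integer(0), length = integer(0))
    flankL <- .random_dna(flank_len); flankR <- .random_dna(flank_len)
    if (length(ilens)) {
      pos <- .intron_positions(tr, length(ilens))
      genomic <- ""
      prev <- 1L
      cursor <- flank_len  # 0-based position in contig where gene starts
      for (i in seq_along(ilens)) {
        exon <- substr(tr, prev, pos[i] - 1L)
        genomic <- paste0(genomic, exon)
        istart <- cursor + nchar(genomic)            # 0-based
        genomic <- paste0(genomic, .make_intron(ilens[i]))
        introns <- rbind(introns, data.frame(
          transcript_pos = pos[i], start = istart,
          end = istart + ilens[i], length = ilens[i]))
        prev <- pos[i]
      }
      genomic <- paste0(genomic, substr(tr, prev, nchar(tr)))
    } else {
      genomic <- tr
    }
    ctg_single <- paste0(flankL, genomic, flankR)

    # --- multi-gene segment, spacers deleted in the recipient ------------
    spacers <- vapply(seq_len(length(segment_genes) - 1), function(i)
      .random_dna(round(stats::runif(1, spacer_range[1], spacer_range[2]))),
      character(1))
    donor_flank <- .random_dna(flank_len)
    donor_parts <- character(0)
    donor_ann <- data.frame()
    pos0 <- flank_len
    for (i in seq_along(segment_genes)) {
      donor_ann <- rbind(donor_ann, data.frame(
        seq_id = "donor_chr1", start = pos0,
        end = pos0 + nchar(segment_genes[i]), strand = "+",
        gene = names(segment_genes)[i], stringsAsFactors = FALSE))
      donor_parts <- c(donor_parts, segment_genes[i])
      pos0 <- pos0 + nchar(segment_genes[i])
      if (i < length(segment_genes)) {
        donor_parts <- c(donor_parts, spacers[i])
        pos0 <- pos0 + nchar(spacers[i])
      }
    }
    donor_seq <- paste0(donor_flank, paste(donor_parts, collapse = ""),
                        .random_dna(flank_len))
    spacer_truth <- data.frame(
      start = donor_ann$end[-nrow(donor_ann)],
      end = donor_ann$start[-1])
    hostL <- .random_dna(flank_len); hostR <- .random_dna(flank_len)
    ctg_multi <- paste0(hostL, paste(segment_genes, collapse = ""), hostR)
    gene_positions <- data.frame(
      gene = names(segment_genes),
      start = flank_len + c(0, cumsum(nchar(segment_genes)))[
        seq_along(segment_genes)],
      stringsAsFactors = FALSE)
    gene_positions$end <- gene_positions$start + nchar(segment_genes)

    list(
      contigs = c(ctg_single = ctg_single, ctg_multi = ctg_multi),
      transcripts = c(transcript_single = tr),
      donor_seq = c(donor_chr1 = donor_seq),
      donor_ann = donor_ann,
      truth = list(introns = introns,
                   co_transferred = names(segment_genes),
                   spacers = spacer_truth,
                   gene_positions = gene_positions)
    )
  })
}

# random in-frame CDS of n codons without stops
.random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, TRUE), collapse = "")
}
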