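# Translated homology search against a taxonomy-labelled reference protein
# set: a stand-in for BLASTx against a local database, reproducible without
# an external binary.  Candidate (segment, reference) pairs are pre-screened
# by shared amino-acid 4-mers (at least `min_shared` distinct ones, in any
# reading frame), then scored with an affine-gap Smith-Waterman on BLOSUM62
# (gap open 11 / extend 1) taking the best of the six frames; E-values use
# fixed Karlin-Altschul parameters with the total reference residue count
# as database size.

#' Derive a hit table from segments and reference proteins
#'
#' @param segments named character vector of nucleotide query segments.
#' @param reference named character vector of amino-acid reference proteins;
#'   names follow the `species|protein` convention.
#' @param taxmap data.frame with `species` and `taxon_group`.
#' @param max_report_e report hits with E-value at or below this (default
#'   1e-3; the filter cascade applies its own, stricter, threshold).
#' @param seed_k amino-acid k-mer size of the candidate pre-screen.
#' @param min_shared minimum distinct shared k-mers (per frame) for a
#'   reference to be aligned.
#' @return data.frame of hits sorted by query then ascending E-value, with
#'   BLAST outfmt-6 columns plus `species_id` and `taxon_group`.
#' @export
derive_hit_table <- function(segments, reference, taxmap,
                             max_report_e = 1e-3, seed_k = 4,
                             min_shared = 2) {
  stopifnot(length(reference) >= 1)
  db_size <- sum(nchar(reference))
  species <- sub("\\|.*$", "", names(reference))
  group <- taxmap$taxon_group[match(species, taxmap$species)]
  if (anyNA(group)) stop("reference species missing from taxonomy map")

  # k-mer -> reference index lookup
  ref_kmers <- lapply(reference, function(s) unique(.kmers(s, seed_k)))
  idx <- split(rep(seq_along(reference), lengths(ref_kmers)),
               unlist(ref_kmers))

  rows <- vector("list", length(segments))
  for (qi in seq_along(segments)) {
    q <- segments[[qi]]
    qid <- names(segments)[qi]
    if (nchar(q) < 3) {
      warning("segment ", qid, " shorter than one codon: skipped")
      next
    }
    frames <- translate_six_frames(q)
    qlen <- nchar(q)
    # one vectorised alignment call per frame (references as pattern set)
    frame_hits <- list()
    for (f in seq_len(nrow(frames))) {
      aa <- frames$aa[f]
      shared <- unlist(idx[unique(.kmers(aa, seed_k))], use.names = FALSE)
      if (!length(shared)) next
      counts <- tabulate(shared, nbins = length(reference))
      cand <- which(counts >= min_shared)
      if (!length(cand)) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(unname(reference[cand])),
        Biostrings::AAString(aa), type = "local",
        substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
      ind <- Biostrings::nindel(aln)
      frame_hits[[f]] <- data.frame(
        ref = cand,
        score = Biostrings::score(aln),
        matches = Biostrings::nmatch(aln),
        mismatch = Biostrings::nmismatch(aln),
        aln_length = Biostrings::nchar(aln),
        gapopen = Biostrings::insertion(ind)[, 1] +
          Biostrings::deletion(ind)[, 1],
        q_aa_start = Biostrings::start(Biostrings::subject(aln)),
        q_aa_end = Biostrings::end(Biostrings::subject(aln)),
        sstart = Biostrings::start(Biostrings::pattern(aln)),
        send = Biostrings::end(Biostrings::pattern(aln)),
        frame = frames$frame[f], offset = frames$offset[f],
        m = nchar(aa))
    }
    fh <- do.call(rbind, frame_hits)
    if (is.null(fh) || !nrow(fh)) next
    # best frame per reference
    fh <- fh[order(fh$ref, -fh$score), , drop = FALSE]
    fh <- fh[!duplicated(fh$ref), , drop = FALSE]
    fh$e_value <- karlin_altschul_evalue(fh$score, fh$m, db_size,
                                         type = "protein")
    fh <- fh[fh$e_value <= max_report_e, , drop = FALSE]
    if (!nrow(fh)) next
    # map amino-acid query coordinates back to the forward strand
    fwd <- fh$frame > 0
    qs <- ifelse(fwd, fh$offset + 3 * (fh$q_aa_start - 1) + 1,
                 qlen - (fh$offset + 3 * fh$q_aa_end) + 1)
    qe <- ifelse(fwd, fh$offset + 3 * fh$q_aa_end,
                 qlen - (fh$offset + 3 * (fh$q_aa_start - 1)))
    recs <- data.frame(
      query_id = qid, subject_id = names(reference)[fh$ref],
      species_id = species[fh$ref], taxon_group = group[fh$ref],
      percent_identity = round(100 * fh$matches / fh$aln_length, 2),
      overlap = fh$aln_length, mismatch = fh$mismatch,
      gapopen = fh$gapopen, qstart = qs, qend = qe,
      sstart = fh$sstart, send = fh$send,
      e_value = fh$e_value, bitscore = round(bit_score(fh$score), 1),
      stringsAsFactors = FALSE)
    rows[[qi]] <- recs[order(recs$e_value), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      species_id = character(0), taxon_group = character(0),
                      percent_identity = numeric(0), overlap = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      e_value = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
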