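# Local alignment stack shared by the hit-table generator, the contig mapper
# and the six-frame segment comparison.  Dynamic programming is delegated to
# Biostrings::pairwiseAlignment; significance uses fixed Karlin-Altschul
# parameters so no external BLAST binary is needed.  The protein constants
# (lambda = 0.267, K = 0.041) are the published gapped values for BLOSUM62
# with gap open 11 / extend 1; the nucleotide constants (lambda = 1.28,
# K = 0.46) are the standard ungapped values for match +1 / mismatch -2,
# reused for the lightly-gapped mapper.

.KA_PROTEIN <- c(lambda = 0.267, K = 0.041)
.KA_NUCLEOTIDE <- c(lambda = 1.28, K = 0.46)

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' E = K * m * n * exp(-lambda * S), with m the query length and n the
#' database length in residues.
#'
#' @param score raw alignment score.
#' @param m query length.
#' @param n database (total subject) length.
#' @param type "protein" or "nucleotide" parameter set.
#' @return expected number of chance alignments at or above `score`.
#' @export
karlin_altschul_evalue <- function(score, m, n, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  p <- if (type == "protein") .KA_PROTEIN else .KA_NUCLEOTIDE
  unname(p["K"] * m * n * exp(-p["lambda"] * score))
}

#' Bit score from a raw score under the same parameter set
#' @inheritParams karlin_altschul_evalue
#' @export
bit_score <- function(score, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  p <- if (type == "protein") .KA_PROTEIN else .KA_NUCLEOTIDE
  unname((p["lambda"] * score - log(p["K"])) / log(2))
}

.align_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  # shipped with Biostrings; cached after first load
  if (is.null(.align_cache$BLOSUM62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$BLOSUM62 <- get("BLOSUM62", envir = e)
  }
  .align_cache$BLOSUM62
}

.dna_submat <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

#' Affine-gap Smith-Waterman local alignment of two sequences
#'
#' Protein scoring: BLOSUM62, gap open 11 / extend 1 (a gap of length k
#' costs 11 + k).  Nucleotide scoring: match +1, mismatch -2, gap open 5 /
#' extend 2.
#'
#' @param query,subject character scalars.
#' @param type "protein" or "nucleotide".
#' @return list with `score`, `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive on the input strings), `matches`, `aln_length`, `gapopen`.
#' @export
local_align <- function(query, subject, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (type == "protein") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subject),
      type = "local", substitutionMatrix = .blosum62(),
      gapOpening = 11, gapExtension = 1)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = .dna_submat(),
      gapOpening = 5, gapExtension = 2)
  }
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  pv <- strsplit(pat, "")[[1]]
  sv <- strsplit(sub, "")[[1]]
  gapopen <- function(x) sum(x == "-" & c("x", x[-length(x)]) != "-")
  list(
    score = Biostrings::score(aln),
    qstart = Biostrings::start(Biostrings::pattern(aln)),
    qend = Biostrings::end(Biostrings::pattern(aln)),
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)),
    matches = sum(pv == sv & pv != "-"),
    mismatches = sum(pv != sv & pv != "-" & sv != "-"),
    aln_length = length(pv),
    gapopen = gapopen(pv) + gapopen(sv)
  )
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' @param seq nucleotide string.
#' @return data.frame with columns `frame` (1..3 forward, -1..-3 reverse),
#'   `offset` (0-based nucleotide offset of the frame on the forward strand
#'   for + frames, on the reverse complement for - frames) and `aa`.
#' @export
translate_six_frames <- function(seq) {
  fwd <- toupper(seq)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  one <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3
    if (n < 3) return(NA_character_)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, off + 1, off + n)),
      if.fuzzy.codon = "X"))
  }
  out <- data.frame(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    offset = c(0L, 1L, 2L, 0L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  out$aa <- c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
              one(rev, 0), one(rev, 1), one(rev, 2))
  out[!is.na(out$aa), , drop = FALSE]
}

# all overlapping k-mers of a string (character scalar -> character vector)
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}
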