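# File-format plumbing.  Sequences travel through the package as named
# character vectors; Biostrings does the FASTA/FASTQ serialisation and
# rtracklayer the GFF3 round trip.  Annotations use 0-based half-open
# coordinates internally and are converted to 1-based inclusive on GFF3 I/O.

#' Read a FASTA file as a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector (DNA or protein).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read FASTQ reads (qualities discarded)
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with uniform qualities
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write gene annotations to GFF3
#'
#' @param ann data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `gene`.
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(all(c("seq_id", "start", "end", "strand", "gene") %in% names(ann)))
  stopifnot(all(ann$start < ann$end), all(ann$strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seq_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- ann$gene
  S4Vectors::mcols(gr)$Name <- ann$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#' @param path GFF3 file.
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  nm <- S4Vectors::mcols(gr)$ID
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$Name
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = as.character(nm),
    stringsAsFactors = FALSE
  )
}

.HIT_COLS <- c("query_id", "subject_id", "percent_identity", "overlap",
               "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
               "e_value", "bitscore")

#' Write a hit table in 12-column BLAST tabular (outfmt 6) dialect
#' @param hits hit data.frame (see [derive_hit_table()]).
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column BLAST tabular file with a species-to-group taxonomy map
#'
#' Subject ids are expected in the `species|protein` convention; the species
#' component is looked up in the two-column map (species, taxon_group).
#'
#' @param path BLAST tabular file.
#' @param taxmap data.frame with columns `species`, `taxon_group`, or a path
#'   to a two-column TSV.
#' @return hit data.frame including `species_id` and `taxon_group`.
#' @export
read_hit_table <- function(path, taxmap) {
  h <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = .HIT_COLS)
  if (is.character(taxmap)) taxmap <- read_taxmap(taxmap)
  h$species_id <- sub("\\|.*$", "", h$subject_id)
  h$taxon_group <- taxmap$taxon_group[match(h$species_id, taxmap$species)]
  if (anyNA(h$taxon_group))
    stop("species missing from taxonomy map: ",
         paste(unique(h$species_id[is.na(h$taxon_group)]), collapse = ", "))
  h
}

#' Read a two-column species-to-taxon-group TSV
#' @param path TSV path (columns: species, taxon_group; no header).
#' @export
read_taxmap <- function(path) {
  utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("species", "taxon_group"))
}

#' Write a species-to-taxon-group TSV
#' @param taxmap data.frame with `species` and `taxon_group`.
#' @param path output path.
#' @export
write_taxmap <- function(taxmap, path) {
  utils::write.table(taxmap[, c("species", "taxon_group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV (stages in header, L column for CDS length)
#' @param path TSV path.
#' @return list with `counts` (genes x stages integer matrix), `lengths`
#'   (per-gene CDS bp) and `lib_sizes` (per-stage totals).
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  stopifnot("L" %in% colnames(d))
  L <- d[["L"]]
  cm <- as.matrix(d[, setdiff(colnames(d), "L"), drop = FALSE])
  storage.mode(cm) <- "integer"
  count_matrix(cm, lengths = L)
}

#' Write a count matrix TSV
#' @param cm a `count_matrix` object.
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  d <- data.frame(gene = rownames(cm$counts), cm$counts, L = cm$lengths,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
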