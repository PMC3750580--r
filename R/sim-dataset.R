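# Assembly of a complete synthetic dataset with ground truth: gene families
# and a hit table for the filter cascade, contigs and reads for genome
# verification, structural contigs with planted introns and a spacer-deleted
# multi-gene segment, ortholog pairs with known dN/dS, and stage-wise
# counts with planted differential expression.  Everything derives from one
# seed; writing the dataset twice gives byte-identical files.

#' Generate a complete synthetic dataset
#'
#' @param config a [simulation_config()].
#' @param n_host_contigs background (host-only) contigs for the coverage
#'   test.
#' @param host_contig_len length range of background contigs (bp).
#' @param flank_len host flanking sequence around each planted gene.
#' @param n_pairs_per_omega simulated ortholog pairs per omega target.
#' @return list of class `synthetic_dataset` with elements `config`,
#'   `families`, `segments`, `hits`, `taxmap`, `contigs`, `mito`,
#'   `structural` (the [plant_contig()] output), `reads`,
#'   `ortholog_pairs`, `counts` and `truth`.
#' @export
synthetic_dataset <- function(config = simulation_config(),
                              n_host_contigs = 30,
                              host_contig_len = c(3000, 5000),
                              flank_len = 500,
                              n_pairs_per_omega = 3) {
  fam <- simulate_gene_families(config)
  hits <- derive_hit_table(fam$segments, fam$reference, fam$taxmap)
  structural <- plant_contig(config)

  hgt_ids <- fam$truth$segment_id[fam$truth$is_hgt]
  contigs <- with_substream(config$seed, .SUBSTREAM[["demo"]], {
    ctg <- vapply(hgt_ids, function(id)
      paste0(.random_dna(flank_len), fam$segments[[id]],
             .random_dna(flank_len)), character(1))
    names(ctg) <- paste0("ctg_", hgt_ids)
    host <- vapply(seq_len(n_host_contigs), function(i)
      .random_dna(round(stats::runif(1, host_contig_len[1],
                                     host_contig_len[2]))), character(1))
    names(host) <- sprintf("ctg_host%03d", seq_len(n_host_contigs))
    c(ctg, host)
  })
  contigs <- c(contigs, structural$contigs)
  mito <- with_substream(config$seed, .SUBSTREAM[["demo"]] + 1L,
                         .random_dna(2000))

  reads <- simulate_reads(contigs, depth = config$read_depth,
                          read_length = config$read_length,
                          seed = config$seed)

  orth <- simulate_ortholog_pairs(config$omega_targets, config$t_codon,
                                  n_codons = config$n_codons,
                                  n_pairs = n_pairs_per_omega,
                                  seed = config$seed)

  genes <- fam$truth$segment_id
  cm <- simulate_counts(genes, mean = config$count_model$mean,
                        de_genes = hgt_ids,
                        fold = config$count_model$fold,
                        de_stages = config$count_model$de_stages,
                        n_stages = config$count_model$n_stages,
                        lengths = nchar(fam$segments[genes]),
                        seed = config$seed)

  orphans <- with_substream(config$seed, .SUBSTREAM[["demo"]] + 2L, {
    if (config$n_orphans > 0) {
      o <- vapply(seq_len(config$n_orphans), function(i)
        .random_dna(3 * config$protein_length), character(1))
      names(o) <- sprintf("seg_orphan%02d", seq_len(config$n_orphans))
      o
    } else character(0)
  })

  structure(list(
    config = config,
    families = fam,
    segments = c(fam$segments, orphans),
    hits = hits,
    taxmap = fam$taxmap,
    contigs = contigs,
    mito = mito,
    structural = structural,
    reads = reads,
    ortholog_pairs = orth,
    counts = cm$counts,
    truth = list(
      hgt_segments = hgt_ids,
      donor_groups = stats::setNames(
        fam$truth$donor_group[fam$truth$is_hgt], hgt_ids),
      host_segments = fam$truth$segment_id[!fam$truth$is_hgt],
      orphan_segments = names(orphans),
      segment_contig = stats::setNames(paste0("ctg_", hgt_ids), hgt_ids),
      introns = structural$truth$introns,
      co_transferred = structural$truth$co_transferred,
      spacers = structural$truth$spacers,
      omega = orth$truth,
      de_genes = cm$truth
    )
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset (seed %d): %d segments (%d planted HGT), %d contigs, %d reads\n",
    x$config$seed, length(x$segments), length(x$truth$hgt_segments),
    length(x$contigs), length(x$reads)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits segments/contigs/donor/pair FASTA, reads FASTQ, a GFF3 donor
#' annotation, a 12-column BLAST tabular hit table with taxonomy map, a
#' count TSV, per-family aligned FASTA and true newick trees, and the truth
#' tables as plain TSV/key-value text.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(ds$segments, p("segments.fasta"))
  write_hit_table(ds$hits, p("hits.tsv"))
  write_taxmap(ds$taxmap, p("taxmap.tsv"))
  write_fasta(ds$contigs, p("contigs.fasta"))
  write_fasta(c(mitochondrion = ds$mito), p("mito.fasta"))
  write_fasta(ds$structural$donor_seq, p("donor_genome.fasta"))
  write_gff3(ds$structural$donor_ann, p("donor_genome.gff3"))
  write_fasta(ds$structural$transcripts, p("transcripts.fasta"))
  write_fastq(ds$reads, p("reads.fastq"))
  write_fasta(ds$ortholog_pairs$pairs, p("ortholog_pairs.fasta"))
  write_count_matrix(ds$counts, p("counts.tsv"))
  dir.create(p("alignments"), showWarnings = FALSE)
  for (f in names(ds$families$alignments)) {
    write_fasta(ds$families$alignments[[f]],
                p("alignments", paste0(f, ".fasta")))
    ape::write.tree(ds$families$trees[[f]],
                    p("alignments", paste0(f, ".nwk")))
  }
  tdir <- p("truth")
  dir.create(tdir, showWarnings = FALSE)
  writeLines(c(
    paste0("seed\t", ds$config$seed),
    paste0("hgt_segments\t", paste(ds$truth$hgt_segments, collapse = ",")),
    paste0("orphan_segments\t",
           paste(ds$truth$orphan_segments, collapse = ",")),
    paste0("co_transferred\t", paste(ds$truth$co_transferred, collapse = ",")),
    paste0("de_genes\t", paste(ds$truth$de_genes, collapse = ","))
  ), file.path(tdir, "truth.txt"))
  utils::write.table(ds$truth$introns, file.path(tdir, "introns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$spacers, file.path(tdir, "spacers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$omega, file.path(tdir, "omega.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
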