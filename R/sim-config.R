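# Configuration for the synthetic-data generator.  Defaults describe a
# small but realistic world: a few dozen recipient ("host") gene families,
# a handful of planted transfers from bacterial and fungal donors (the 5:2
# split echoes the dominant-bacterial donor mix at reduced scale), taxa
# sampled from four groups deep enough (0.5 substitutions/site between
# domains) for clean donor-clade nesting, ~40x read coverage, and planted
# introns including the 105/117 bp pair used throughout the tests.

#' Build a simulation configuration
#'
#' @param seed master integer seed; every stochastic operation derives its
#'   substream from it by a fixed offset, so a fixed seed gives
#'   byte-identical datasets.
#' @param n_host_genes number of vertically inherited gene families.
#' @param n_planted_hgt named integer vector: planted transfers per donor
#'   group.
#' @param taxon_counts named integer vector: reference species per taxon
#'   group (arthropod, other_eukaryote, fungi, bacteria).
#' @param tree_depth between-domain backbone depth in expected
#'   substitutions/site.
#' @param protein_length family protein length (aa).
#' @param n_orphans segments generated without any reference homolog.
#' @param intron_lengths intron lengths (bp, each >= 4) planted in the
#'   single-gene transfer contig.
#' @param read_depth mean fold coverage of simulated reads.
#' @param read_length read length (bp).
#' @param count_model list: `mean` (per-gene expected count), `fold`
#'   (planted fold change), `de_stages` (stage indices carrying the fold),
#'   `n_stages`.
#' @param omega_targets dN/dS values for simulated ortholog pairs.
#' @param t_codon nucleotide divergence (proposed substitutions/site) of
#'   ortholog pairs.
#' @param n_codons codons per simulated ortholog pair.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_host_genes = 50,
                              n_planted_hgt = c(bacteria = 5, fungi = 2),
                              taxon_counts = c(arthropod = 5,
                                               other_eukaryote = 4,
                                               fungi = 5,
                                               bacteria = 8),
                              tree_depth = 0.5,
                              protein_length = 200,
                              n_orphans = 5,
                              intron_lengths = c(105, 117),
                              read_depth = 40,
                              read_length = 100,
                              count_model = list(mean = 500, fold = 8,
                                                 de_stages = c(3, 4),
                                                 n_stages = 5),
                              omega_targets = c(0.1, 0.5, 1.0),
                              t_codon = 0.3,
                              n_codons = 300) {
  stopifnot(n_host_genes >= 0, all(n_planted_hgt >= 0),
            all(taxon_counts >= 0), tree_depth >= 0,
            protein_length >= 10, read_depth > 0, read_length > 0,
            all(omega_targets > 0) || length(omega_targets) == 0,
            t_codon >= 0, n_codons >= 30)
  if (length(intron_lengths) && any(intron_lengths < 4))
    stop("intron lengths must be >= 4 (room for GT..AG)")
  if (is.null(names(n_planted_hgt)) || !is.null(names(n_planted_hgt)) &&
      !all(names(n_planted_hgt) %in% names(taxon_counts)))
    stop("n_planted_hgt must be named by donor groups present in taxon_counts")
  miss <- names(n_planted_hgt)[n_planted_hgt > 0 &
                                 taxon_counts[names(n_planted_hgt)] == 0]
  if (length(miss))
    stop("zero taxa in required donor group(s): ", paste(miss, collapse = ", "))
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config(seed=%d): %d host + %s planted families, depth %.2f\n",
    x$seed, x$n_host_genes,
    paste(sprintf("%d %s", x$n_planted_hgt, names(x$n_planted_hgt)),
          collapse = " + "),
    x$tree_depth))
  invisible(x)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.STAGES <- c("egg", "nauplius", "zoea", "mysis", "postlarva")

# inverse genetic code: amino acid -> codons
.aa_codons <- function() {
  if (is.null(.codon_cache$by_aa)) {
    sc <- sense_codons()
    .codon_cache$by_aa <- split(sc, codon_aa(sc))
  }
  .codon_cache$by_aa
}

# random nucleotide string
.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

# back-translate an amino-acid string with uniformly chosen synonymous codons
.back_translate <- function(aa) {
  tab <- .aa_codons()
  paste(vapply(strsplit(aa, "")[[1]], function(a)
    sample(tab[[a]], 1), character(1)), collapse = "")
}
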