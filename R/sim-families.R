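# Gene-family simulation with known trees and planted transfers.  Each
# family evolves a protein along a four-group species tree (arthropods,
# other eukaryotes, fungi, bacteria joined by a fixed backbone); the
# recipient's gene ("query") is attached sister to the arthropod subtree in
# vertically inherited families and inside the donor-group subtree in
# planted-transfer families.  Evolution is indel-free under a Poisson
# (equal-exchangeability) substitution model, so every family alignment is
# gap-free and column-homologous by construction.

# random binary subtree over labels; children carry branch lengths, the
# subtree root does not (the caller appends a stem length)
.random_subtree_nwk <- function(labels, bl_range = c(0.03, 0.08)) {
  bl <- function() stats::runif(1, bl_range[1], bl_range[2])
  if (length(labels) == 1) return(labels)
  k <- sample(seq_len(length(labels) - 1), 1)
  pick <- sample(labels)
  left <- .random_subtree_nwk(pick[seq_len(k)], bl_range)
  right <- .random_subtree_nwk(pick[-seq_len(k)], bl_range)
  sprintf("(%s:%.6f,%s:%.6f)", left, bl(), right, bl())
}

# family tree newick: backbone ((bacteria,fungi),(other_euk,arthropod)) with
# stem lengths tree_depth/2; query attached per is_hgt/donor_group
.family_tree_nwk <- function(taxon_counts, tree_depth, query_id,
                             is_hgt, donor_group = NULL) {
  d2 <- max(tree_depth / 2, 1e-9)
  groups <- c("bacteria", "fungi", "other_eukaryote", "arthropod")
  groups <- groups[groups %in% names(taxon_counts) &
                     unlist(taxon_counts[groups]) > 0]
  subs <- stats::setNames(lapply(groups, function(g)
    .random_subtree_nwk(paste0(g, "_sp", seq_len(taxon_counts[[g]])))),
    groups)
  if (is_hgt) {
    if (!donor_group %in% groups) stop("zero taxa in donor group")
    # graft the query as a cherry with a random donor leaf; the cherry's
    # stem is kept long enough to be recoverable by bootstrap
    leaf <- sprintf("%s_sp%d", donor_group,
                    sample(taxon_counts[[donor_group]], 1))
    if (length(subs[[donor_group]]) && subs[[donor_group]] == leaf) {
      subs[[donor_group]] <- sprintf("(%s:%.6f,%s:%.6f)", leaf, 0.04,
                                     query_id, 0.04)
    } else {
      pat <- sprintf("%s:([0-9.]+)", leaf)
      m <- regmatches(subs[[donor_group]],
                      regexec(pat, subs[[donor_group]]))[[1]]
      len <- as.numeric(m[2])
      repl <- sprintf("(%s:%.6f,%s:%.6f):%.6f", leaf, 0.4 * len, query_id,
                      0.4 * len, max(0.6 * len, 0.05))
      subs[[donor_group]] <- sub(pat, repl, subs[[donor_group]])
    }
  } else {
    if (!"arthropod" %in% groups)
      stop("vertical families require arthropod taxa")
    subs[["arthropod"]] <- sprintf("(%s:%.6f,%s:%.6f)",
                                   query_id, stats::runif(1, 0.05, 0.1),
                                   subs[["arthropod"]],
                                   stats::runif(1, 0.03, 0.06))
  }
  stems <- vapply(names(subs), function(g)
    sprintf("%s:%.6f", subs[[g]], d2), character(1))
  if (all(c("bacteria", "fungi", "other_eukaryote", "arthropod") %in%
          names(subs))) {
    return(sprintf("((%s,%s):%.6f,(%s,%s):%.6f);",
                   stems[["bacteria"]], stems[["fungi"]], d2,
                   stems[["other_eukaryote"]], stems[["arthropod"]], d2))
  }
  if (length(stems) == 1)
    return(sprintf("(%s);", stems[[1]]))
  joined <- Reduce(function(a, b) sprintf("(%s,%s):%.6f", a, b, d2), stems)
  paste0(sub(":[0-9.]+$", "", joined), ";")
}

# evolve a protein along a tree under the Poisson model:
# per site, substitution probability 1 - exp(-b), new residue uniform
.evolve_protein <- function(tree, root_seq) {
  L <- length(root_seq)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    b <- ord$edge.length[e]
    s <- seqs[[parent]]
    hit <- stats::runif(L) < (1 - exp(-b))
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(a)
        sample(setdiff(.AA20, a), 1), character(1))
    }
    seqs[[child]] <- s
  }
  tips <- vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), character(1))
  stats::setNames(tips, tree$tip.label)
}

#' Simulate gene families with planted horizontal transfers
#'
#' @param config a [simulation_config()].
#' @return list with `alignments` (per family, named character vectors of
#'   aligned amino-acid sequences including the query), `trees` (the true
#'   `phylo` per family), `segments` (query nucleotide CDS, one per
#'   family), `reference` (amino-acid reference proteins named
#'   `species|family`), `taxmap` (species/taxon_group data.frame) and
#'   `truth` (data.frame: family, segment_id, is_hgt, donor_group).
#' @export
simulate_gene_families <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tc <- config$taxon_counts
  if (sum(tc) == 0) stop("no taxa configured")
  with_substream(config$seed, .SUBSTREAM[["families"]], {
    donor_plan <- rep(names(config$n_planted_hgt), config$n_planted_hgt)
    n_fam <- config$n_host_genes + length(donor_plan)
    fams <- sprintf("fam%03d", seq_len(n_fam))
    is_hgt <- c(rep(FALSE, config$n_host_genes),
                rep(TRUE, length(donor_plan)))
    donor <- c(rep(NA_character_, config$n_host_genes), donor_plan)

    alignments <- trees <- vector("list", n_fam)
    names(alignments) <- names(trees) <- fams
    segments <- character(n_fam)
    refs <- list()
    for (i in seq_len(n_fam)) {
      seg_id <- paste0("seg_", fams[i])
      nwk <- .family_tree_nwk(tc, config$tree_depth, seg_id,
                              is_hgt[i], donor[i])
      tree <- ape::read.tree(text = nwk)
      root_seq <- sample(.AA20, config$protein_length, TRUE)
      aln <- .evolve_protein(tree, root_seq)
      alignments[[i]] <- aln
      trees[[i]] <- tree
      segments[i] <- .back_translate(aln[[seg_id]])
      others <- setdiff(names(aln), seg_id)
      refs[[i]] <- stats::setNames(aln[others],
                                   paste0(others, "|", fams[i]))
    }
    names(segments) <- paste0("seg_", fams)
    species <- unlist(lapply(names(tc), function(g)
      if (tc[[g]] > 0) paste0(g, "_sp", seq_len(tc[[g]])) else character(0)))
    taxmap <- data.frame(species = species,
                         taxon_group = sub("_sp[0-9]+$", "", species),
                         stringsAsFactors = FALSE)
    list(alignments = alignments, trees = trees, segments = segments,
         reference = unlist(refs), taxmap = taxmap,
         truth = data.frame(family = fams,
                            segment_id = paste0("seg_", fams),
                            is_hgt = is_hgt, donor_group = donor,
                            stringsAsFactors = FALSE))
  })
}
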