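# End-to-end orchestration.  The stage order mirrors the detection chain:
# homology filter cascade -> phylogenetic nesting classification -> genomic
# verification (contig mapping + coverage bias) -> annotative stages
# (structure, selection, expression) that support but never veto a call.
# Every input segment ends in exactly one terminal bucket of the manifest.

#' Run the full detection pipeline on a synthetic dataset
#'
#' @param ds a [synthetic_dataset()].
#' @param thresholds filter cascade thresholds ([filter_thresholds()]).
#' @param bootstrap_reps bootstrap replicates for candidate trees.
#' @param min_support minimum bootstrap support of the nesting clade.
#' @param min_basal_donor_species minimum basal donor species.
#' @param donor_groups,recipient_groups taxon groups for the classifier.
#' @param contig_max_e,contig_min_identity contig-mapping thresholds.
#' @param n_background background contigs for the coverage test (default:
#'   all non-target contigs).
#' @param alpha significance level of the coverage test.
#' @param seed seed for bootstrap and background sampling (default: the
#'   dataset's own seed).
#' @return list of class `hgt_run`: stage outputs, `final_calls`, and a
#'   `manifest` with the per-stage attrition table and parameter snapshot.
#' @export
run_all <- function(ds,
                    thresholds = filter_thresholds(),
                    bootstrap_reps = 200,
                    min_support = 70,
                    min_basal_donor_species = 3,
                    donor_groups = c("bacteria", "fungi"),
                    recipient_groups = "arthropod",
                    contig_max_e = 1e-40,
                    contig_min_identity = 90,
                    n_background = NULL,
                    alpha = 0.05,
                    seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (is.null(seed)) seed <- ds$config$seed

  # stage 1: homology filter cascade
  report <- run_cascade(names(ds$segments), ds$hits, thresholds)
  candidates <- report$candidates

  # stage 2: trees with bootstrap + nesting classification
  groups <- stats::setNames(ds$taxmap$taxon_group, ds$taxmap$species)
  fam_of <- stats::setNames(ds$families$truth$family,
                            ds$families$truth$segment_id)
  calls <- list()
  for (id in candidates) {
    aln <- ds$families$alignments[[fam_of[[id]]]]
    if (is.null(aln)) {
      calls[[id]] <- .new_hgt_call(id, "ambiguous",
                                   notes = "no alignment available")
      next
    }
    tree <- bootstrap_support(aln, n_reps = bootstrap_reps,
                              seed = seed + match(id, candidates))
    g <- c(groups, stats::setNames(recipient_groups[1], id))
    calls[[id]] <- classify_hgt_topology(
      tree, id, g, donor_groups = donor_groups,
      recipient_groups = recipient_groups,
      min_basal_donor_species = min_basal_donor_species,
      min_support = min_support)
  }
  calls_df <- do.call(rbind, lapply(calls, function(x)
    data.frame(query_id = x$query_id, verdict = x$verdict,
               donor_group = x$donor_group,
               nesting_support = x$nesting_support,
               n_basal_donor_species = x$n_basal_donor_species,
               notes = x$notes, stringsAsFactors = FALSE)))
  phylo_pass <- if (is.null(calls_df)) character(0) else
    calls_df$query_id[calls_df$verdict == "hgt"]

  # stage 3: genomic verification
  mapping <- if (length(phylo_pass))
    map_to_contigs(ds$segments[phylo_pass], ds$contigs,
                   max_e = contig_max_e, min_identity = contig_min_identity)
  else
    map_to_contigs(character(0), ds$contigs)
  mapped <- intersect(phylo_pass, unique(mapping$candidate_id))

  coverage <- compute_coverage(ds$reads, ds$contigs)
  target_ctgs <- unique(mapping$contig_id[mapping$candidate_id %in% mapped])
  cov_test <- NULL
  verified <- mapped
  if (length(target_ctgs) >= 2) {
    tdep <- coverage$depth[match(target_ctgs, coverage$contig_id)]
    bdep <- coverage$depth[!coverage$contig_id %in% target_ctgs]
    nb <- if (is.null(n_background)) length(bdep)
    else min(n_background, length(bdep))
    cov_test <- coverage_bias_test(tdep, bdep, n_background = nb,
                                   seed = seed, alpha = alpha)
    if (cov_test$verdict == "biased") verified <- character(0)
  }
  mito <- mito_screen(ds$segments[verified], ds$mito)

  # annotative stages (never veto)
  struct <- tryCatch({
    blocks <- compare_segments(ds$structural$contigs[["ctg_multi"]],
                               ds$structural$donor_seq[[1]])
    summarize_transfer(blocks, ds$structural$donor_ann)
  }, error = function(e) NULL)
  introns <- tryCatch(
    detect_introns(ds$structural$transcripts[[1]],
                   ds$structural$contigs[["ctg_single"]]),
    error = function(e) NULL)
  kaks <- tryCatch(dnds_table(ds$ortholog_pairs$pairs),
                   error = function(e) NULL)
  dge <- tryCatch(run_dge(ds$counts), error = function(e) NULL)

  final <- sort(verified)
  manifest <- list(
    stage_counts = data.frame(
      stage = c("input", "filter_candidates", "phylo_hgt", "contig_mapped",
                "final"),
      n = c(length(ds$segments), length(candidates), length(phylo_pass),
            length(mapped), length(final))),
    params = list(thresholds = thresholds, bootstrap_reps = bootstrap_reps,
                  min_support = min_support,
                  min_basal_donor_species = min_basal_donor_species,
                  contig_max_e = contig_max_e,
                  contig_min_identity = contig_min_identity,
                  alpha = alpha, seed = seed),
    filter_stage_counts = report$stage_counts
  )
  structure(list(
    filter_report = report,
    hgt_calls = calls_df,
    mapping = mapping,
    coverage = coverage,
    coverage_test = cov_test,
    mito = mito,
    transfer_report = struct,
    intron_calls = introns,
    kaks_table = kaks,
    dge_table = dge,
    final_calls = final,
    manifest = manifest
  ), class = "hgt_run")
}

#' @export
print.hgt_run <- function(x, ...) {
  cat("HGT detection run\n")
  print(x$manifest$stage_counts, row.names = FALSE)
  cat("final calls:", paste(x$final_calls, collapse = ", "), "\n")
  if (!is.null(x$coverage_test))
    cat(sprintf("coverage: %s (p = %.3g)\n", x$coverage_test$verdict,
                x$coverage_test$p_value))
  invisible(x)
}

#' Build the demonstration dataset (optionally writing it to disk)
#'
#' 50 host gene families with 5 bacterial and 2 fungal planted transfers
#' (the package defaults), intended to run end to end in a few minutes on
#' one CPU.
#'
#' @param seed integer seed (default 7).
#' @param dir optional output directory; when given, the dataset is written
#'   with [write_dataset()].
#' @return the `synthetic_dataset`, invisibly when `dir` is given.
#' @export
make_demo <- function(seed = 7, dir = NULL) {
  ds <- synthetic_dataset(simulation_config(seed = seed))
  if (!is.null(dir)) {
    write_dataset(ds, dir)
    return(invisible(ds))
  }
  ds
}

#' dN/dS table for a paired CDS set
#'
#' Pairs are two records per pair named `<id>_a` / `<id>_b`.
#'
#' @param pairs named character vector of CDS.
#' @param alpha significance level.
#' @return data.frame, one row per pair, with NG86 quantities and the
#'   selection classification; summary counts in attribute `summary`.
#' @export
dnds_table <- function(pairs, alpha = 0.05) {
  ids <- unique(sub("_[ab]$", "", names(pairs)))
  rows <- lapply(ids, function(id) {
    a <- pairs[[paste0(id, "_a")]]
    b <- pairs[[paste0(id, "_b")]]
    if (is.null(a) || is.null(b)) return(NULL)
    r <- compute_dnds(a, b, alpha = alpha)
    data.frame(pair = id, n_codons = r$n_codons, Sd = r$Sd, Nd = r$Nd,
               dS = r$dS, dN = r$dN, omega = r$omega, p_value = r$p_value,
               classification = r$classification, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- table(out$classification)
  out
}
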