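# The three-step homology filter cascade that reduces gene segments to HGT
# candidates: (1) similarity thresholds on translated hits, with segments
# lacking any retained hit set aside as "no homolog"; (2) exclusion of
# segments scoring best against the recipient's own lineage (arthropods);
# (3) a homolog floor requiring enough distinct subject species to support a
# phylogeny.  Every segment ends in exactly one terminal bucket, so stage
# counts always sum to the input size.

#' Filter thresholds for the cascade
#'
#' Defaults are the published cutoffs: E <= 1e-20, identity >= 25 percent,
#' overlap >= 25 aligned residues, and at least 10 homologs per candidate.
#'
#' @param max_e maximum E-value (inclusive).
#' @param min_identity minimum percent identity (inclusive).
#' @param min_overlap minimum aligned length in residues (inclusive).
#' @param min_homologs minimum number of distinct subject species.
#' @return list of thresholds.
#' @export
filter_thresholds <- function(max_e = 1e-20, min_identity = 25,
                              min_overlap = 25, min_homologs = 10) {
  stopifnot(max_e > 0, min_homologs >= 2)
  list(max_e = max_e, min_identity = min_identity,
       min_overlap = min_overlap, min_homologs = min_homologs)
}

#' Similarity-threshold filter on a hit table
#'
#' Keeps exactly the hits with e_value <= max_e AND percent_identity >=
#' min_identity AND overlap >= min_overlap; all boundaries inclusive.
#'
#' @param hits hit data.frame (see [read_hit_table()]).
#' @param thresholds a [filter_thresholds()] list.
#' @return the retained subset of `hits`.
#' @export
threshold_filter <- function(hits, thresholds = filter_thresholds()) {
  keep <- hits$e_value <= thresholds$max_e &
    hits$percent_identity >= thresholds$min_identity &
    hits$overlap >= thresholds$min_overlap
  hits[keep, , drop = FALSE]
}

#' Segments with no retained homolog
#'
#' @param segment_ids all query segment ids.
#' @param retained_hits output of [threshold_filter()].
#' @return character vector of segment ids with zero retained hits.
#' @export
classify_no_homolog <- function(segment_ids, retained_hits) {
  setdiff(segment_ids, unique(retained_hits$query_id))
}

#' Ingroup-preference filter (recipient-lineage best hits excluded)
#'
#' A query is excluded when all its hits are from the recipient group, or
#' when its best (bit)score over recipient-group hits strictly exceeds its
#' best score over all other groups.  Ties retain the query: the exclusion
#' rule removes only strictly higher recipient-lineage similarity.
#'
#' @param hits retained hits for queries with at least one hit.
#' @param recipient_group taxon group of the recipient lineage.
#' @return named logical vector, TRUE = retained, indexed by query id.
#' @export
ingroup_preference_filter <- function(hits, recipient_group = "arthropod") {
  qs <- unique(hits$query_id)
  out <- vapply(qs, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    ing <- h$taxon_group == recipient_group
    if (all(ing)) return(FALSE)
    if (!any(ing)) return(TRUE)
    max(h$bitscore[ing]) <= max(h$bitscore[!ing])
  }, logical(1))
  names(out) <- qs
  out
}

#' Homolog-floor filter on distinct subject species
#'
#' @param hits retained hits.
#' @param min_homologs minimum number of distinct subject species.
#' @return named logical vector, TRUE = retained, indexed by query id.
#' @export
homolog_count_filter <- function(hits, min_homologs = 10) {
  qs <- unique(hits$query_id)
  out <- vapply(qs, function(q) {
    length(unique(hits$species_id[hits$query_id == q])) >= min_homologs
  }, logical(1))
  names(out) <- qs
  out
}

#' Run the full filter cascade
#'
#' Applies, in order: similarity thresholds (emitting the "no homolog"
#' bucket), the ingroup-preference exclusion, and the homolog floor.  The
#' report satisfies the conservation invariant: at every stage, eliminated
#' plus remaining equals the stage input.
#'
#' @param segment_ids character vector of all query segment ids (must be
#'   unique).
#' @param hits full hit table.
#' @param thresholds a [filter_thresholds()] list.
#' @param recipient_group taxon group of the recipient lineage.
#' @return object of class `filter_report`: list with `verdicts` (named
#'   character: no_homolog / arthropod_preferred / too_few_homologs /
#'   candidate), `candidates`, `stage_counts` (data.frame: stage, input,
#'   eliminated, remaining) and `retained_hits`.
#' @export
run_cascade <- function(segment_ids, hits,
                        thresholds = filter_thresholds(),
                        recipient_group = "arthropod") {
  if (anyDuplicated(segment_ids)) stop("duplicate query ids")
  unknown <- setdiff(unique(hits$query_id), segment_ids)
  if (length(unknown))
    stop("hit table references unknown segments: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  verdicts <- stats::setNames(rep(NA_character_, length(segment_ids)),
                              segment_ids)

  retained <- threshold_filter(hits, thresholds)
  nh <- classify_no_homolog(segment_ids, retained)
  verdicts[nh] <- "no_homolog"
  s1 <- data.frame(stage = "no_homolog", input = length(segment_ids),
                   eliminated = length(nh),
                   remaining = length(segment_ids) - length(nh))

  with_hits <- setdiff(segment_ids, nh)
  keep2 <- ingroup_preference_filter(retained, recipient_group)
  excl2 <- names(keep2)[!keep2]
  verdicts[excl2] <- "arthropod_preferred"
  s2 <- data.frame(stage = "ingroup_preference", input = length(with_hits),
                   eliminated = length(excl2),
                   remaining = length(with_hits) - length(excl2))

  left <- setdiff(with_hits, excl2)
  keep3 <- homolog_count_filter(
    retained[retained$query_id %in% left, , drop = FALSE],
    thresholds$min_homologs)
  excl3 <- names(keep3)[!keep3]
  verdicts[excl3] <- "too_few_homologs"
  cand <- setdiff(left, excl3)
  verdicts[cand] <- "candidate"
  s3 <- data.frame(stage = "homolog_floor", input = length(left),
                   eliminated = length(excl3),
                   remaining = length(cand))

  structure(list(
    verdicts = verdicts,
    candidates = cand,
    stage_counts = rbind(s1, s2, s3),
    retained_hits = retained[retained$query_id %in% cand, , drop = FALSE]
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Homology filter cascade\n")
  print(x$stage_counts, row.names = FALSE)
  cat(sprintf("candidates: %d\n", length(x$candidates)))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  d <- data.frame(segment = names(report$verdicts),
                  verdict = unname(report$verdicts))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
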