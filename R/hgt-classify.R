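# Donor-clade nesting classification of candidate gene trees.  A candidate
# is called horizontally transferred when its leaf is nested inside a
# well-supported clade of one donor group while additional species of that
# donor group branch basally (outside the nesting clade), the tree pattern
# used to diagnose transfer direction.  Recipient-lineage leaves inside the
# donor clade are tolerated: a transfer predating the recipient's
# speciation drags related recipient-side taxa into the donor clade.

# canonical key for an unrooted bipartition given one side's tip set
.split_key <- function(tips, all_tips) {
  a <- sort(tips)
  b <- sort(setdiff(all_tips, tips))
  pick <- if (length(a) < length(b)) a
  else if (length(b) < length(a)) b
  else if (paste(a, collapse = "\r") <= paste(b, collapse = "\r")) a else b
  paste(pick, collapse = "\r")
}

# support map keyed by bipartition, from node.label of an unrooted tree
.support_map <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  keys <- character(tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    node <- ntip + i
    tips <- tree$tip.label[.descendant_tips(tree, node)]
    keys[i] <- .split_key(tips, tree$tip.label)
  }
  stats::setNames(sup, keys)
}

# indices of tip descendants of a node (the node itself if a tip)
.descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .descendant_tips, tree = tree))
}

#' Root a tree for nesting classification
#'
#' Uses the designated outgroup group when one is given and present among
#' the leaves, otherwise midpoint rooting (unit branch lengths are assumed
#' when the tree carries none).
#'
#' @param tree `phylo` tree.
#' @param groups named character vector mapping leaf label to taxon group.
#' @param outgroup_group optional taxon group to root with.
#' @return rooted `phylo` tree.
#' @export
root_for_classification <- function(tree, groups, outgroup_group = NULL) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  if (!is.null(outgroup_group)) {
    og <- tree$tip.label[groups[tree$tip.label] %in% outgroup_group]
    if (length(og)) {
      rooted <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                         error = function(e) NULL)
      if (is.null(rooted))
        rooted <- ape::root(tree, outgroup = og[1], resolve.root = TRUE)
      return(rooted)
    }
  }
  phangorn::midpoint(tree)
}

.new_hgt_call <- function(query_id, verdict, donor_group = NA_character_,
                          nesting_support = NA_real_,
                          n_basal_donor_species = NA_integer_,
                          notes = "") {
  structure(list(query_id = query_id, verdict = verdict,
                 donor_group = donor_group,
                 nesting_support = nesting_support,
                 n_basal_donor_species = n_basal_donor_species,
                 notes = notes),
            class = "hgt_call")
}

#' @export
print.hgt_call <- function(x, ...) {
  cat(sprintf("hgt_call: %s -> %s", x$query_id, x$verdict))
  if (!is.na(x$donor_group))
    cat(sprintf(" (donor %s, support %s, %d basal donor species)",
                x$donor_group,
                ifelse(is.na(x$nesting_support), "n/a", x$nesting_support),
                x$n_basal_donor_species))
  if (nzchar(x$notes)) cat(" [", x$notes, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Classify a candidate gene tree for horizontal transfer
#'
#' Verdict "hgt" requires a clade that contains the query leaf, whose other
#' leaves all belong to a single donor group (leaves of recipient groups are
#' tolerated inside it), with at least `min_basal_donor_species` distinct
#' species of that donor group outside the clade, and clade support at
#' least `min_support` (clades without an assessed support pass).  The
#' smallest such clade determines the reported donor group and support.  If
#' no such clade exists and the query's sister leaves are all from recipient
#' groups, the verdict is "no_hgt"; otherwise "ambiguous".
#'
#' @param tree `phylo` tree with leaf labels; supports on internal nodes
#'   (`node.label`) are honoured when present.
#' @param query_id leaf label of the candidate.
#' @param groups named character vector mapping leaf label to taxon group.
#' @param species optional named character vector mapping leaf label to
#'   species (defaults to the label itself).
#' @param donor_groups taxon groups considered potential donors.
#' @param recipient_groups taxon groups of the recipient lineage.
#' @param min_basal_donor_species minimum distinct donor species outside
#'   the nesting clade.
#' @param min_support minimum bootstrap support (0-100) of the nesting
#'   clade.
#' @param outgroup_group optional taxon group used for rooting.
#' @return an `hgt_call` object.
#' @export
classify_hgt_topology <- function(tree, query_id, groups, species = NULL,
                                  donor_groups = c("bacteria", "fungi"),
                                  recipient_groups = "arthropod",
                                  min_basal_donor_species = 3,
                                  min_support = 70,
                                  outgroup_group = NULL) {
  if (!query_id %in% tree$tip.label) stop("query leaf absent from tree")
  if (is.null(species))
    species <- stats::setNames(tree$tip.label, tree$tip.label)
  supports <- .support_map(tree)
  rooted <- root_for_classification(tree, groups, outgroup_group)
  ntip <- length(rooted$tip.label)
  all_tips <- rooted$tip.label

  best <- NULL
  for (i in seq_len(rooted$Nnode)) {
    node <- ntip + i
    tips <- all_tips[.descendant_tips(rooted, node)]
    if (!query_id %in% tips) next
    others <- setdiff(tips, query_id)
    if (!length(others)) next
    og <- groups[others]
    for (g in donor_groups) {
      if (!all(og %in% c(g, recipient_groups))) next
      if (!any(og == g)) next
      outside <- setdiff(all_tips, tips)
      basal <- unique(species[outside[groups[outside] == g]])
      if (length(basal) < min_basal_donor_species) next
      sup <- if (is.null(supports)) NA_real_
      else unname(supports[.split_key(tips, all_tips)])
      if (!is.na(sup) && sup < min_support) next
      cand <- list(size = length(tips), group = g, support = sup,
                   n_basal = length(basal),
                   tolerated = any(og %in% recipient_groups))
      if (is.null(best) || cand$size < best$size) best <- cand
    }
  }
  if (!is.null(best)) {
    return(.new_hgt_call(
      query_id, "hgt", donor_group = best$group,
      nesting_support = best$support,
      n_basal_donor_species = best$n_basal,
      notes = if (best$tolerated) "pre-speciation transfer" else ""))
  }
  # query's immediate sister leaves
  qi <- match(query_id, all_tips)
  parent <- rooted$edge[rooted$edge[, 2] == qi, 1]
  sis <- setdiff(all_tips[.descendant_tips(rooted, parent)], query_id)
  if (length(sis) && all(groups[sis] %in% recipient_groups))
    .new_hgt_call(query_id, "no_hgt")
  else
    .new_hgt_call(query_id, "ambiguous")
}

#' Brute-force reference classifier (testing oracle)
#'
#' Enumerates every clade of the rooted tree explicitly and applies the
#' nesting rule verbatim.  Refuses trees with more than 12 leaves; intended
#' for cross-checking [classify_hgt_topology()] on small instances.
#'
#' @inheritParams classify_hgt_topology
#' @return an `hgt_call` object.
#' @export
brute_force_classifier <- function(tree, query_id, groups, species = NULL,
                                   donor_groups = c("bacteria", "fungi"),
                                   recipient_groups = "arthropod",
                                   min_basal_donor_species = 3,
                                   min_support = 70,
                                   outgroup_group = NULL) {
  if (length(tree$tip.label) > 12) stop("brute-force classifier: > 12 leaves")
  if (!query_id %in% tree$tip.label) stop("query leaf absent from tree")
  if (is.null(species))
    species <- stats::setNames(tree$tip.label, tree$tip.label)
  supports <- .support_map(tree)
  rooted <- root_for_classification(tree, groups, outgroup_group)
  ntip <- length(rooted$tip.label)
  all_tips <- rooted$tip.label
  root_node <- ntip + 1L

  # clades via node paths: a tip belongs to the clade of `node` iff its
  # path from the root passes through `node`
  clade_of <- function(node) {
    keep <- logical(ntip)
    for (t in seq_len(ntip)) {
      path <- ape::nodepath(rooted, root_node, t)
      keep[t] <- node %in% path
    }
    all_tips[keep]
  }

  hits <- list()
  for (node in (ntip + 1L):(ntip + rooted$Nnode)) {
    tips <- clade_of(node)
    if (!(query_id %in% tips)) next
    rest <- setdiff(tips, query_id)
    if (length(rest) == 0) next
    for (g in donor_groups) {
      donors_inside <- sum(groups[rest] == g)
      intruders <- sum(!(groups[rest] %in% c(g, recipient_groups)))
      outside <- setdiff(all_tips, tips)
      basal_species <- unique(species[outside[groups[outside] == g]])
      sup <- if (is.null(supports)) NA_real_
      else unname(supports[.split_key(tips, all_tips)])
      ok <- donors_inside >= 1 && intruders == 0 &&
        length(basal_species) >= min_basal_donor_species &&
        (is.na(sup) || sup >= min_support)
      if (ok) {
        hits[[length(hits) + 1]] <- list(
          tips = tips, group = g, support = sup,
          n_basal = length(basal_species),
          tolerated = any(groups[rest] %in% recipient_groups))
      }
    }
  }
  if (length(hits)) {
    sizes <- vapply(hits, function(h) length(h$tips), numeric(1))
    h <- hits[[which.min(sizes)]]
    return(.new_hgt_call(
      query_id, "hgt", donor_group = h$group, nesting_support = h$support,
      n_basal_donor_species = h$n_basal,
      notes = if (h$tolerated) "pre-speciation transfer" else ""))
  }
  qi <- match(query_id, all_tips)
  parent <- rooted$edge[rooted$edge[, 2] == qi, 1]
  sis <- setdiff(clade_of(parent), query_id)
  if (length(sis) && all(groups[sis] %in% recipient_groups))
    .new_hgt_call(query_id, "no_hgt")
  else
    .new_hgt_call(query_id, "ambiguous")
}
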