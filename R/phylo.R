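# Distance phylogenetics for candidate homolog sets: conserved-block
# trimming, Poisson-corrected protein distances, Saitou-Nei neighbor
# joining (via ape) and nonparametric bootstrap supports from column
# resampling.

# aligned named character vector -> rows x columns character matrix
.aln_matrix <- function(aln) {
  stopifnot(length(aln) >= 1)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

.aln_collapse <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Trim an alignment to its conserved blocks
#'
#' Keeps maximal runs of columns whose gap fraction is at most
#' `max_gap_frac` and whose majority (most frequent non-gap) residue
#' frequency is at least `min_conservation`; runs shorter than
#' `min_block_len` are dropped.  Column order is preserved.  This is a
#' Gblocks-style cleanup of poorly aligned flanks, not a reimplementation of
#' Gblocks.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   ("-" = gap).
#' @param max_gap_frac maximum fraction of gaps per kept column.
#' @param min_block_len minimum run length of kept columns.
#' @param min_conservation minimum majority-residue frequency (over all
#'   rows) per kept column.
#' @return list with `alignment` (trimmed, same names) and `blocks`
#'   (data.frame of kept column intervals, 1-based inclusive on the input).
#' @export
trim_conserved_blocks <- function(aln, max_gap_frac = 0.5,
                                  min_block_len = 10,
                                  min_conservation = 0.5) {
  m <- .aln_matrix(aln)
  nr <- nrow(m)
  gap_frac <- colMeans(m == "-")
  maj <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / nr
  })
  good <- gap_frac <= max_gap_frac & maj >= min_conservation
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep_runs <- which(r$values & r$lengths >= min_block_len)
  if (!length(keep_runs)) stop("no conserved blocks")
  cols <- unlist(lapply(keep_runs, function(i) starts[i]:ends[i]))
  list(
    alignment = .aln_collapse(m[, cols, drop = FALSE]),
    blocks = data.frame(start = starts[keep_runs], end = ends[keep_runs])
  )
}

#' Poisson-corrected pairwise distance matrix from a protein alignment
#'
#' For each pair, p is the mismatch fraction over columns where both rows
#' are non-gap, and d = -ln(1 - p).  p is capped at `p_cap` (with a
#' warning) so distances stay finite.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param p_cap saturation cap on the mismatch proportion.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
compute_distance_matrix <- function(aln, p_cap = 0.95) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= p_cap) { p <- p_cap; capped <- TRUE }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  if (capped) warning("saturated distance(s) capped at -ln(1 - ", p_cap, ")")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (ape's implementation); negative
#' branch-length estimates are clamped to zero afterwards.  On an additive
#' matrix the leaf-to-leaf path lengths reproduce the input exactly.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return unrooted `phylo` tree.
#' @export
build_nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least three taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and >= 0")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilding the tree
#' each time; the support of each internal edge is the percentage of
#' replicate trees containing the same bipartition.  Deterministic under a
#' fixed seed.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param p_cap distance saturation cap.
#' @return `phylo` tree whose `node.label` holds supports (0-100; root
#'   label NA).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1, p_cap = 0.95) {
  stopifnot(n_reps >= 1)
  m <- .aln_matrix(aln)
  if (ncol(m) < 1) stop("alignment has no columns")
  point <- build_nj_tree(suppressWarnings(compute_distance_matrix(aln, p_cap)))
  reps <- with_substream(seed, .SUBSTREAM[["bootstrap"]], {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), replace = TRUE)
      a <- .aln_collapse(m[, cols, drop = FALSE])
      build_nj_tree(suppressWarnings(compute_distance_matrix(a, p_cap)))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sup <- round(100 * counts / n_reps, 1)
  # the root "bipartition" is trivially present everywhere; mark it NA
  sup[1] <- NA
  point$node.label <- as.character(sup)
  point
}
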