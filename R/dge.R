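# FPKM normalisation and no-replicate differential expression across
# developmental stages.  Expression is FPKM = 1e9 * C / (N * L) with C the
# uniquely aligned fragment count of a gene, N the stage library size and L
# the CDS length in bp.  Stage pairs are compared with the Audic-Claverie
# two-library exact test (the standard test without replicates), p-values
# adjusted by Benjamini-Hochberg, and a gene/pair is flagged when
# ratio >= 2, p <= 0.001 and q <= 0.001 (all inclusive, configurable).

#' Construct a count matrix container
#'
#' @param counts genes x stages matrix of nonnegative integer fragment
#'   counts with dimnames.
#' @param lengths per-gene CDS lengths (bp), positive.
#' @param lib_sizes per-stage totals of uniquely aligned fragments; defaults
#'   to the column sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(lengths) != nrow(counts) || any(lengths <= 0))
    stop("lengths must be positive, one per gene")
  if (length(lib_sizes) != ncol(counts) || any(colSums(counts) > lib_sizes))
    stop("per-stage count totals may not exceed library sizes")
  structure(list(counts = counts, lengths = as.numeric(lengths),
                 lib_sizes = as.numeric(lib_sizes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d stages (library sizes %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(format(x$lib_sizes, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' FPKM from fragment counts
#'
#' FPKM = 1e9 * C / (N * L).  Stages with library size 0 get FPKM 0 with a
#' warning.
#'
#' @param cm a [count_matrix()].
#' @return genes x stages numeric matrix of FPKM values.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  N <- cm$lib_sizes
  if (any(N == 0)) {
    warning("library size 0 in stage(s): ",
            paste(colnames(cm$counts)[N == 0], collapse = ", "))
  }
  f <- sweep(cm$counts, 2, ifelse(N == 0, NA, N), "/")
  f <- sweep(f, 1, cm$lengths, "/") * 1e9
  f[is.na(f)] <- 0
  f
}

#' Audic-Claverie two-library exact test
#'
#' Exact two-sided p-value for observing counts (x, y) of one gene in two
#' libraries of sizes (n1, n2) under equal underlying expression.  Uses the
#' negative-binomial form of the Audic-Claverie posterior: given x, Y is
#' NB(size = x + 1, prob = n1 / (n1 + n2)).  The two-sided p-value follows
#' the minimum-likelihood convention (as stats::fisher.test does): it sums
#' the probabilities of all outcomes no more likely than the observed one,
#' which keeps the attained size close to nominal (doubling the smaller
#' tail is markedly conservative for these discrete distributions).
#'
#' @param x,y observed counts (equal-length vectors).
#' @param n1,n2 library sizes (scalars).
#' @return vector of p-values.
#' @export
ac_test <- function(x, y, n1, n2) {
  stopifnot(n1 > 0, n2 > 0, length(x) == length(y))
  pr <- n1 / (n1 + n2)
  vapply(seq_along(x), function(i) {
    size <- x[i] + 1
    d0 <- stats::dnbinom(y[i], size, pr) * (1 + 1e-7)
    mode <- max(0, floor((size - 1) * (1 - pr) / pr))
    if (y[i] <= mode) {
      lo <- stats::pnbinom(y[i], size, pr)
      # smallest y' >= mode whose density has fallen to <= d0
      lo_b <- mode
      hi_b <- mode + 20L * ceiling(sqrt(size * (1 - pr)) / pr + 10)
      while (stats::dnbinom(hi_b, size, pr) > d0) hi_b <- hi_b * 2L
      while (lo_b < hi_b) {
        m <- (lo_b + hi_b) %/% 2
        if (stats::dnbinom(m, size, pr) <= d0) hi_b <- m else lo_b <- m + 1
      }
      p <- lo + 1 - stats::pnbinom(lo_b - 1, size, pr)
    } else {
      hi <- 1 - stats::pnbinom(y[i] - 1, size, pr)
      # largest y' <= mode whose density is still <= d0
      lo_b <- 0
      hi_b <- mode
      while (lo_b < hi_b) {
        m <- (lo_b + hi_b + 1) %/% 2
        if (stats::dnbinom(m, size, pr) <= d0) lo_b <- m else hi_b <- m - 1
      }
      p <- hi + (if (stats::dnbinom(lo_b, size, pr) <= d0)
        stats::pnbinom(lo_b, size, pr) else 0)
    }
    min(1, p)
  }, numeric(1))
}

#' Per-gene expression ratio and exact-test p for one stage pair
#'
#' The ratio is FPKM_a / FPKM_b folded to >= 1; genes with a zero FPKM on
#' either side have the smallest nonzero FPKM of the stage pair added to
#' both sides as a pseudo-value (the guard affects only zeros, so finite
#' fold changes are exact); p-values come from [ac_test()] on the raw
#' counts with the stage library sizes.
#'
#' @param cm a [count_matrix()].
#' @param stage_a,stage_b distinct stage names or indices.
#' @return data.frame with `gene`, `ratio`, `p_value`.
#' @export
pairwise_dge <- function(cm, stage_a, stage_b) {
  stopifnot(inherits(cm, "count_matrix"))
  ia <- if (is.character(stage_a)) match(stage_a, colnames(cm$counts)) else stage_a
  ib <- if (is.character(stage_b)) match(stage_b, colnames(cm$counts)) else stage_b
  if (is.na(ia) || is.na(ib)) stop("unknown stage")
  if (ia == ib) stop("stages must be distinct")
  f <- compute_fpkm(cm)
  fa <- f[, ia]; fb <- f[, ib]
  nz <- c(fa[fa > 0], fb[fb > 0])
  eps <- if (length(nz)) min(nz) else 1
  guard <- fa == 0 | fb == 0
  ratio <- ifelse(guard, (fa + eps) / (fb + eps), fa / fb)
  ratio <- pmax(ratio, 1 / ratio)
  p <- ac_test(cm$counts[, ia], cm$counts[, ib],
               cm$lib_sizes[ia], cm$lib_sizes[ib])
  data.frame(gene = rownames(cm$counts), ratio = unname(ratio),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1, mapped back to the
#' input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Flag differential expression under the joint criteria
#'
#' @param ratio fold-change ratio (>= 1 orientation).
#' @param p raw p-value.
#' @param q BH-adjusted q-value.
#' @param min_ratio,max_p,max_fdr inclusive thresholds.
#' @return logical vector.
#' @export
flag_dge <- function(ratio, p, q, min_ratio = 2, max_p = 0.001,
                     max_fdr = 0.001) {
  ratio >= min_ratio & p <= max_p & q <= max_fdr
}

#' All pairwise stage comparisons with BH adjustment and flags
#'
#' Emits choose(k, 2) comparisons for k stages; q-values are adjusted
#' within each stage pair across genes.
#'
#' @param cm a [count_matrix()].
#' @param min_ratio,max_p,max_fdr flag criteria (see [flag_dge()]).
#' @return data.frame with `gene`, `stage_a`, `stage_b`, `ratio`,
#'   `p_value`, `q_value`, `flag`.
#' @export
run_dge <- function(cm, min_ratio = 2, max_p = 0.001, max_fdr = 0.001) {
  stages <- colnames(cm$counts)
  if (length(stages) < 2) stop("need at least two stages")
  pairs <- utils::combn(stages, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    d <- pairwise_dge(cm, pairs[1, k], pairs[2, k])
    d$q_value <- bh_fdr(d$p_value)
    d$stage_a <- pairs[1, k]
    d$stage_b <- pairs[2, k]
    d$flag <- flag_dge(d$ratio, d$p_value, d$q_value,
                       min_ratio = min_ratio, max_p = max_p,
                       max_fdr = max_fdr)
    d[, c("gene", "stage_a", "stage_b", "ratio", "p_value", "q_value", "flag")]
  })
  do.call(rbind, out)
}
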