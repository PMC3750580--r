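# Nei-Gojobori (1986) dN/dS estimation for pairwise codon alignments, with a
# Fisher exact significance test on the site/substitution table.  The method
# is the classic approximate counting one: per-codon synonymous and
# nonsynonymous site fractions from the single-mutant neighbourhood,
# pathway-averaged substitution counts, Jukes-Cantor multiple-hit correction
# of the proportions.  An external (dN, dS) pair can be supplied to
# `classify_selection()` for users wanting parity with other estimators.

#' Validate and normalise a pairwise codon alignment
#'
#' Both sequences must be equal length, in frame, and free of internal stop
#' codons.  Codon columns containing an ambiguous base or an alignment gap in
#' either sequence are dropped with a warning.
#'
#' @param a,b in-frame nucleotide strings of equal length.
#' @return list with codon vectors `a`, `b` and `n_codons`.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("alignment length not divisible by 3")
  ca <- split_codons(a)
  cb <- split_codons(b)
  ok_base <- function(x) grepl("^[ACGT]{3}$", x)
  keep <- ok_base(ca) & ok_base(cb)
  if (any(!keep)) {
    warning(sum(!keep), " codon column(s) with gaps/ambiguity skipped")
    ca <- ca[keep]; cb <- cb[keep]
  }
  if (length(ca) < 1) stop("no usable codons")
  if (any(codon_aa(ca) == "*") || any(codon_aa(cb) == "*"))
    stop("internal stop codon in codon alignment")
  list(a = ca, b = cb, n_codons = length(ca))
}

#' NG86 synonymous and nonsynonymous site counts for one sequence
#'
#' @param codons character vector of sense codons.
#' @return named numeric `c(S =, N =)`.
#' @export
count_sites <- function(codons) {
  tab <- ng_site_table()
  if (!all(codons %in% rownames(tab))) stop("non-sense codon in input")
  c(S = sum(tab[codons, "S"]), N = sum(tab[codons, "N"]))
}

#' Pathway-averaged synonymous / nonsynonymous differences between two
#' codon sequences
#'
#' @param a,b equal-length character vectors of sense codons.
#' @return named numeric `c(Sd =, Nd =)`.
#' @export
count_differences <- function(a, b) {
  stopifnot(length(a) == length(b))
  tabs <- ng_diff_tables()
  idx <- cbind(match(a, rownames(tabs$Sd)), match(b, colnames(tabs$Sd)))
  if (anyNA(idx)) stop("non-sense codon in input")
  c(Sd = sum(tabs$Sd[idx]), Nd = sum(tabs$Nd[idx]))
}

#' Pairwise dN/dS with Jukes-Cantor correction and Fisher exact test
#'
#' Sites are averaged between the two sequences; proportions pS = Sd/S and
#' pN = Nd/N receive the correction d = -(3/4) ln(1 - (4/3) p).  omega is
#' dN/dS, undefined (NA) when dS = 0.  The p-value comes from a two-sided
#' Fisher exact test on the 2x2 table [[Sd, S-Sd], [Nd, N-Nd]] with counts
#' rounded half-up to integers (rates always use unrounded values).
#' Classification: "negative" if omega < 1 and p <= alpha, "positive" if
#' omega > 1 and p <= alpha, "undefined" when omega is undefined, else
#' "neutral".
#'
#' @param a,b in-frame nucleotide strings (a pairwise codon alignment).
#' @param alpha significance level for the classification (default 0.05).
#' @return object of class `dnds_result`: list with fields `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `p_value`, `classification`,
#'   `n_codons`, `saturated`.
#' @export
compute_dnds <- function(a, b, alpha = 0.05) {
  al <- codon_alignment(a, b)
  sa <- count_sites(al$a)
  sb <- count_sites(al$b)
  S <- (sa["S"] + sb["S"]) / 2
  N <- (sa["N"] + sb["N"]) / 2
  d <- count_differences(al$a, al$b)
  pS <- as.numeric(d["Sd"] / S)
  pN <- as.numeric(d["Nd"] / N)
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  if (saturated) warning("substitution proportion >= 3/4: distance saturated")
  omega <- if (saturated || is.na(dS) || dS == 0) NA_real_ else dN / dS
  rh <- function(x) floor(x + 0.5)  # round half-up for the Fisher table
  tab <- rbind(c(rh(d["Sd"]), max(0, rh(S - d["Sd"]))),
               c(rh(d["Nd"]), max(0, rh(N - d["Nd"]))))
  p_value <- stats::fisher.test(tab)$p.value
  classification <- if (is.na(omega)) "undefined"
    else if (omega < 1 && p_value <= alpha) "negative"
    else if (omega > 1 && p_value <= alpha) "positive"
    else "neutral"
  structure(list(
    S = as.numeric(S), N = as.numeric(N),
    Sd = as.numeric(d["Sd"]), Nd = as.numeric(d["Nd"]),
    pS = pS, pN = pN, dS = dS, dN = dN,
    omega = omega, p_value = p_value,
    classification = classification,
    n_codons = al$n_codons, saturated = saturated
  ), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "dN/dS (NG86): %d codons  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f\n  dS=%s dN=%s  omega=%s  p=%.3g  [%s]\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    format(x$dS, digits = 4), format(x$dN, digits = 4),
    if (is.na(x$omega)) "undefined" else format(x$omega, digits = 4),
    x$p_value, x$classification))
  invisible(x)
}

#' Classify an externally computed (dN, dS) pair
#'
#' Hook for users bringing rates from another estimator (e.g. a
#' transition-bias-corrected one); applies the same omega/p classification
#' rule as [compute_dnds()].
#'
#' @param dN,dS substitution rates.
#' @param p_value significance of omega != 1.
#' @param alpha significance level.
#' @return classification string.
#' @export
classify_selection <- function(dN, dS, p_value, alpha = 0.05) {
  if (is.na(dS) || dS == 0) return("undefined")
  omega <- dN / dS
  if (omega < 1 && p_value <= alpha) "negative"
  else if (omega > 1 && p_value <= alpha) "positive"
  else "neutral"
}

#' Screen HGT genes against ortholog sets for selection pressure
#'
#' Each focal CDS is paired with its best reciprocal nucleotide match among
#' the ortholog transcripts (local alignment score both ways); the aligned
#' pair is then scored with [compute_dnds()].  Genes without any ortholog
#' above `min_score` are reported unpaired.
#'
#' @param cds named character vector of focal in-frame CDS.
#' @param orthologs named character vector of candidate ortholog CDS.
#' @param min_score minimum nucleotide alignment score to accept a pairing.
#' @param alpha significance level.
#' @return data.frame, one row per focal gene: `gene`, `ortholog`,
#'   `n_codons`, `dN`, `dS`, `omega`, `p_value`, `classification`
#'   (classification "unpaired" when no ortholog qualifies).
#' @export
screen_orthologs <- function(cds, orthologs, min_score = 50, alpha = 0.05) {
  if (length(cds) == 0 || length(orthologs) == 0) {
    return(data.frame(gene = character(0), ortholog = character(0),
                      n_codons = integer(0), dN = numeric(0), dS = numeric(0),
                      omega = numeric(0), p_value = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE))
  }
  genes <- sort(names(cds))
  smat <- vapply(orthologs, function(o) vapply(genes, function(g)
    local_align(cds[[g]], o, type = "nucleotide")$score, numeric(1)),
    numeric(length(genes)))
  smat <- matrix(smat, nrow = length(genes),
                 dimnames = list(genes, names(orthologs)))
  col_best <- apply(smat, 2, which.max)
  rows <- lapply(genes, function(g) {
    scores <- smat[g, ]
    best <- which.max(scores)
    reciprocal <- genes[col_best[best]] == g
    if (scores[best] < min_score || !reciprocal) {
      return(data.frame(gene = g, ortholog = NA_character_,
                        n_codons = NA_integer_, dN = NA_real_, dS = NA_real_,
                        omega = NA_real_, p_value = NA_real_,
                        classification = "unpaired",
                        stringsAsFactors = FALSE))
    }
    o <- orthologs[[best]]
    n <- min(nchar(cds[[g]]), nchar(o))
    n <- n - n %% 3
    r <- compute_dnds(substr(cds[[g]], 1, n), substr(o, 1, n), alpha = alpha)
    data.frame(gene = g, ortholog = names(orthologs)[best],
               n_codons = r$n_codons, dN = r$dN, dS = r$dS, omega = r$omega,
               p_value = r$p_value, classification = r$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
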