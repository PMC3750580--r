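# Codon bookkeeping for the Nei-Gojobori machinery and the codon simulator.
# Tables are built once per session on first use and cached in a package
# environment; everything is derived from the universal genetic code shipped
# with Biostrings.

.codon_cache <- new.env(parent = emptyenv())

.bases <- c("T", "C", "A", "G")

#' All 64 codons in TCAG order
#' @keywords internal
all_codons <- function() {
  if (is.null(.codon_cache$all)) {
    g <- expand.grid(p3 = .bases, p2 = .bases, p1 = .bases,
                     stringsAsFactors = FALSE)
    .codon_cache$all <- paste0(g$p1, g$p2, g$p3)
  }
  .codon_cache$all
}

#' Amino acid translation of codons (universal code, "*" for stops)
#' @keywords internal
codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' The 61 sense codons
#' @keywords internal
sense_codons <- function() {
  if (is.null(.codon_cache$sense)) {
    ac <- all_codons()
    .codon_cache$sense <- ac[codon_aa(ac) != "*"]
  }
  .codon_cache$sense
}

# Single-nucleotide mutational neighbourhood of a codon: the 9 mutants.
.codon_mutants <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(.bases, substr(codon, pos, pos))) {
      m <- codon
      substr(m, pos, pos) <- b
      out <- c(out, m)
    }
  }
  out
}

# Per-codon synonymous / nonsynonymous site counts under the NG86 convention:
# each of the 9 single-nucleotide mutants contributes 1/3 of a site,
# classified by amino-acid identity; mutants that create a stop codon
# contribute nothing (they are excluded, not renormalised), so S + N = 3
# exactly only for codons with no stop-adjacent mutants.
ng_site_table <- function() {
  if (is.null(.codon_cache$sites)) {
    sc <- sense_codons()
    S <- N <- numeric(length(sc))
    names(S) <- names(N) <- sc
    for (cod in sc) {
      aa0 <- codon_aa(cod)
      for (m in .codon_mutants(cod)) {
        aam <- codon_aa(m)
        if (aam == "*") next
        if (aam == aa0) S[cod] <- S[cod] + 1 / 3 else N[cod] <- N[cod] + 1 / 3
      }
    }
    .codon_cache$sites <- cbind(S = S, N = N)
  }
  .codon_cache$sites
}

# Pathway-averaged synonymous / nonsynonymous difference counts for every
# ordered sense-codon pair.  Minimal mutational pathways (1, 2 or 6 orderings
# for 1, 2 or 3 differing positions) are averaged; pathways passing through a
# stop codon are excluded.  If every pathway is blocked by stops, all
# pathways are used as a defined fallback (flagged never in practice for
# sense-codon pairs of interest).
ng_diff_tables <- function() {
  if (!is.null(.codon_cache$Sd)) {
    return(list(Sd = .codon_cache$Sd, Nd = .codon_cache$Nd))
  }
  sc <- sense_codons()
  n <- length(sc)
  Sd <- Nd <- matrix(0, n, n, dimnames = list(sc, sc))
  aa <- codon_aa(sc)
  names(aa) <- sc
  orderings <- list(
    matrix(1L, 1, 1),
    rbind(c(1L, 2L), c(2L, 1L)),
    rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  walk_path <- function(c1, c2, dpos, ord) {
    cur <- c1; sd <- 0; nd <- 0
    for (pos in dpos[ord]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      a <- codon_aa(nxt)
      if (a == "*") return(NULL)
      if (a == codon_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  for (i in seq_len(n)) {
    ci <- sc[i]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- sc[j]
      dpos <- which(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
      ords <- orderings[[length(dpos)]]
      acc <- c(0, 0); k <- 0L
      blocked <- matrix(0, 0, 2)
      for (r in seq_len(nrow(ords))) {
        res <- walk_path(ci, cj, dpos, ords[r, ])
        if (!is.null(res)) { acc <- acc + res; k <- k + 1L }
      }
      if (k == 0L) {
        # fallback: average over all pathways ignoring stop exclusion
        for (r in seq_len(nrow(ords))) {
          cur <- ci; sd <- 0; nd <- 0
          for (pos in dpos[ords[r, ]]) {
            nxt <- cur
            substr(nxt, pos, pos) <- substr(cj, pos, pos)
            if (codon_aa(nxt) != "*" && codon_aa(nxt) == codon_aa(cur))
              sd <- sd + 1
            else nd <- nd + 1
            cur <- nxt
          }
          acc <- acc + c(sd, nd); k <- k + 1L
        }
      }
      Sd[i, j] <- acc[1] / k
      Nd[i, j] <- acc[2] / k
    }
  }
  .codon_cache$Sd <- Sd
  .codon_cache$Nd <- Nd
  list(Sd = Sd, Nd = Nd)
}

#' Split an in-frame nucleotide string into codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# purines/pyrimidines for the HKY simulator
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}
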