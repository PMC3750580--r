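# Codon-pair simulation with controlled selection pressure.  Substitution
# proposals follow an HKY background (transition/transversion ratio kappa =
# 2, uniform base frequencies); proposals that keep the amino acid are
# always accepted, nonsynonymous proposals are accepted with relative
# probability omega, and proposals creating stop codons are rejected
# (Goldman-Yang-style acceptance thinning under the universal code).

# evolve one CDS for t proposed substitutions/site at acceptance ratio omega
.evolve_cds <- function(cds, t, omega, kappa = 2) {
  codons <- split_codons(cds)
  L <- nchar(cds)
  n_events <- stats::rpois(1, t * L)
  if (n_events > 0) {
    for (e in seq_len(n_events)) {
      site <- sample.int(L, 1)
      ci <- (site - 1L) %/% 3L + 1L
      pos <- (site - 1L) %% 3L + 1L
      cod <- codons[ci]
      cur <- substr(cod, pos, pos)
      alts <- setdiff(c("A", "C", "G", "T"), cur)
      w <- ifelse(.is_transition(cur, alts), kappa, 1)
      b <- sample(alts, 1, prob = w)
      m <- cod
      substr(m, pos, pos) <- b
      aam <- codon_aa(m)
      if (aam == "*") next
      acc <- if (aam == codon_aa(cod)) 1 else omega
      if (stats::runif(1) < acc) codons[ci] <- m
    }
  }
  paste(codons, collapse = "")
}

#' Simulate ortholog CDS pairs under known dN/dS
#'
#' Each pair starts from a random ancestral CDS; one copy is evolved for
#' `t_codon` proposed substitutions per nucleotide site at acceptance ratio
#' omega.  With omega = 0 the emitted pairs differ only at synonymous
#' sites; with t = 0 they are identical.
#'
#' @param omega_targets dN/dS value per pair batch (each >= 0).
#' @param t_codon proposed substitutions per nucleotide site.
#' @param n_codons codons per sequence (>= 30).
#' @param n_pairs pairs per omega value.
#' @param seed integer seed.
#' @return list with `pairs` (named character vector with two records per
#'   pair: `<id>_a`, `<id>_b`) and `truth` (data.frame: pair id, omega).
#' @export
simulate_ortholog_pairs <- function(omega_targets, t_codon, n_codons = 300,
                                    n_pairs = 1, seed = 1) {
  if (any(omega_targets < 0)) stop("omega must be >= 0")
  stopifnot(n_codons >= 30, t_codon >= 0, n_pairs >= 1)
  with_substream(seed, .SUBSTREAM[["orthologs"]], {
    pairs <- list()
    truth <- data.frame(pair = character(0), omega = numeric(0))
    k <- 0L
    for (om in omega_targets) {
      for (i in seq_len(n_pairs)) {
        k <- k + 1L
        id <- sprintf("pair%04d", k)
        a <- .random_cds(n_codons)
        b <- .evolve_cds(a, t_codon, om)
        pairs[[paste0(id, "_a")]] <- a
        pairs[[paste0(id, "_b")]] <- b
        truth <- rbind(truth, data.frame(pair = id, omega = om))
      }
    }
    list(pairs = unlist(pairs), truth = truth)
  })
}
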