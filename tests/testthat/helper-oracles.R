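# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force dynamic programming for local
# alignment, explicit single-mutant / pathway enumeration for the
# Nei-Gojobori counts, and plain-loop re-statements of the filter rules.

.O_BASES <- c("T", "C", "A", "G")
.O_CODE <- Biostrings::GENETIC_CODE

o_aa <- function(codon) unname(.O_CODE[codon])

# --- NG86 oracle: explicit enumeration -----------------------------------

# synonymous/nonsynonymous sites of one codon: loop over the 9 mutants
o_ng_sites <- function(codon) {
  s <- 0; n <- 0
  for (pos in 1:3) {
    for (b in .O_BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (o_aa(mut) == "*") next
      if (o_aa(mut) == o_aa(codon)) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(S = s, N = n)
}

# pathway-averaged differences via explicit permutation walking
o_ng_diffs <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dpos)) return(c(Sd = 0, Nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  tot <- c(0, 0); k <- 0
  for (ord in perms(dpos)) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (o_aa(nxt) == "*") { ok <- FALSE; break }
      if (o_aa(nxt) == o_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); k <- k + 1 }
  }
  if (k == 0) {
    for (ord in perms(dpos)) {
      cur <- c1; sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (o_aa(nxt) != "*" && o_aa(nxt) == o_aa(cur)) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      tot <- tot + c(sd, nd); k <- k + 1
    }
  }
  c(Sd = tot[1] / k, Nd = tot[2] / k)
}

# --- quadratic-time affine-gap Smith-Waterman oracle ---------------------

# returns the optimal local alignment score only (Gotoh three-state DP)
o_sw_score <- function(a, b, submat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      sub <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0,
                     M[i - 1, j - 1] + sub,
                     X[i - 1, j - 1] + sub,
                     Y[i - 1, j - 1] + sub)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

o_blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

o_dna_submat <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(-2, 4, 4, dimnames = list(b, b))
  diag(m) <- 1
  m
}

# --- misc ---------------------------------------------------------------

# random amino-acid / nucleotide strings
o_random_aa <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
o_random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

# random sense codon vector as a string
o_random_cds <- function(n_codons) {
  sense <- names(.O_CODE)[.O_CODE != "*"]
  paste(sample(sense, n_codons, TRUE), collapse = "")
}

# split an in-frame CDS into codons
o_split <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

# a tiny hit-table row constructor
o_hit <- function(query, subject, species, group, e, id, ov, bits) {
  data.frame(query_id = query, subject_id = subject, species_id = species,
             taxon_group = group, percent_identity = id, overlap = ov,
             mismatch = 0, gapopen = 0, qstart = 1, qend = ov, sstart = 1,
             send = ov, e_value = e, bitscore = bits,
             stringsAsFactors = FALSE)
}

# random hit table over given segments (for conservation properties)
o_random_hits <- function(segment_ids, n_species = 12) {
  groups <- c("arthropod", "other_eukaryote", "fungi", "bacteria")
  rows <- list()
  for (q in segment_ids) {
    k <- sample(0:n_species, 1)
    if (k == 0) next
    sp <- sample(n_species, k)
    for (s in sp) {
      g <- groups[(s %% 4) + 1]
      rows[[length(rows) + 1]] <- o_hit(
        q, sprintf("sp%02d|p", s), sprintf("sp%02d", s), g,
        e = 10^stats::runif(1, -60, 0), id = stats::runif(1, 10, 100),
        ov = sample(10:300, 1), bits = stats::runif(1, 30, 500))
    }
  }
  if (!length(rows)) return(o_hit("x", "y", "z", "bacteria", 1, 0, 0, 0)[0, ])
  do.call(rbind, rows)
}
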