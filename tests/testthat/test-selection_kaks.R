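# Nei-Gojobori machinery against explicit enumeration oracles.

test_that("count_sites matches single-mutant enumeration on spot codons", {
  # TTT (Phe): T->C at pos 3 is synonymous, the other non-stop mutants are
  # nonsynonymous; oracle recomputes, implementation must agree
  s <- count_sites("TTT")
  expect_equal(unname(s["S"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(s["N"]), 8 / 3, tolerance = 1e-12)
  for (cod in c("ATG", "TGG", "CTA", "AGA", "TAT")) {
    expect_equal(unname(count_sites(cod)), unname(o_ng_sites(cod)),
                 tolerance = 1e-12, label = cod)
  }
  # additivity over identical codons
  s10 <- count_sites(rep("TTT", 10))
  expect_equal(unname(s10), 10 * unname(s), tolerance = 1e-12)
})

test_that("count_differences resolves single- and multi-path codon pairs", {
  expect_equal(unname(count_differences("ATT", "ATC")), c(1, 0))  # Ile/Ile
  expect_equal(unname(count_differences("TTT", "TTA")), c(0, 1))  # Phe/Leu
  expect_equal(unname(count_differences("AAA", "AAA")), c(0, 0))
  set.seed(42)
  sense <- names(.O_CODE)[.O_CODE != "*"]
  for (r in 1:200) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    expect_equal(unname(count_differences(c1, c2)),
                 unname(o_ng_diffs(c1, c2)), tolerance = 1e-9,
                 label = paste(c1, c2))
  }
})

test_that("compute_dnds handles identities, classification and symmetry", {
  cds <- o_random_cds(100)
  r <- compute_dnds(cds, cds)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$omega))
  expect_identical(r$classification, "undefined")
  # site conservation S + N = 3 x codons for stop-free neighbourhoods
  s <- count_sites(c("TTT", "CTT"))
  expect_equal(unname(s["S"] + s["N"]), 6, tolerance = 1e-9)
  # symmetry
  set.seed(7)
  sim <- simulate_ortholog_pairs(0.3, 0.2, n_codons = 60, seed = 5)
  a <- sim$pairs[[1]]; b <- sim$pairs[[2]]
  r1 <- compute_dnds(a, b); r2 <- compute_dnds(b, a)
  expect_equal(r1$omega, r2$omega, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("classification rule follows omega and p", {
  # omega = 0.0527 with p = 1.54e-06 must classify as negative selection
  expect_identical(classify_selection(dN = 0.0527, dS = 1, p_value = 1.54e-6),
                   "negative")
  expect_identical(classify_selection(dN = 2, dS = 1, p_value = 0.01),
                   "positive")
  expect_identical(classify_selection(dN = 0.5, dS = 1, p_value = 0.2),
                   "neutral")
  expect_identical(classify_selection(dN = 0.5, dS = 0, p_value = 0.01),
                   "undefined")
})

test_that("codon_alignment validates frame, stops and gaps", {
  expect_error(codon_alignment("ATGA", "ATGA"), "divisible")
  expect_error(codon_alignment("ATG", "ATGCCC"), "length")
  expect_error(codon_alignment("TAAATG", "ATGATG"), "stop")
  expect_warning(al <- codon_alignment("ATG---AAA", "ATGCCCAAA"), "skipped")
  expect_equal(al$n_codons, 2)
})

test_that("omega = 0 pairs differ only synonymously; t = 0 pairs identical", {
  sim0 <- simulate_ortholog_pairs(0, 0.4, n_codons = 120, n_pairs = 5,
                                  seed = 11)
  ids <- unique(sub("_[ab]$", "", names(sim0$pairs)))
  for (id in ids) {
    a <- sim0$pairs[[paste0(id, "_a")]]
    b <- sim0$pairs[[paste0(id, "_b")]]
    # every accepted event preserves the amino acid, so the proteins are
    # identical even where codons differ (NG86 pathway averaging may still
    # apportion fractional Nd across two-step synonymous paths)
    expect_identical(o_aa(o_split(a)), o_aa(o_split(b)), label = id)
    expect_false(identical(a, b) && id == ids[1])  # divergence happened
  }
  simt <- simulate_ortholog_pairs(0.5, 0, n_codons = 60, n_pairs = 3,
                                  seed = 3)
  ids <- unique(sub("_[ab]$", "", names(simt$pairs)))
  for (id in ids)
    expect_identical(simt$pairs[[paste0(id, "_a")]],
                     simt$pairs[[paste0(id, "_b")]])
  expect_error(simulate_ortholog_pairs(-0.1, 0.3), "omega")
})

test_that("screen_orthologs pairs reciprocally and classifies planted omega", {
  sim <- simulate_ortholog_pairs(0.1, 0.3, n_codons = 150, n_pairs = 4,
                                 seed = 21)
  ids <- unique(sub("_[ab]$", "", names(sim$pairs)))
  cds <- sim$pairs[paste0(ids, "_a")]
  names(cds) <- paste0("gene_", ids)
  orth <- sim$pairs[paste0(ids, "_b")]
  tab <- screen_orthologs(cds, orth)
  expect_equal(nrow(tab), length(ids))
  expect_true(all(tab$classification == "negative"))
  expect_identical(sub("gene_", "", tab$gene), sub("_b", "", tab$ortholog))
  # empty ortholog set -> empty table
  expect_equal(nrow(screen_orthologs(cds, character(0))), 0)
})
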