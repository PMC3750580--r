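# Contig mapping, read coverage under the two-mismatch rule and the
# coverage-bias test.

test_that("map_to_contigs reports exact substrings and enforces identity", {
  set.seed(41)
  ctg <- c(big = o_random_dna(3000), other = o_random_dna(1500))
  cand <- c(hit = substr(ctg[["big"]], 501, 1100))
  hits <- map_to_contigs(cand, ctg)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$contig_id, "big")
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$sstart, 501)
  expect_equal(hits$send, 1100)
  # a reverse-complement candidate is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cand[[1]])))
  hits_rc <- map_to_contigs(c(r = rc), ctg)
  expect_equal(nrow(hits_rc), 1)
  expect_identical(hits_rc$strand, "-")
  # heavily mutated candidate fails min_identity
  v <- strsplit(cand[[1]], "")[[1]]
  mut <- sample(length(v), round(length(v) * 0.2))
  v[mut] <- vapply(v[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  expect_equal(nrow(map_to_contigs(c(m = paste(v, collapse = "")), ctg)), 0)
  expect_error(map_to_contigs(cand, character(0)), "empty contig")
})

test_that("nucleotide scores agree with the brute-force Gotoh oracle", {
  set.seed(43)
  sm <- o_dna_submat()
  for (rep in 1:20) {
    a <- o_random_dna(sample(60:150, 1))
    b <- o_random_dna(sample(60:150, 1))
    # embed a shared core so local alignments are non-trivial
    core <- o_random_dna(40)
    a <- paste0(substr(a, 1, 30), core, substr(a, 31, nchar(a)))
    b <- paste0(substr(b, 1, 50), core, substr(b, 51, nchar(b)))
    got <- local_align(a, b, type = "nucleotide")$score
    want <- o_sw_score(a, b, sm, gap_open = 5, gap_ext = 2)
    expect_equal(got, want, label = paste("rep", rep))
  }
})

test_that("protein scores agree with the brute-force Gotoh oracle", {
  set.seed(47)
  B <- o_blosum62()
  for (rep in 1:20) {
    core <- o_random_aa(30)
    a <- paste0(o_random_aa(20), core, o_random_aa(25))
    b <- paste0(o_random_aa(35), core, o_random_aa(10))
    got <- local_align(a, b, type = "protein")$score
    want <- o_sw_score(a, b, B, gap_open = 11, gap_ext = 1)
    expect_equal(got, want, label = paste("rep", rep))
  }
})

test_that("compute_coverage respects the mismatch cap and conserves bases", {
  set.seed(53)
  ctg <- c(c1 = o_random_dna(4000), c2 = o_random_dna(3000))
  reads <- simulate_reads(ctg, depth = 15, read_length = 100, seed = 5)
  cov <- compute_coverage(reads, ctg)
  expect_equal(cov$depth, rep(15, 2), tolerance = 0.03)
  expect_equal(sum(cov$n_reads) * 100, attr(cov, "aligned_bases"))
  expect_equal(sum(cov$depth * cov$length), attr(cov, "aligned_bases"),
               tolerance = 1e-9)
  # no reads -> zero depth
  cov0 <- compute_coverage(character(0), ctg)
  expect_true(all(cov0$depth == 0))
  # a read with >2 mismatches everywhere goes unmapped
  r <- substr(ctg[["c1"]], 101, 200)
  v <- strsplit(r, "")[[1]]
  for (i in c(30, 50, 70)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  cov3 <- compute_coverage(c(bad = paste(v, collapse = "")), ctg)
  expect_true(all(cov3$n_reads == 0))
  # the same read with 2 mismatches maps
  v2 <- strsplit(r, "")[[1]]
  for (i in c(30, 50)) v2[i] <- setdiff(c("A", "C", "G", "T"), v2[i])[1]
  cov2 <- compute_coverage(c(ok = paste(v2, collapse = "")), ctg)
  expect_equal(sum(cov2$n_reads), 1)
  expect_equal(cov2$n_reads[cov2$contig_id == "c1"], 1)
})

test_that("welch test matches the closed form on a 3-vs-3 example", {
  x <- c(10, 12, 14); y <- c(20, 21, 19)
  res <- coverage_bias_test(x, y, n_background = 3, seed = 1)
  sx <- stats::var(x) / 3; sy <- stats::var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)
  expect_identical(res$verdict, "biased")
})

test_that("coverage_bias_test degenerate and shifted cases", {
  expect_error(coverage_bias_test(1, rep(1, 10)), "two target")
  expect_error(coverage_bias_test(c(1, 2), rep(1, 5), n_background = 10),
               "exceeds")
  # identical constant depths: p = 1 by definition
  res <- coverage_bias_test(rep(40, 5), rep(40, 100), n_background = 50,
                            seed = 2)
  expect_equal(res$p_value, 1)
  expect_equal(res$t, 0)
  expect_identical(res$verdict, "consistent")
  # clear 2x shift is detected
  set.seed(3)
  tgt <- stats::rnorm(14, 80, 4)
  bg <- stats::rnorm(1200, 40, 4)
  res2 <- coverage_bias_test(tgt, bg, n_background = 1000, seed = 4)
  expect_identical(res2$verdict, "biased")
})

test_that("mito screen flags only mito-like candidates", {
  set.seed(59)
  mito <- o_random_dna(2000)
  cands <- c(numt = substr(mito, 301, 800), clean = o_random_dna(500))
  res <- mito_screen(cands, mito)
  expect_identical(res$not_numt_like, "clean")
  expect_true("numt" %in% res$hits$candidate_id)
})
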