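# Determinism, truth consistency and hit-table behaviour of the generator.

test_that("gene family simulation is deterministic and respects depth 0", {
  cfg <- simulation_config(seed = 101, n_host_genes = 2,
                           n_planted_hgt = c(bacteria = 1),
                           taxon_counts = c(arthropod = 2,
                                            other_eukaryote = 2, fungi = 2,
                                            bacteria = 4),
                           protein_length = 80, n_orphans = 0)
  f1 <- simulate_gene_families(cfg)
  f2 <- simulate_gene_families(cfg)
  expect_identical(f1$segments, f2$segments)
  expect_identical(f1$alignments, f2$alignments)
  # depth 0: all leaves identical to each other
  cfg0 <- simulation_config(seed = 102, n_host_genes = 1,
                            n_planted_hgt = c(bacteria = 0),
                            tree_depth = 0, protein_length = 60,
                            n_orphans = 0)
  cfg0$taxon_counts <- c(arthropod = 2, other_eukaryote = 2, fungi = 2,
                         bacteria = 2)
  # zero within-group branch lengths are not configurable; force them by
  # checking the zero-rate limit through the evolution model directly:
  # with tree_depth = 0 the backbone contributes nothing, so leaves differ
  # only through within-group branches; instead assert the backbone-free
  # invariant that alignment rows are equal length and gap-free
  f0 <- simulate_gene_families(cfg0)
  aln <- f0$alignments[[1]]
  expect_equal(length(unique(nchar(aln))), 1)
  expect_false(any(grepl("-", aln)))
  # configuration errors
  expect_error(simulation_config(
    n_planted_hgt = c(bacteria = 1),
    taxon_counts = c(arthropod = 2, other_eukaryote = 2, fungi = 2,
                     bacteria = 0)), "zero taxa")
})

test_that("planted truth resolves against emitted artifacts", {
  cfg <- simulation_config(seed = 107, n_host_genes = 3,
                           n_planted_hgt = c(bacteria = 1, fungi = 1),
                           protein_length = 120, n_orphans = 2)
  ds <- synthetic_dataset(cfg, n_host_contigs = 4,
                          host_contig_len = c(1500, 2000))
  # every planted HGT id exists among segments and has a contig
  expect_true(all(ds$truth$hgt_segments %in% names(ds$segments)))
  for (id in ds$truth$hgt_segments) {
    ctg <- ds$contigs[[ds$truth$segment_contig[[id]]]]
    expect_true(grepl(ds$segments[[id]], ctg, fixed = TRUE), label = id)
  }
  # intron coordinates lie within their contig
  intr <- ds$truth$introns
  expect_true(all(intr$end <= nchar(ds$structural$contigs[["ctg_single"]])))
  # planted contig reproduces the transcript after removing truth introns
  ctg <- ds$structural$contigs[["ctg_single"]]
  keep <- rep(TRUE, nchar(ctg))
  for (i in seq_len(nrow(intr))) keep[(intr$start[i] + 1):intr$end[i]] <- FALSE
  degapped <- paste(strsplit(ctg, "")[[1]][keep], collapse = "")
  expect_true(grepl(ds$structural$transcripts[[1]], degapped, fixed = TRUE))
  # counts truth: DE genes are the planted set
  expect_setequal(ds$truth$de_genes, ds$truth$hgt_segments)
  # dataset determinism at file level
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(synthetic_dataset(cfg, n_host_contigs = 4,
                                  host_contig_len = c(1500, 2000)), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("derive_hit_table ranks exact matches first and skips orphans", {
  cfg <- simulation_config(seed = 109, n_host_genes = 2,
                           n_planted_hgt = c(bacteria = 1),
                           protein_length = 100, n_orphans = 0)
  fam <- simulate_gene_families(cfg)
  # a segment that is the exact CDS of one reference protein
  ref1 <- fam$reference[1]
  seg <- withr::with_seed(1, paste(
    vapply(strsplit(ref1[[1]], "")[[1]], function(a)
      sample(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE == a], 1), character(1)), collapse = ""))
  hits <- derive_hit_table(c(exact = seg), fam$reference, fam$taxmap)
  top <- hits[hits$query_id == "exact", ][1, ]
  expect_identical(top$subject_id, names(ref1))
  expect_equal(top$percent_identity, 100)
  # segments without any homolog produce no records
  hits2 <- derive_hit_table(c(orphan = o_random_dna(300)), fam$reference,
                            fam$taxmap)
  expect_equal(nrow(hits2[hits2$query_id == "orphan", ]), 0)
  # sub-codon segments are skipped with a warning
  expect_warning(derive_hit_table(c(tiny = "AT"), fam$reference,
                                  fam$taxmap), "skipped")
})

test_that("hit-table scores agree with the brute-force protein DP", {
  set.seed(113)
  B <- o_blosum62()
  taxmap <- data.frame(species = "sp1", taxon_group = "bacteria")
  for (rep in 1:8) {
    prot <- o_random_aa(sample(50:120, 1))
    # query: CDS of a mutated copy so alignment is non-trivial
    v <- strsplit(prot, "")[[1]]
    idx <- sample(length(v), round(length(v) * 0.2))
    v[idx] <- vapply(v[idx], function(a) sample(setdiff(
      strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], a), 1), character(1))
    mut <- paste(v, collapse = "")
    cds <- paste(vapply(strsplit(mut, "")[[1]], function(a)
      sample(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE == a], 1), character(1)), collapse = "")
    hits <- derive_hit_table(c(q = cds), c("sp1|p" = prot), taxmap)
    if (!nrow(hits)) next
    want <- o_sw_score(mut, prot, B, gap_open = 11, gap_ext = 1)
    # bitscore back to raw score: S = (bits*log(2) + log(K)) / lambda
    raw <- (hits$bitscore[1] * log(2) + log(0.041)) / 0.267
    expect_lt(abs(raw - want), 0.5)  # bitscore rounding only
  }
})

test_that("read simulation hits requested depth and is reproducible", {
  set.seed(127)
  ctg <- c(a = o_random_dna(10000))
  r1 <- simulate_reads(ctg, depth = 40, read_length = 100, seed = 5)
  r2 <- simulate_reads(ctg, depth = 40, read_length = 100, seed = 5)
  expect_identical(r1, r2)
  expect_equal(length(r1), 4000)
  expect_error(simulate_reads(c(a = o_random_dna(50)), 10, 100), "exceeds")
  # per-contig depth vector supports coverage-biased contaminants
  two <- c(a = o_random_dna(4000), b = o_random_dna(4000))
  rr <- simulate_reads(two, depth = c(88, 42), read_length = 100, seed = 9)
  cov <- compute_coverage(rr, two)
  ratio <- cov$depth[cov$contig_id == "a"] / cov$depth[cov$contig_id == "b"]
  expect_equal(ratio, 88 / 42, tolerance = 0.05)
})
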