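# Synteny blocks, transfer summaries, intron detection and the operon
# heuristic.

test_that("compare_segments finds exact donor copies and nothing spurious", {
  set.seed(61)
  gene <- o_random_cds(150)
  donor <- paste0(o_random_dna(400), gene, o_random_dna(400))
  contig <- paste0(o_random_dna(200), gene, o_random_dna(200))
  bl <- compare_segments(contig, donor)
  expect_equal(nrow(bl), 1)
  expect_gte(bl$identity[1], 99)
  expect_lte(bl$q_start[1], 210)
  expect_gte(bl$q_end[1], 190 + nchar(gene))
  # unrelated sequences share no translated 7-mer block
  expect_equal(nrow(compare_segments(o_random_dna(300), o_random_dna(300))),
               0)
  expect_error(compare_segments("AT", donor), "codon")
})

test_that("spacer-deleted transfers reproduce truth", {
  # (the 20-replicate sweep lives in the acceptance suite)
  for (seed in c(2, 5, 8, 13, 21)) {
    cfg <- simulation_config(seed = seed)
    pc <- plant_contig(cfg)
    bl <- compare_segments(pc$contigs[["ctg_multi"]], pc$donor_seq[[1]])
    rep_out <- summarize_transfer(bl, pc$donor_ann)
    expect_identical(sort(rep_out$co_transferred),
                     sort(pc$truth$co_transferred), label = seed)
    expect_equal(rep_out$missing_intergenic$start, pc$truth$spacers$start,
                 label = seed)
    expect_equal(rep_out$missing_intergenic$end, pc$truth$spacers$end,
                 label = seed)
  }
})

test_that("fully conserved segments report no missing intergenic DNA", {
  set.seed(67)
  g1 <- o_random_cds(120); g2 <- o_random_cds(100)
  spacer <- o_random_dna(120)
  segment <- paste0(g1, spacer, g2)
  donor <- paste0(o_random_dna(300), segment, o_random_dna(300))
  contig <- paste0(o_random_dna(250), segment, o_random_dna(250))
  ann <- data.frame(seq_id = "d", start = c(300, 300 + nchar(g1) + 120),
                    end = c(300 + nchar(g1),
                            300 + nchar(g1) + 120 + nchar(g2)),
                    strand = "+", gene = c("gA", "gB"))
  bl <- compare_segments(contig, donor)
  rep_out <- summarize_transfer(bl, ann)
  expect_setequal(rep_out$co_transferred, c("gA", "gB"))
  expect_equal(nrow(rep_out$missing_intergenic), 0)
  # empty blocks -> empty report
  empty <- summarize_transfer(bl[0, ], ann)
  expect_length(empty$co_transferred, 0)
})

test_that("intron planting and detection are exact inverses", {
  for (seed in c(2, 9, 31)) {
    cfg <- simulation_config(seed = seed, intron_lengths = c(105, 117, 370))
    pc <- plant_contig(cfg)
    ic <- detect_introns(pc$transcripts[[1]], pc$contigs[["ctg_single"]])
    expect_equal(ic$start, pc$truth$introns$start, label = seed)
    expect_equal(ic$length, pc$truth$introns$length, label = seed)
    expect_true(all(ic$canonical), label = seed)
  }
  # no introns: transcript equals its genomic span, zero calls
  cfg0 <- simulation_config(seed = 3, intron_lengths = numeric(0))
  pc0 <- plant_contig(cfg0)
  expect_equal(nrow(detect_introns(pc0$transcripts[[1]],
                                   pc0$contigs[["ctg_single"]])), 0)
  expect_error(simulation_config(intron_lengths = c(3)), ">= 4")
})

test_that("sub-threshold genomic gaps are not called introns", {
  set.seed(71)
  tr <- o_random_dna(300)
  # insert a 10 bp gap (below min_intron = 30)
  genomic <- paste0(substr(tr, 1, 150), "GTCCCCCCAG", substr(tr, 151, 300))
  contig <- paste0(o_random_dna(100), genomic, o_random_dna(100))
  ic <- detect_introns(tr, contig)
  expect_equal(nrow(ic), 0)
  # unmappable transcript errors
  expect_error(detect_introns(o_random_dna(200), o_random_dna(1000)),
               "not mappable")
})

test_that("operon heuristic equals a brute-force scan", {
  ann <- data.frame(seq_id = "s", start = c(0, 500, 1200, 3000, 3400),
                    end = c(400, 1100, 1500, 3300, 3900),
                    strand = c("+", "+", "+", "-", "-"),
                    gene = paste0("g", 1:5))
  ops <- predict_operons(ann, max_gap = 200, min_genes = 2)
  expect_length(ops, 2)
  expect_equal(ops[[1]]$gene, c("g1", "g2", "g3"))
  expect_equal(ops[[2]]$gene, c("g4", "g5"))
  # strand flip breaks a run
  ann2 <- ann; ann2$strand[2] <- "-"
  ops2 <- predict_operons(ann2, max_gap = 200, min_genes = 2)
  expect_false(any(vapply(ops2, function(o)
    all(c("g1", "g2") %in% o$gene), logical(1))))
  # randomized annotations vs an independent linear scan
  set.seed(73)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    starts <- sort(sample(0:5000, n))
    ends <- starts + sample(100:400, n, TRUE)
    ends <- pmin(ends, c(starts[-1], Inf) - 1)
    keep <- ends > starts
    a <- data.frame(seq_id = "s", start = starts[keep], end = ends[keep],
                    strand = sample(c("+", "-"), sum(keep), TRUE),
                    gene = paste0("g", seq_len(sum(keep))))
    got <- predict_operons(a, max_gap = 150, min_genes = 2)
    # oracle: explicit pairwise chain walk
    want <- list(); cur <- c(1)
    if (nrow(a) >= 2) {
      for (i in 2:nrow(a)) {
        if (a$strand[i] == a$strand[cur[length(cur)]] &&
            a$start[i] - a$end[cur[length(cur)]] <= 150) {
          cur <- c(cur, i)
        } else {
          if (length(cur) >= 2) want[[length(want) + 1]] <- a$gene[cur]
          cur <- i
        }
      }
    }
    if (length(cur) >= 2) want[[length(want) + 1]] <- a$gene[cur]
    expect_equal(lapply(got, function(o) o$gene), want, label = rep)
  }
})

test_that("GFF3 annotations round-trip bit-exactly", {
  ann <- data.frame(seq_id = "donor_chr1", start = c(500L, 1200L),
                    end = c(950L, 1800L), strand = c("+", "-"),
                    gene = c("gene_a", "gene_b"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff3(path)
  expect_equal(back[order(back$start), ], ann[order(ann$start), ],
               ignore_attr = TRUE)
})
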