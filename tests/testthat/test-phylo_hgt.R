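# Alignment trimming, Poisson distances, NJ round trips, bootstrap and the
# nesting classifier against the brute-force oracle.

test_that("trim_conserved_blocks matches a column-scan oracle", {
  aln <- c(a = "AAAAAAAAAAAA", b = "AAAAAAAAAAAA", c = "AAAAAAAAAAAA")
  tr <- trim_conserved_blocks(aln, 0.5, 5, 0.5)
  expect_identical(tr$alignment, aln)
  # an all-gap column is removed (with the run-length floor relaxed)
  aln2 <- c(a = "AAAAA-AAAAAA", b = "CCCCC-CCCCCC", c = "AAAAA-AAAAAA")
  tr2 <- trim_conserved_blocks(aln2, 0.5, 1, 0.5)
  expect_false(grepl("-", tr2$alignment[1]))
  expect_error(trim_conserved_blocks(
    c(a = "-A", b = "-C", c = "-G"), 0.2, 5, 0.9), "no conserved blocks")
  # random alignments against an independent per-column classifier
  set.seed(31)
  for (rep in 1:10) {
    rows <- replicate(4, paste(sample(c("A", "C", "D", "-"), 60, TRUE,
                                      prob = c(.4, .25, .15, .2)),
                               collapse = ""))
    names(rows) <- paste0("t", 1:4)
    m <- do.call(rbind, strsplit(rows, ""))
    good <- logical(60)
    for (j in 1:60) {
      col <- m[, j]
      gaps <- mean(col == "-")
      nong <- col[col != "-"]
      maj <- if (length(nong)) max(table(nong)) / 4 else 0
      good[j] <- gaps <= 0.5 && maj >= 0.5
    }
    runs <- rle(good)
    keep <- rep(runs$values & runs$lengths >= 10, runs$lengths)
    if (!any(keep)) {
      expect_error(trim_conserved_blocks(rows, 0.5, 10, 0.5))
    } else {
      got <- trim_conserved_blocks(rows, 0.5, 10, 0.5)
      want <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
      expect_identical(unname(got$alignment), unname(want))
    }
  }
})

test_that("Poisson distances follow the closed form and saturate", {
  aln <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(c(rep("C", 10), rep("A", 90)), collapse = ""))
  D <- compute_distance_matrix(aln)
  expect_equal(D["a", "b"], -log(0.9), tolerance = 1e-9)
  expect_equal(D["a", "a"], 0)
  expect_equal(D, t(D))
  # monotone in p below the cap
  ds <- vapply(c(5, 20, 50), function(k) {
    x <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(c(rep("C", k), rep("A", 100 - k)), collapse = ""))
    compute_distance_matrix(x)[1, 2]
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  # saturation cap with warning
  sat <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(rep("C", 100), collapse = ""))
  expect_warning(Dc <- compute_distance_matrix(sat), "capped")
  expect_equal(Dc[1, 2], -log(1 - 0.95), tolerance = 1e-9)
  # gap-only overlap errors
  expect_error(compute_distance_matrix(c(a = "A-", b = "-C")),
               "comparable")
})

test_that("NJ recovers additive matrices exactly", {
  # fixed 4-taxon additive tree ((A:1,B:2):1,(C:3,D:1))
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D <- ape::cophenetic.phylo(tr)
  nj <- build_nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(nj))), 0)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "three")
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(build_nj_tree(Dbad), "symmetric")
})

test_that("bootstrap supports are deterministic and sane", {
  set.seed(5)
  fam <- simulate_gene_families(simulation_config(
    seed = 5, n_host_genes = 0, n_planted_hgt = c(bacteria = 1),
    taxon_counts = c(arthropod = 2, other_eukaryote = 2, fungi = 2,
                     bacteria = 4), protein_length = 150, n_orphans = 0))
  aln <- fam$alignments[[1]]
  t1 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # n_reps = 1: supports are 0 or 100
  t3 <- bootstrap_support(aln, n_reps = 1, seed = 1)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
  # leaf-order permutation leaves supports on the same splits
  perm <- sample(names(aln))
  t4 <- bootstrap_support(aln[perm], n_reps = 50, seed = 9)
  expect_setequal(t4$tip.label, t1$tip.label)
})

test_that("nesting classifier handles the three canonical patterns", {
  groups <- c(q = "arthropod", b1 = "bacteria", b2 = "bacteria",
              b3 = "bacteria", b4 = "bacteria", b5 = "bacteria",
              e1 = "other_eukaryote", e2 = "other_eukaryote",
              e3 = "other_eukaryote",
              a1 = "arthropod", a2 = "arthropod", n1 = "other_metazoan")
  # nested with basal donors
  t1 <- ape::read.tree(text = paste0(
    "(((q:1,(b1:1,b2:1):1):1,((b3:1,b4:1):1,b5:1):1):2,",
    "(e1:1,(e2:1,e3:1):1):2);"))
  c1 <- classify_hgt_topology(t1, "q", groups)
  expect_identical(c1$verdict, "hgt")
  expect_identical(c1$donor_group, "bacteria")
  expect_gte(c1$n_basal_donor_species, 3)
  # query sister to arthropods, bacteria distant
  t2 <- ape::read.tree(text = paste0(
    "(((q:1,(a1:1,a2:1):1):1,(e1:1,e2:1):1):2,",
    "((b1:1,b2:1):1,(b3:1,(b4:1,b5:1):1):1):2);"))
  c2 <- classify_hgt_topology(t2, "q", groups)
  expect_identical(c2$verdict, "no_hgt")
  # pre-speciation transfer: query + metazoan relative nested in bacteria
  t3 <- ape::read.tree(text = paste0(
    "((((q:1,n1:1):1,(b1:1,b2:1):1):1,((b3:1,b4:1):1,b5:1):1):2,",
    "(e1:1,(e2:1,e3:1):1):2);"))
  c3 <- classify_hgt_topology(t3, "q", groups,
                              recipient_groups = c("arthropod",
                                                   "other_metazoan"))
  expect_identical(c3$verdict, "hgt")
  expect_identical(c3$donor_group, "bacteria")
  expect_match(c3$notes, "pre-speciation")
  expect_error(classify_hgt_topology(t1, "zz", groups), "absent")
})

test_that("classifier agrees with the brute-force oracle (small trees)", {
  set.seed(17)
  params <- list(min_basal_donor_species = 2, min_support = 70)
  for (n in c(5, 6, 7)) {
    for (rep in 1:40) {
      tr <- ape::rtree(n)
      tr$tip.label <- c("q", paste0("t", seq_len(n - 1)))
      g <- c(q = "arthropod",
             stats::setNames(sample(c("bacteria", "arthropod"), n - 1, TRUE),
                             paste0("t", seq_len(n - 1))))
      a <- classify_hgt_topology(tr, "q", g,
                                 min_basal_donor_species = 2,
                                 donor_groups = "bacteria")
      b <- brute_force_classifier(tr, "q", g,
                                  min_basal_donor_species = 2,
                                  donor_groups = "bacteria")
      expect_identical(a$verdict, b$verdict, label = ape::write.tree(tr))
      if (a$verdict == "hgt") {
        expect_identical(a$donor_group, b$donor_group)
        expect_identical(a$n_basal_donor_species, b$n_basal_donor_species)
      }
    }
  }
  # star tree with zero supports is ambiguous
  star <- ape::read.tree(text = "(q:1,b1:1,b2:1,b3:1,b4:1,e1:1);")
  star$node.label <- "0"
  g <- c(q = "arthropod", b1 = "bacteria", b2 = "bacteria", b3 = "bacteria",
         b4 = "bacteria", e1 = "other_eukaryote")
  expect_identical(classify_hgt_topology(star, "q", g)$verdict, "ambiguous")
})

test_that("planted families are recovered with no false positives", {
  cfg <- simulation_config(seed = 19, n_host_genes = 6,
                           n_planted_hgt = c(bacteria = 3, fungi = 2),
                           n_orphans = 0, protein_length = 200)
  fam <- simulate_gene_families(cfg)
  groups <- stats::setNames(fam$taxmap$taxon_group, fam$taxmap$species)
  for (i in seq_len(nrow(fam$truth))) {
    id <- fam$truth$segment_id[i]
    tree <- bootstrap_support(fam$alignments[[i]], n_reps = 100,
                              seed = 100 + i)
    g <- c(groups, stats::setNames("arthropod", id))
    call <- classify_hgt_topology(tree, id, g)
    if (fam$truth$is_hgt[i]) {
      expect_identical(call$verdict, "hgt", label = id)
      expect_identical(call$donor_group, fam$truth$donor_group[i],
                       label = id)
    } else {
      expect_false(call$verdict == "hgt", label = id)
    }
  }
})

test_that("planted query's nearest leaves are donors (patristic check)", {
  cfg <- simulation_config(
    seed = 23, n_host_genes = 0, n_planted_hgt = c(bacteria = 3),
    taxon_counts = c(arthropod = 0, other_eukaryote = 4, fungi = 0,
                     bacteria = 6), n_orphans = 0)
  fam <- simulate_gene_families(cfg)
  for (i in 1:3) {
    tr <- fam$trees[[i]]
    D <- ape::cophenetic.phylo(tr)
    q <- fam$truth$segment_id[i]
    nn <- names(sort(D[q, setdiff(rownames(D), q)]))[1:2]
    expect_true(all(grepl("^bacteria", nn)), label = q)
  }
})
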