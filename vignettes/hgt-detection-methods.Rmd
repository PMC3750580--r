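---
title: "Methods: detecting horizontal gene transfer with hgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting horizontal gene transfer with hgtscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Expressed-sequence surveys of a eukaryote (the motivating case is a
crustacean) occasionally turn up genes whose closest relatives are bacterial
or fungal rather than metazoan. Three explanations compete: genuine
horizontal gene transfer (HGT) into the host genome, contamination of the
RNA libraries, and plain phylogenetic noise. `hgtscan` implements the full
evidence chain used to separate them:

1. **Homology filter cascade.** Translated similarity hits against a
   taxonomy-labelled protein set are thresholded (E ≤ 1e-20, identity ≥
   25%, aligned length ≥ 25 residues, all inclusive). Segments with no
   retained homolog are set aside; segments scoring best against the
   recipient's own lineage (arthropods) are removed as vertically
   inherited; segments with fewer than 10 distinct subject species are
   removed as untestable by phylogeny. Every segment ends in exactly one
   terminal bucket, so stage counts always sum to the input — an invariant
   the tests enforce.
2. **Phylogenetic nesting.** For each surviving candidate, a
   neighbor-joining tree is built from Poisson-corrected distances
   (d = −ln(1 − p) on pairwise mismatch fractions over shared non-gap
   columns, capped at p = 0.95), with bootstrap supports from column
   resampling. A candidate is called HGT when its leaf is *nested* inside a
   well-supported clade of one donor group while additional species of that
   group branch basally. Recipient-lineage leaves inside the donor clade
   are tolerated, which covers transfers predating the recipient's
   speciation (related metazoans then travel with the query).
3. **Genomic verification.** A transcript-level candidate might still be a
   contaminant. Two checks: the candidate must map to an assembly contig at
   strict thresholds (E ≤ 1e-40, identity ≥ 90%), and the candidate-bearing
   contigs must show the same shotgun read coverage as randomly selected
   background contigs (two-sided Welch t-test on per-contig mean depth;
   "consistent" ⇔ p > α). A mitochondrial screen flags NUMT-like
   candidates.
4. **Annotative stages.** Structure analysis (co-transferred gene
   clusters, lost intergenic DNA, introns, operon heuristics), a
   Nei–Gojobori selection screen, and FPKM-based differential expression
   characterise the verified calls. They support interpretation and never
   veto a call.

## The synthetic world

Real surveys of this kind hinge on external databases and wet-lab
verification, so the package ships a generator that emulates each input
with known ground truth. Its defaults are a *stated world*, fixed once:

* **Gene families.** 50 vertically inherited families plus 5 bacterial and
  2 fungal planted transfers (echoing the dominant-bacterial donor mix of
  published shrimp surveys at reduced scale). Each family evolves a
  200-residue protein along a species tree whose four groups (arthropods,
  other eukaryotes, fungi, bacteria) are joined by a fixed backbone with
  stem lengths `tree_depth/2` (default depth 0.5 substitutions/site);
  within-group branches are uniform on 0.03–0.08. Evolution is indel-free
  under a Poisson model (per site, substitution probability 1 − e^(−b),
  uniform replacement), so alignments are gap-free and column-homologous by
  construction — a green tree test therefore says nothing about alignment
  error on real data. The recipient gene is grafted sister to the
  arthropods (vertical) or as a cherry inside the donor subtree (planted),
  with the cherry stem kept ≥ 0.05 so bootstrap can resolve the nesting.
* **Hit tables** come from an in-repo translated search: affine-gap
  Smith–Waterman (BLOSUM62, gap open 11 / extend 1; Biostrings does the
  DP), best of six frames, with fixed Karlin–Altschul parameters
  (λ = 0.267, K = 0.041, database size = total reference residues) so no
  BLAST binary is needed. Candidate pairs are pre-screened by ≥ 2 shared
  amino-acid 4-mers; like any seeded search this can miss homologs below
  roughly 30% identity, which mirrors real heuristic behaviour.
* **Contigs** carry each planted gene with 500 bp host flanks; one contig
  carries a single-gene transfer with GT..AG introns (default lengths
  105 and 117 bp) planted at positions chosen to avoid splice ambiguity
  (the transcript base after each insertion point must differ from the
  intron's leading G — otherwise exact recovery is ill-posed, not merely
  hard); another carries a three-gene donor segment whose intergenic
  spacers (150–400 bp in the donor) are deleted, emulating transfer via
  mature transcripts. The donor genome keeps the spacers and a GFF3
  annotation.
* **Reads** are error-free, uniform, both strands, at 40× by default; the
  per-contig read count is the deterministic round(depth·L/ℓ), so realised
  mean coverage equals the request up to rounding (an optional uniform
  error rate exists for robustness checks).
* **Ortholog pairs** evolve under HKY proposals (κ = 2 fixed, uniform base
  frequencies) thinned by ω: synonymous proposals always accepted,
  nonsynonymous with probability ω, stop-creating rejected. NG86 counting
  under this κ recovers ω with a mild downward bias (≈ 10%), well inside
  the 20% acceptance band; at ω = 0 every accepted event is synonymous, so
  the two proteins are identical even though NG86's pathway averaging may
  still apportion fractional nonsynonymous counts to two-step synonymous
  paths.
* **Counts** are Poisson around per-gene means (default 500), with planted
  genes carrying an 8-fold change in the zoea/mysis stages — the
  development-stage pattern reported for transferred genes in shrimp.

All randomness flows from one seed through fixed per-operation offsets;
writing a dataset twice gives byte-identical files.

## Numerical and design choices

* **NG86 rather than a κ-corrected estimator.** The approximate counting
  method is exactly specifiable and oracle-testable (the suite checks all
  61×61 sense-codon pairs against explicit enumeration). Users wanting
  transition-corrected rates can classify externally computed (dN, dS) via
  `classify_selection()`. Fisher's exact test runs on the site/substitution
  2×2 table with counts rounded half-up; rates always use unrounded values.
  dS = 0 leaves ω undefined (`NA`), not infinite, so summaries stay finite.
* **Audic–Claverie exact test for expression.** With one library per stage
  there are no replicates; the negative-binomial identity
  P(Y ≤ y | x) = pnbinom(y, x + 1, N₁/(N₁+N₂)) gives exact two-sided
  p-values under the minimum-likelihood convention (summing all outcomes no
  more likely than the observed one, as `fisher.test` does) — doubling the
  smaller tail was considered and rejected as markedly conservative for
  these discrete distributions (attained size ≈ half nominal). The null
  rejection rate at p ≤ 0.001 sits near 0.001–0.0015 under a Poisson
  null. Results are
  method-dependent; a negative-binomial GLM package would flag a somewhat
  different set on real overdispersed data.
* **Expression ratios.** FPKM = 10⁹·C/(N·L). Ratios are exact where both
  FPKMs are positive; when one side is zero, the smallest nonzero FPKM of
  the stage pair is added to both sides, so "expressed vs silent" genes get
  large finite ratios instead of infinities.
* **Welch, not Student.** The coverage comparison pits ~14 target contigs
  against up to 1000 background contigs; pooled-variance assumptions are
  inappropriate at that imbalance. "No bias" is operationalised as
  p > α (two-sided), with the degenerate all-equal case defined as p = 1.
* **Nesting rule quantification.** "Many donor species basal" becomes
  ≥ 3 distinct donor species outside the nesting clade (configurable);
  nesting-clade support ≥ 70% bootstrap by default; clades without an
  assessed support (externally supplied trees) pass the support check.
  Rooting uses a designated outgroup group when present, else midpoint.
  Supports are carried by bipartition, not node index, so rooting cannot
  misattach them. A brute-force classifier that enumerates every clade
  explicitly ships in the package and is held equal to the production
  classifier on exhaustive small instances (all topologies × 2-group
  labelings at 5–6 leaves; sampled 7–8 leaf instances — full 8-leaf
  enumeration is beyond the 1-CPU time budget).
* **NJ via ape.** Saitou–Nei agglomeration is delegated to `ape::nj`
  (negative branch estimates clamped to 0 afterwards); round-trip
  exactness on additive matrices is pinned by tests rather than by
  reimplementation. ML/Bayesian tree methods are out of scope; externally
  built newick trees can be fed straight to the classifier.
* **Structure thresholds.** Co-transfer requires ≥ 50% of a donor gene
  covered by translated synteny blocks; an intergenic interval counts as
  "missing" below 20% coverage. These operationalise qualitative
  conserved/not-conserved calls; the source analyses give no cutoffs.
  Intron calls require ≥ 30 bp genomic gaps with zero transcript gap
  between chained exact exon matches (≥ 20 bp); smaller gaps are alignment
  gaps, not introns. The operon predictor is a same-strand/≤ 200 bp-gap
  heuristic — a stand-in for a curated operon database, not a
  reimplementation of one.

## What a green suite establishes — and what it does not

The acceptance tests show that, in a world where the planted signal is
clean (gap-free alignments, donor-only similarity, error-free reads,
Poisson counts), the pipeline recovers exactly the planted transfers with
calibrated error rates, and that the arithmetic building blocks (NG86
counts, FPKM, BH step-up, Welch t, NJ on additive matrices) are exact
against independent oracles. They do not establish robustness to alignment
error, compositional bias, assembly artefacts, overdispersed expression, or
databases with mislabelled taxonomy — all of which matter on real data and
are deliberately outside the generator's world.
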