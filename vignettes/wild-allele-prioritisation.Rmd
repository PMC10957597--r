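---
title: "Prioritising wild-relative alleles of drought and salt response genes"
author: "WildAlleleScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising wild-relative alleles of drought and salt response genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WildAlleleScan)
```

## The problem

Crop domestication narrows genetic diversity, and alleles conferring
tolerance to drought or salinity are among those that can be lost. Wild
relatives — here modelled on the wild tomato *Solanum chilense*, a
self-incompatible species of hyper-arid Andean habitats — retain such
alleles. Given an annotated wild-relative genome, a cultivated reference, and
a panel of resequenced accessions spanning the related species, the pipeline
asks: *which amino acid variants private to the wild relative are predicted
to matter functionally, and how are they distributed across the wider species
group?*

The procedure is a chain of well-defined steps, each exposed as a package
function and each testable in isolation:

1. **Gene selection** (`searchGOTerms`, `selectGenes`). Flat keyword search
   (case-insensitive substring) over GO term names — salt, salinity, water,
   drought — selects the candidate genes. No GO-graph traversal is performed:
   the selection is over the terms actually annotated, which is what a flat
   annotation table supports and keeps the gene set auditable.
2. **Ortholog matching** (`bestHit`, `matchOrthologs`). Each selected wild
   gene is matched to its reference counterpart by affine-gap local alignment
   subject to a query-coverage floor of 90% on the single best-scoring local
   alignment, mirroring per-HSP query-coverage semantics. Nucleotide scoring
   is +2/−3 with gap open 5, extend 2; protein mode uses BLOSUM62 with open
   11, extend 1 — parameters chosen to mirror common BLAST defaults. A
   tabular import path (`importHits`) accepts externally computed hits.
3. **Variant extraction** (`alignProteinPair`, `extractAAVariants`). The
   protein pair is globally aligned (BLOSUM62, gap open 10, extend 0.5;
   externally produced aligned FASTA is accepted via
   `readProteinAlignment`). A column walk emits one substitution per
   mismatch column, and one insertion or deletion per maximal gap run.
   Positions count ungapped *reference* residues, because the downstream
   back-translation targets the reference genome; labels put the wild
   residue first (`P63A` = wild proline, reference position 63, reference
   alanine). Adjacent mismatch columns stay separate single-residue
   substitutions rather than being merged into multi-residue events.
4. **Impact filtering** (`proveanScreen`, `classifyImpactful`). Two stages:
   a PROVEAN screen (score strictly below −2.5) retaining genes with at
   least one passing variant, then the triple rule — PROVEAN < −2.5 **and**
   SIFT4G < 0.05 **and** PPVED > 0.5, all strict. Strictness follows the
   inequality signs of the published rule; the choice is immaterial on the
   published table (no score sits exactly on a threshold) but a PPVED of
   exactly 0.51 passes, which the published bolding confirms. Missing scores
   fail conservatively and are counted.
5. **Back-translation** (`proteinPosToCodon`, `aaVariantToSNVs`). A
   substitution at reference protein position *p* maps to codon bases
   3(p−1)+1..3p of the spliced CDS, located in the genome through the gene
   model (codons may span exon junctions; minus-strand positions descend).
   The wild codon aligned to *p* is taken through the protein alignment
   column — not by raw position arithmetic — so indels elsewhere in the pair
   do not shift the correspondence. One SNV is emitted per differing codon
   base, expressed VCF-style on the forward strand. Every back-translated
   variant is validated by `roundtripCheck`: apply the SNVs to the genome,
   re-splice, translate, and require the wild residue at *p* and reference
   residues elsewhere. Indels are not back-translated (the published variant
   table contains substitutions only); variants whose codon bases cannot be
   retrieved are dropped with a logged reason.
6. **Accession scan** (`scanAccession`, `homozygousGeneFilter`,
   `buildSharingMatrix`). SNVs are matched exactly on (chrom, pos, ref, alt)
   against each accession's VCF, with multi-allelic records decomposed
   first. A site absent from a resequencing VCF is called homozygous
   reference — such VCFs record non-reference calls only; a strict mode
   treating absence as missing sits behind a flag. An accession *shares* the
   wild amino acid only when homozygous-ALT at **every** SNV of the codon
   change, so the full wild codon is reconstructed; only homozygous evidence
   counts, and genes in which no variant has any homozygous carrier are
   eliminated. The sharing proportion divides by all accessions of a species
   (missing counts as not sharing), which keeps the denominator reproducible
   without per-cell call-rate bookkeeping.
7. **Clustering and report** (`clusterSpecies`, `renderHeatmap`). Species
   columns are clustered with average linkage on Euclidean distances —
   unstated in the original analysis, so the choice is recorded in the
   output metadata. The leaf order is canonicalised (smaller subtree first,
   ties by smallest label) so it is a pure function of the input. The
   heatmap is a side output; every assertion runs against its ordered TSV
   twin, which is byte-stable across runs. Variant-axis clustering is off by
   default and available behind a flag.
8. **Genome size** (`findPeaks`, `estimateGenomeSize`). From a k-mer
   occurrence histogram, total k-mer observations are Σ occ·count; the
   estimate is (total − artifact) / homozygous coverage, where the artifact
   part is the same sum below the cutoff. This reading of "k-mers counted"
   as *observations* is the only one consistent with the published worked
   example: (133×10⁹ − 18×10⁹) / 136 = 845.6 Mbp. Peaks are local maxima of
   a window-3 moving average; two maxima in a 2:1 occurrence ratio (±25%, a
   tolerance robust to discreteness) are reported as the heterozygous and
   homozygous peaks. The cutoff is user-supplied (30 in the worked example)
   or auto-selected at the first local minimum. No mixture model is fitted:
   the estimator reproduces the simple spectrum arithmetic, not a
   GenomeScope-style fit.

`runPipeline` chains stages 1–7 from one configuration (YAML or list), writes
every intermediate as a headered TSV plus a manifest with row counts and
echoed thresholds, and reproduces byte-identical TSVs on identical inputs.
The package's interface is these functions; the pipeline is driven from R or
`Rscript` rather than a separate shell tool.

## The synthetic data generator

All inputs can be generated with recorded ground truth (`syntheticConfig`,
`simulateReference`, `simulateWildProteome`, `simulateAccessions`,
`simulateKmerHistogram`), so the whole chain is testable without any
download. The generator is first-class, validated code: its outputs are
byte-identical under a fixed seed, and its own invariants (CDS divisibility
by 3, ATG starts, stop ends, GFF3/FASTA consistency) are tested against
independent oracles (a hand-coded codon table, brute-force exon splicing).

What it emulates, and the defaults chosen as realistic study conditions:

* Multi-exon genes (1–5 exons, proteins of 120–400 residues) on both strands
  of two chromosomes, with introns of 60–300 bp — desk-scale versions of
  plant gene structure.
* A diverged wild proteome with per-residue substitution rate 0.01 and
  in-frame indel rates 0.001 — about 1% protein divergence, consistent with
  closely related congeners. Planted events are kept ≥ 6 residues apart so
  the optimal global alignment around each event is unique; this is what
  makes exact recovery (precision = recall = 1) a meaningful target rather
  than a statement about alignment ambiguity.
* Score triples in which a configured fraction (default 0.3) of planted
  substitutions passes all three thresholds; the rest fail at least one
  (always SIFT4G and PPVED, sometimes passing PROVEAN alone, as real
  predictors disagree).
* A panel of 12 species × 7 accessions = 84 genomes in four taxonomic
  groups with group-structured sharing probabilities (0.05 for the
  domesticated-like group; 0.65–0.90 for the wild groups), heterozygous and
  missing genotypes at low rates (0.05 / 0.02), and single-sample VCFs that
  record non-reference calls only. Realized sharing fractions are recorded
  and are what the sharing matrix must reproduce exactly.
* A 25-mer spectrum with an error spike below the cutoff (13.5% of
  observations, matching the worked example's 18/133), a heterozygous
  component at c/2 carrying 30% of genuine observations, and a homozygous
  component at c = 136. Components are symmetric discretised kernels of
  Poisson width (variance = mean), truncated at the cutoff and scaled so
  genuine observations equal genome size × coverage exactly up to rounding.
  The kernel is deliberately recorded in the generator output: symmetric
  kernels put the smoothed argmax exactly on the planted coverage and keep
  the two peaks resolvable down to c = 30, where peaks at 15 and 30 sit
  only a few standard deviations apart.

What it does **not** emulate — and what passing tests therefore do not show
about real data: sequencing reads and base errors (no FASTQ), alignment and
variant-calling noise, structural variants, polyploidy,
linkage/population structure within species, annotation errors,
multi-transcript genes, and k-mer spectra distorted by repeats or
contamination. Exact sharing-matrix agreement, in particular, holds because
generator VCFs are noise-free realisations of the recorded genotypes.

## Numerical and degenerate-input choices

* All thresholds are strict inequalities; scores exactly at a threshold
  fail.
* Best-hit ties break by higher identity, then lexicographically smallest
  subject id; leaf-order ties break by subtree size then smallest label —
  every ordering in the package is a deterministic function of its input.
* Translation always uses the standard genetic code with initiator-codon
  special-casing disabled, so a lone CTG codon is leucine, never an
  alternative start.
* Degenerate inputs are first-class: empty keyword sets terminate the
  pipeline cleanly after stage 1; empty subject sets, single-species
  matrices, unimodal spectra and spectra with no mass above the cutoff all
  have defined behaviour (tested).
* Problem sizes in the test-suite and acceptance runs: 8–55 genes, proteins
  of 100–350 residues, panels of 12–84 accessions, ≥ 200 planted variants
  for the round-trip property, and 10 Mbp spectra — sizes chosen so every
  property that should hold exactly can be checked exhaustively.

## Open decisions taken

* Variant positions are numbered in the reference protein (the
  back-translation target); the frame is recorded per variant so wild-frame
  numbering could be reported as well.
* Multi-nucleotide codon differences are represented as separate SNVs for
  the intersection stage; an accession must carry all of them homozygously
  to share the variant.
* The homozygosity rule is "at least one homozygous carrier anywhere"
  (per-variant), the weakest criterion consistent with eliminating genes
  that have no homozygous evidence at all.
* When a gene has alternative transcripts, the first transcript's CDS is
  used (generated annotations have one transcript per gene).
* Genes annotated by several matching GO terms are deduplicated before
  counting.

## Limitations

The aligner stands in for external BLAST/MSA programs; scores match a
brute-force dynamic-programming oracle, but heuristic seeded search
(E-values, word hits) is out of scope, as are codon-aware alignment,
back-translation of indels, genotype imputation, GO-graph ancestor
propagation, and mixture-model spectrum fitting. The sharing analysis
assumes the accession VCFs were called against the same reference
coordinates used for back-translation.
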