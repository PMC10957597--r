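# Independent splice-and-index oracle: build the spliced CDS coordinate list
# directly from the segment table, by brute force.
oracle_codon_positions <- function(segments, strand, aa_pos) {
  pos <- integer()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, 1]; e <- segments[i, 2]
    pos <- c(pos, if (strand == "+") s:e else e:s)
  }
  pos[(3 * (aa_pos - 1) + 1):(3 * aa_pos)]
}

test_that("single-exon plus-strand codon arithmetic is exact", {
  gm <- GeneModel("g", "chr1", "+", cbind(start = 101L, end = 160L))
  expect_equal(proteinPosToCodon(gm, 1)$pos, c(101L, 102L, 103L))
  expect_equal(proteinPosToCodon(gm, 2)$pos, c(104L, 105L, 106L))
  # protein length = 60/3 - 1 = 19; last addressable codon before the stop
  expect_equal(proteinLength(gm), 19L)
  expect_equal(proteinPosToCodon(gm, 19)$pos, c(155L, 156L, 157L))
  expect_error(proteinPosToCodon(gm, 20), "outside")
})

test_that("junction-spanning codons on the minus strand match the splice oracle", {
  # two-exon minus-strand gene: transcription order descends genomic coords
  seg <- cbind(start = c(201L, 101L), end = c(230L, 136L))
  gm <- GeneModel("g", "chr1", "-", seg)
  expect_equal(cdsLength(gm), 66L)
  for (p in c(1L, 5L, 10L, 11L, proteinLength(gm))) {
    expect_equal(proteinPosToCodon(gm, p)$pos,
                 oracle_codon_positions(seg, "-", p),
                 info = paste("aa_pos", p))
  }
  # codon 10 spans the exon junction (30 nt in exon 1)
  expect_equal(proteinPosToCodon(gm, 10)$pos, c(203L, 202L, 201L))
  expect_equal(proteinPosToCodon(gm, 11)$pos, c(136L, 135L, 134L))
})

test_that("codon differences become forward-strand SNVs (one per differing base)", {
  # plus-strand toy: ref codon GCT (A) vs wild CCT (P) at protein position 2
  cds_ref <- "ATGGCTTGGTAA"
  cds_wild <- "ATGCCTTGGTAA"
  gm <- GeneModel("g", "chr1", "+", cbind(start = 11L, end = 22L))
  aln <- alignProteinPair(oracle_translate("ATGGCTTGG"),
                          oracle_translate("ATGCCTTGG"))
  v <- data.frame(gene = "g", kind = "substitution", position = 2L,
                  wild_aa = "P", ref_aa = "A", label = "P2A")
  snv <- aaVariantToSNVs(gm, cds_ref, cds_wild, aln, v)
  expect_equal(nrow(snv), 1L)
  expect_equal(snv$pos, 14L)           # first base of codon 2
  expect_equal(snv$ref, "G")
  expect_equal(snv$alt, "C")
  # editing the codon with the SNV yields a codon encoding the wild residue
  codon <- strsplit("GCT", "")[[1]]
  codon[snv$codon_base] <- snv$alt
  expect_equal(oracle_translate(paste(codon, collapse = "")), "P")
})

test_that("multi-base codon differences emit one SNV per base and identical codons none", {
  # ref AAA (K) vs wild GAG (E): bases 1 and 3 differ
  cds_ref <- "ATGAAATAA"
  cds_wild <- "ATGGAGTAA"
  gm <- GeneModel("g", "chr1", "+", cbind(start = 1L, end = 9L))
  aln <- alignProteinPair("MK", "ME")
  v <- data.frame(gene = "g", kind = "substitution", position = 2L,
                  wild_aa = "E", ref_aa = "K", label = "E2K")
  snv <- aaVariantToSNVs(gm, cds_ref, cds_wild, aln, v)
  expect_equal(snv$pos, c(4L, 6L))
  expect_equal(snv$ref, c("A", "A"))
  expect_equal(snv$alt, c("G", "G"))
  # identical codons: empty result
  v0 <- data.frame(gene = "g", kind = "substitution", position = 1L,
                   wild_aa = "M", ref_aa = "M", label = "M1M")
  expect_equal(nrow(aaVariantToSNVs(gm, cds_ref, cds_ref,
                                    alignProteinPair("MK", "MK"), v0)), 0L)
})

test_that("inconsistent wild codons and indel variants are rejected", {
  gm <- GeneModel("g", "chr1", "+", cbind(start = 1L, end = 9L))
  v <- data.frame(gene = "g", kind = "substitution", position = 2L,
                  wild_aa = "E", ref_aa = "K", label = "E2K")
  expect_error(
    aaVariantToSNVs(gm, "ATGAAATAA", "ATGCGCTAA", alignProteinPair("MK", "MR"),
                    v),
    "inconsistent")
  vi <- data.frame(gene = "g", kind = "insertion", position = 2L,
                   wild_aa = "R", ref_aa = "", label = NA)
  expect_error(aaVariantToSNVs(gm, "ATGAAATAA", "ATGAAATAA",
                               alignProteinPair("MK", "MK"), vi),
               "unsupported")
})

test_that("round-trip holds for every planted variant across strands and exon structures", {
  b <- small_bundle()
  genome <- Biostrings::readDNAStringSet(b$ref$paths$genome)
  subs <- b$gt$variants[b$gt$variants$kind == "substitution", ]
  expect_gt(nrow(subs), 10)
  strands <- vapply(b$ref$models, function(m) m@strand, "")
  expect_setequal(unique(strands[unique(subs$gene)]), c("+", "-"))
  n_ok <- 0L
  for (i in seq_len(nrow(subs))) {
    v <- subs[i, , drop = FALSE]
    snv <- b$gt$snvs[b$gt$snvs$gene == v$gene & b$gt$snvs$label == v$label, ]
    ok <- roundtripCheck(b$ref$models[[v$gene]], genome, snv, v)
    n_ok <- n_ok + ok
  }
  expect_equal(n_ok, nrow(subs))
  # every SNV position lies inside a CDS segment of its gene
  for (g in unique(subs$gene)) {
    seg <- cdsSegments(b$ref$models[[g]])
    pos <- b$gt$snvs$pos[b$gt$snvs$gene == g]
    inside <- vapply(pos, function(p)
      any(p >= seg[, 1] & p <= seg[, 2]), logical(1))
    expect_true(all(inside))
  }
})

test_that("a corrupted alt base fails the round-trip (negative control)", {
  b <- small_bundle()
  genome <- Biostrings::readDNAStringSet(b$ref$paths$genome)
  subs <- b$gt$variants[b$gt$variants$kind == "substitution", ]
  v <- subs[1, , drop = FALSE]
  snv <- b$gt$snvs[b$gt$snvs$gene == v$gene & b$gt$snvs$label == v$label, ]
  bad <- snv
  bad$alt[1] <- setdiff(c("A", "C", "G", "T"),
                        c(bad$alt[1], bad$ref[1]))[1]
  expect_false(roundtripCheck(b$ref$models[[v$gene]], genome, bad, v))
})

test_that("gene models read back from GFF3 reproduce the generator's models", {
  b <- small_bundle()
  models <- readGeneModels(b$ref$paths$gff)
  expect_setequal(names(models), names(b$ref$models))
  for (g in names(models)) {
    expect_equal(cdsSegments(models[[g]]), cdsSegments(b$ref$models[[g]]))
    expect_equal(models[[g]]@strand, b$ref$models[[g]]@strand)
  }
})
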