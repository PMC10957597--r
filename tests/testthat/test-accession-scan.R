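write_test_vcf <- function(records, sample_id = "acc1") {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  writeLines(c(hdr, records), path)
  path
}

test_that("genotype states map from GT fields and absent sites default to hom_ref", {
  vcf <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./."))
  keys <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
  st <- scanAccession(vcf, keys)$state
  expect_equal(st, c("hom_alt", "het", "missing", "hom_ref"))
  # strict mode: absence becomes missing
  st2 <- scanAccession(vcf, keys, absent_as_missing = TRUE)$state
  expect_equal(st2[4], "missing")
})

test_that("non-matching alt alleles do not count as sharing and are reported", {
  vcf <- write_test_vcf("chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t1/1")
  keys <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  out <- scanAccession(vcf, keys)
  expect_equal(out$state, "hom_ref")
  expect_equal(nrow(attr(out, "mismatched")), 1L)
})

test_that("multi-allelic records are decomposed before matching", {
  vcf <- write_test_vcf("chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/1")
  keys <- data.frame(chrom = "chr1", pos = c(100L, 100L), ref = "A",
                     alt = c("G", "T"))
  st <- scanAccession(vcf, keys)$state
  expect_equal(st[1], "hom_alt")
})

test_that("an unreadable VCF fails naming the file", {
  keys <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  expect_error(scanAccession("/nonexistent/x.vcf", keys), "x.vcf")
})

test_that("sharing requires homozygosity at every SNV of the codon change", {
  expect_true(variantShared(c("hom_alt", "hom_alt")))
  expect_false(variantShared(c("hom_alt", "het")))
  expect_false(variantShared(c("hom_alt", "missing")))
  expect_false(variantShared("het"))
  expect_true(variantShared("hom_alt"))
})

test_that("planted carriers are recovered as sharing from their VCFs", {
  b <- small_bundle()
  calls <- scanAccessions(b$gt$vcf_paths, b$gt$snvs)
  sh <- merge(
    aggregate(state ~ accession + gene + label, data = calls,
              FUN = function(s) all(s == "hom_alt")),
    b$gt$genotypes, by = c("accession", "gene", "label"))
  expect_true(all(sh$state.x == (sh$state.y == "hom_alt")))
})

test_that("variants without homozygous evidence are dropped, eliminating their genes", {
  variants <- data.frame(gene = c("g1", "g2", "g2"),
                         label = c("A5R", "K7E", "W9C"))
  calls <- rbind(
    data.frame(accession = "a1", gene = "g1", label = "A5R", chrom = "chr1",
               pos = 1L, ref = "A", alt = "G", state = "het"),
    data.frame(accession = "a2", gene = "g1", label = "A5R", chrom = "chr1",
               pos = 1L, ref = "A", alt = "G", state = "het"),
    data.frame(accession = "a1", gene = "g2", label = "K7E", chrom = "chr1",
               pos = 10L, ref = "C", alt = "T", state = "hom_alt"),
    data.frame(accession = "a2", gene = "g2", label = "K7E", chrom = "chr1",
               pos = 10L, ref = "C", alt = "T", state = "hom_ref"),
    data.frame(accession = "a1", gene = "g2", label = "W9C", chrom = "chr1",
               pos = 20L, ref = "G", alt = "A", state = "het"),
    data.frame(accession = "a2", gene = "g2", label = "W9C", chrom = "chr1",
               pos = 20L, ref = "G", alt = "A", state = "missing"))
  hf <- homozygousGeneFilter(variants, calls)
  expect_equal(hf$retained$label, "K7E")
  expect_equal(hf$dropped_genes, "g1")
  expect_setequal(hf$dropped_variants$label, c("A5R", "W9C"))
})

test_that("sharing proportions are counts of sharing accessions over all accessions of the species", {
  mk_call <- function(acc, state)
    data.frame(accession = acc, gene = "g1", label = "A5R", chrom = "chr1",
               pos = 1L, ref = "A", alt = "G", state = state)
  calls <- do.call(rbind, Map(mk_call,
                              c("a1", "a2", "a3", "a4", "b1", "b2"),
                              c("hom_alt", "hom_alt", "hom_alt", "het",
                                "hom_ref", "hom_ref")))
  map <- data.frame(accession_id = c("a1", "a2", "a3", "a4", "b1", "b2"),
                    species = c(rep("spA", 4), rep("spB", 2)),
                    group = "G")
  sm <- buildSharingMatrix(calls, map)
  expect_s4_class(sm, "SharingMatrix")
  expect_equal(unname(sharingValues(sm)[1, "spA"]), 0.75)  # 3 of 4
  expect_equal(unname(sharingValues(sm)[1, "spB"]), 0)
  expect_equal(unname(speciesCounts(sm)), c(4L, 2L))
  # all sharing gives exactly 1
  calls$state <- "hom_alt"
  sm2 <- buildSharingMatrix(calls, map)
  expect_true(all(sharingValues(sm2) == 1))
})

test_that("an accession absent from the species map is an error", {
  calls <- data.frame(accession = "aX", gene = "g", label = "A1R",
                      chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                      state = "hom_alt")
  map <- data.frame(accession_id = "a1", species = "spA", group = "G")
  expect_error(buildSharingMatrix(calls, map), "aX")
})

test_that("the sharing matrix equals the generator's recorded expectations exactly", {
  b <- small_bundle()
  calls <- scanAccessions(b$gt$vcf_paths, b$gt$snvs)
  sm <- buildSharingMatrix(calls, b$gt$species_map)
  rows <- paste(SummarizedExperiment::rowData(sm)$gene,
                SummarizedExperiment::rowData(sm)$label)
  got <- sharingValues(sm)
  exp <- b$gt$expected_sharing[rows, colnames(got), drop = FALSE]
  expect_equal(unname(got), unname(exp))
  # boundary profiles: probability 0 species shares nothing
  expect_true(all(got[, "spD"] == 0))
})
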