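test_that("contradictory configs are rejected with informative messages", {
  expect_error(syntheticConfig(min_exon_length = 2L), "3 nt")
  expect_error(syntheticConfig(sub_rate = 1.5), "\\[0, 1\\]")
  expect_error(syntheticConfig(n_exons_range = c(0L, 3L)), ">= 1")
  expect_error(syntheticConfig(coverage_c = 2), "coverage_c")
  expect_error(syntheticConfig(coverage_c = 40, kmer_cutoff = 30L),
               "heterozygous")
  expect_error(syntheticConfig(n_species = 3,
                               sharing_profiles = c(a = 0.5, b = 0.5)),
               "one entry per species")
})

test_that("the same seed produces byte-identical outputs", {
  cfg <- syntheticConfig(seed = 55, n_genes = 5, n_species = 2L,
                         accessions_per_species = 2L,
                         sharing_profiles = c(s1 = 0.2, s2 = 0.8))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    ref <- simulateReference(cfg, d)
    gt <- simulateWildProteome(ref, cfg, d)
    simulateAccessions(gt, cfg, d)
    simulateKmerHistogram(cfg, path = file.path(d, "reads.histo"))
  }
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("every generated gene satisfies the translation and splice oracles", {
  b <- small_bundle()
  genome <- Biostrings::readDNAStringSet(b$ref$paths$genome)
  strands <- vapply(b$ref$models, function(m) m@strand, "")
  expect_setequal(unique(strands), c("+", "-"))
  for (g in names(b$ref$models)) {
    cds <- b$ref$cds[[g]]
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    prot_stop <- oracle_translate(cds)   # independent codon table
    expect_equal(substr(prot_stop, nchar(prot_stop), nchar(prot_stop)), "*")
    expect_equal(sub("\\*$", "", prot_stop), b$ref$proteins[[g]])
    # brute-force splice: slice exons from the chromosome, complement on minus
    m <- b$ref$models[[g]]
    seg <- cdsSegments(m)
    chrom <- as.character(genome[[m@chrom]])
    slices <- vapply(seq_len(nrow(seg)), function(i)
      substr(chrom, min(seg[i, ]), max(seg[i, ])), "")
    spliced <- if (m@strand == "+") paste(slices, collapse = "") else
      oracle_revcomp(paste(rev(slices), collapse = ""))
    expect_equal(spliced, cds, info = g)
  }
})

test_that("zero planting rates leave the wild proteome identical to the reference", {
  cfg <- syntheticConfig(seed = 9, n_genes = 4, sub_rate = 0, ins_rate = 0,
                         del_rate = 0)
  d <- tempfile()
  ref <- simulateReference(cfg, d)
  gt <- simulateWildProteome(ref, cfg, d)
  expect_equal(gt$wild_proteins, ref$proteins)
  expect_equal(gt$wild_cds, ref$cds)
  expect_equal(nrow(gt$variants), 0L)
})

test_that("planted substitutions are labelled wild-residue-first and map to at least one SNV", {
  b <- small_bundle()
  subs <- b$gt$variants[b$gt$variants$kind == "substitution", ]
  expect_equal(subs$label,
               paste0(subs$wild_aa, subs$position, subs$ref_aa))
  snv_keys <- unique(paste(b$gt$snvs$gene, b$gt$snvs$label))
  expect_true(all(paste(subs$gene, subs$label) %in% snv_keys))
  # indels are in-frame: wild CDS lengths stay divisible by 3
  expect_true(all(nchar(b$gt$wild_cds) %% 3 == 0))
})

test_that("the number of planted substitutions is consistent with the per-residue rate", {
  cfg <- syntheticConfig(seed = 77, n_genes = 25, sub_rate = 0.01,
                         ins_rate = 0, del_rate = 0,
                         protein_length_range = c(200L, 300L))
  d <- tempfile()
  ref <- simulateReference(cfg, d)
  gt <- simulateWildProteome(ref, cfg, d)
  total_res <- sum(nchar(ref$proteins) - 4L)  # eligible positions 2..P-2
  n <- sum(gt$variants$kind == "substitution")
  expected <- total_res * cfg$sub_rate
  sd4 <- 4 * sqrt(total_res * cfg$sub_rate * (1 - cfg$sub_rate))
  expect_gt(n, expected - sd4)
  expect_lt(n, expected + sd4)
})

test_that("boundary sharing probabilities produce all-or-none homozygous carriers", {
  cfg <- syntheticConfig(
    seed = 13, n_genes = 4, n_species = 2L, accessions_per_species = 3L,
    sharing_profiles = c(all = 1.0, none = 0.0),
    species_groups = c(all = "G1", none = "G2"),
    het_rate = 0, missing_rate = 0)
  d <- tempfile()
  ref <- simulateReference(cfg, d)
  gt <- simulateWildProteome(ref, cfg, d)
  gt <- simulateAccessions(gt, cfg, d)
  g <- gt$genotypes
  expect_true(all(g$state[g$species == "all"] == "hom_alt"))
  expect_false(any(g$state[g$species == "none"] == "hom_alt"))
  expect_true(all(gt$expected_sharing[, "all"] == 1))
  expect_true(all(gt$expected_sharing[, "none"] == 0))
})

test_that("the default panel matches the study design: 12 species x 7 accessions = 84 VCFs", {
  b <- study_bundle()
  expect_equal(length(b$gt$vcf_paths), 84L)
  expect_equal(length(unique(b$gt$species_map$species)), 12L)
  expect_true(all(table(b$gt$species_map$species) == 7L))
  expect_true(all(file.exists(b$gt$vcf_paths)))
})

test_that("realized sharing matches requested profiles within binomial error", {
  b <- study_bundle()
  profiles <- b$cfg$sharing_profiles
  n <- b$cfg$accessions_per_species
  exp_share <- b$gt$expected_sharing
  for (sp in colnames(exp_share)) {
    p <- profiles[[sp]]
    tol <- 4 * sqrt(p * (1 - p) / n) + 1e-9
    expect_true(all(abs(exp_share[, sp] - p) <= tol + 0.2),
                info = sp)
    expect_lt(abs(mean(exp_share[, sp]) - p),
              4 * sqrt(p * (1 - p) / (n * nrow(exp_share))) + 0.05)
  }
})
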