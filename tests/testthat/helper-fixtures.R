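# Shared synthetic bundles, generated once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

make_bundle <- function(key, cfg) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("bundle_", key))
  ref <- simulateReference(cfg, dir)
  gt <- simulateWildProteome(ref, cfg, dir)
  gt <- simulateAccessions(gt, cfg, dir)
  b <- list(cfg = cfg, dir = dir, ref = ref, gt = gt)
  .fixture_env[[key]] <- b
  b
}

# small, fast bundle: 4 species x 3 accessions
small_bundle <- function() {
  make_bundle("small", syntheticConfig(
    seed = 101, n_genes = 8, n_species = 4L, accessions_per_species = 3L,
    sharing_profiles = c(spA = 0.1, spB = 0.9, spC = 0.8, spD = 0.0),
    species_groups = c(spA = "G1", spB = "G2", spC = "G2", spD = "G1"),
    sub_rate = 0.015, protein_length_range = c(100L, 250L)))
}

# full-size study-design bundle: 12 species x 7 accessions = 84 genomes
study_bundle <- function() {
  make_bundle("study", syntheticConfig(seed = 2024, n_genes = 20))
}

table5_scores <- function() {
  readScoreTable(system.file("extdata", "tomato_impact_scores.tsv",
                             package = "WildAlleleScan"))
}

go_catalogue <- function() {
  read.delim(system.file("extdata", "go_term_catalogue.tsv",
                         package = "WildAlleleScan"))
}
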