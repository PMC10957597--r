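#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the generator with validation. The defaults emulate
#' the study design the pipeline targets: a multi-exon annotated reference on
#' both strands, a diverged wild-relative gene set with planted substitutions
#' and in-frame indels, 12 species times 7 accessions (84 genomes) with
#' group-structured allele sharing, and a bimodal 25-mer spectrum with an
#' error spike and heterozygous/homozygous peaks at c/2 and c (c = 136).
#'
#' @param seed integer RNG seed; the same seed gives byte-identical outputs.
#' @param n_genes number of reference genes.
#' @param n_exons_range integer (min, max) exons per gene, min >= 1.
#' @param strand_mix fraction of genes placed on the minus strand.
#' @param protein_length_range (min, max) protein length in residues.
#' @param intron_length_range,intergenic_length intron/spacer sizes in bp.
#' @param min_exon_length smallest exon allowed, in nt (>= 3).
#' @param sub_rate,ins_rate,del_rate per-residue probabilities of planting a
#'   substitution / in-frame insertion / in-frame deletion.
#' @param go_keyword_fraction fraction of genes annotated with keyword-bearing
#'   (water/salt/drought) GO terms; the remainder receive decoy terms.
#' @param keywords keywords defining which catalogue terms count as targets.
#' @param n_species,accessions_per_species panel dimensions (defaults 12 x 7 =
#'   84 accessions).
#' @param sharing_profiles named numeric vector (one per species) giving the
#'   probability that an accession is homozygous for the wild allele at a
#'   variant; \code{NULL} uses a group-structured default over four groups of
#'   species (0.05, 0.65, 0.90, 0.85) mimicking a domesticated group plus
#'   three wild groups.
#' @param species_groups named character vector mapping species to group
#'   labels (defaults pair with the default profiles).
#' @param het_rate,missing_rate probabilities (within the non-sharing mass)
#'   that an accession is heterozygous / uncalled at a variant.
#' @param impact_fraction fraction of planted substitutions given score
#'   triples that pass all three deleteriousness thresholds.
#' @param coverage_c homozygous k-mer coverage (>= 4).
#' @param genome_size_true true genome size in bp for the spectrum.
#' @param error_kmer_mass fraction of all k-mer observations sitting in the
#'   sequencing-error spike below the cutoff.
#' @param het_obs_fraction fraction of genuine k-mer observations in the
#'   heterozygous component.
#' @param kmer_cutoff artifact cutoff of the simulated spectrum.
#' @param k k-mer length (metadata only).
#' @return a validated list of class \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, n_genes = 5)
#' @export
syntheticConfig <- function(seed = 1L,
                            n_genes = 30L,
                            n_exons_range = c(1L, 5L),
                            strand_mix = 0.5,
                            protein_length_range = c(120L, 400L),
                            intron_length_range = c(60L, 300L),
                            intergenic_length = 300L,
                            min_exon_length = 10L,
                            sub_rate = 0.01,
                            ins_rate = 0.001,
                            del_rate = 0.001,
                            go_keyword_fraction = 0.5,
                            keywords = c("salt", "salinity", "water",
                                         "drought"),
                            n_species = 12L,
                            accessions_per_species = 7L,
                            sharing_profiles = NULL,
                            species_groups = NULL,
                            het_rate = 0.05,
                            missing_rate = 0.02,
                            impact_fraction = 0.3,
                            coverage_c = 136,
                            genome_size_true = 1e7,
                            error_kmer_mass = 0.135,
                            het_obs_fraction = 0.3,
                            kmer_cutoff = 30L,
                            k = 25L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sharing_profiles)) {
    groups <- rep(c("Esculentum", "Arcanum", "Peruvianum", "Hirsutum"),
                  length.out = n_species)
    group_p <- c(Esculentum = 0.05, Arcanum = 0.65, Peruvianum = 0.90,
                 Hirsutum = 0.85)
    sp <- sprintf("species_%02d", seq_len(n_species))
    cfg$sharing_profiles <- stats::setNames(unname(group_p[groups]), sp)
    cfg$species_groups <- stats::setNames(groups, sp)
  } else if (is.null(cfg$species_groups)) {
    cfg$species_groups <- stats::setNames(
      rep("ungrouped", length(cfg$sharing_profiles)),
      names(cfg$sharing_profiles))
  }
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @rdname syntheticConfig
#' @param cfg a config list to validate.
#' @export
validateSyntheticConfig <- function(cfg) {
  in01 <- function(x) all(x >= 0 & x <= 1)
  if (!in01(c(cfg$strand_mix, cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
              cfg$go_keyword_fraction, cfg$het_rate, cfg$missing_rate,
              cfg$impact_fraction, cfg$error_kmer_mass,
              cfg$het_obs_fraction, cfg$sharing_profiles)))
    stop("all rates, fractions and sharing probabilities must lie in [0, 1]")
  if (cfg$n_exons_range[1] < 1L) stop("n_exons_range minimum must be >= 1")
  if (cfg$n_exons_range[2] < cfg$n_exons_range[1])
    stop("n_exons_range max < min")
  if (cfg$min_exon_length < 3L)
    stop("exons shorter than 3 nt requested (min_exon_length = ",
         cfg$min_exon_length, ")")
  min_cds <- 3L * (cfg$protein_length_range[1] + 1L)
  if (cfg$n_exons_range[2] * cfg$min_exon_length > min_cds)
    stop("contradictory config: ", cfg$n_exons_range[2], " exons of >= ",
         cfg$min_exon_length, " nt cannot fit in a ", min_cds, " nt CDS")
  if (cfg$protein_length_range[1] < 10L)
    stop("protein_length_range minimum must be >= 10")
  if (cfg$coverage_c < 4) stop("coverage_c must be >= 4")
  if (cfg$genome_size_true <= 0) stop("genome_size_true must be positive")
  if (cfg$het_obs_fraction > 0 && cfg$kmer_cutoff >= cfg$coverage_c / 2)
    stop("contradictory config: kmer_cutoff must sit below the heterozygous ",
         "peak at coverage_c / 2")
  if (length(cfg$sharing_profiles) != cfg$n_species)
    stop("sharing_profiles must have one entry per species")
  if (is.null(names(cfg$sharing_profiles)))
    stop("sharing_profiles must be named by species")
  invisible(TRUE)
}
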