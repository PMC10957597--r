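#' Simulate a bimodal k-mer occurrence spectrum
#'
#' Builds a spectrum with three components: a sequencing-error spike below the
#' artifact cutoff (power-law shaped), a heterozygous component centred near
#' half the homozygous coverage, and a homozygous component centred near the
#' coverage \code{c}. Genuine (non-error) components are symmetric
#' discretised kernels of Poisson width (variance equal to the mean),
#' truncated at the cutoff and scaled so that the total number of
#' genuine k-mer observations (sum of occurrence times count at or above the
#' cutoff) equals \code{genome_size_true * coverage_c} up to integer rounding;
#' the error spike carries \code{error_kmer_mass} of all observations. The
#' construction is deterministic given the config.
#'
#' @param config a [syntheticConfig()] (fields \code{coverage_c},
#'   \code{genome_size_true}, \code{error_kmer_mass},
#'   \code{het_obs_fraction}, \code{kmer_cutoff}, \code{k}).
#' @param path optional file to write the spectrum to, in the two-column
#'   whitespace-separated "histo" dialect.
#' @return list with \code{histogram} (a [KmerHistogram]), \code{true_size},
#'   \code{true_het_peak} (NA when \code{het_obs_fraction} is 0),
#'   \code{true_hom_peak}, \code{cutoff} and \code{path}.
#' @export
simulateKmerHistogram <- function(config, path = NULL) {
  validateSyntheticConfig(config)
  cc <- config$coverage_c
  cutoff <- config$kmer_cutoff
  G <- config$genome_size_true
  h <- config$het_obs_fraction
  total_genuine <- G * cc

  occ <- seq.int(cutoff, ceiling(2.6 * cc))
  # symmetric discretised kernels of Poisson width (variance = mean), so the
  # smoothed spectrum peaks exactly at the planted coverages and the two
  # peaks stay resolvable down to low coverage
  kernel <- function(centre) stats::dnorm(occ, mean = centre,
                                          sd = sqrt(centre))
  whom <- kernel(cc)
  count <- (1 - h) * total_genuine * whom / sum(occ * whom)
  if (h > 0) {
    whet <- kernel(cc / 2)
    count <- count + h * total_genuine * whet / sum(occ * whet)
  }
  occ_all <- occ; count_all <- count
  if (config$error_kmer_mass > 0 && cutoff > 1L) {
    e_occ <- seq_len(cutoff - 1L)
    w <- e_occ^-3
    e_mass <- config$error_kmer_mass / (1 - config$error_kmer_mass) *
      total_genuine
    occ_all <- c(e_occ, occ)
    count_all <- c(e_mass * w / sum(e_occ * w), count)
  }
  count_all <- round(count_all)
  keep <- count_all > 0
  hist <- KmerHistogram(occ_all[keep], count_all[keep], k = config$k)
  if (!is.null(path)) writeKmerHistogram(hist, path)
  list(histogram = hist, true_size = G,
       true_het_peak = if (h > 0) cc / 2 else NA_real_,
       true_hom_peak = cc, cutoff = cutoff,
       kernel = "discretised Gaussian, variance = mean", path = path)
}

#' Write a k-mer histogram in the two-column "histo" dialect
#'
#' @param hist a [KmerHistogram].
#' @param path output file.
#' @export
writeKmerHistogram <- function(hist, path) {
  writeLines(sprintf("%d %s", hist@occurrence,
                     format(hist@count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
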