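#' Simulate accession panels as per-accession VCFs
#'
#' Draws, for each accession and each planted substitution variant, a genotype
#' state — homozygous for the wild allele with the species' sharing
#' probability, otherwise heterozygous / missing / homozygous reference — and
#' writes one single-sample VCF v4.2 per accession plus an
#' accession-to-species map. A carrier is homozygous-ALT at \emph{every} SNV
#' making up the variant's codon change; heterozygous carriers are 0/1 at all
#' of them; missing is \code{./.}; homozygous-reference sites are omitted from
#' the VCF (resequencing convention). Realized per-species sharing fractions
#' are recorded in the ground truth.
#'
#' @param ground_truth a \code{SyntheticGroundTruth} from
#'   [simulateWildProteome()].
#' @param config the same [syntheticConfig()].
#' @param dir output directory; VCFs go to \code{dir/vcf}.
#' @return the ground truth, extended with \code{genotypes} (long data.frame:
#'   accession, species, gene, label, state), \code{expected_sharing}
#'   (variant x species matrix of realized fractions), \code{species_map}
#'   (data.frame accession_id, species, group), \code{vcf_paths} (named by
#'   accession) and \code{species_map_path}.
#' @export
simulateAccessions <- function(ground_truth, config, dir) {
  stopifnot(inherits(ground_truth, "SyntheticGroundTruth"))
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 2L)

  species <- names(config$sharing_profiles)
  map <- data.frame(
    accession_id = sprintf("acc%03d",
                           seq_len(config$n_species *
                                     config$accessions_per_species)),
    species = rep(species, each = config$accessions_per_species),
    group = rep(unname(config$species_groups[species]),
                each = config$accessions_per_species))

  subs <- ground_truth$variants[
    ground_truth$variants$kind == "substitution", , drop = FALSE]
  vkey <- paste(subs$gene, subs$label)
  snvs <- ground_truth$snvs
  snv_by_variant <- split(seq_len(nrow(snvs)),
                          paste(snvs$gene, snvs$label))[vkey]

  geno <- list(); vcf_paths <- character()
  for (a in seq_len(nrow(map))) {
    acc <- map$accession_id[a]
    p <- config$sharing_profiles[[map$species[a]]]
    u <- stats::runif(nrow(subs))
    state <- ifelse(u < p, "hom_alt", "hom_ref")
    nonshare <- which(state == "hom_ref")
    if (length(nonshare)) {
      v <- stats::runif(length(nonshare))
      state[nonshare[v < config$het_rate]] <- "het"
      state[nonshare[v >= config$het_rate &
                       v < config$het_rate + config$missing_rate]] <- "missing"
    }
    if (nrow(subs))
      geno[[acc]] <- data.frame(accession = acc, species = map$species[a],
                                gene = subs$gene, label = subs$label,
                                state = state)
    rows <- list()
    for (i in which(state != "hom_ref")) {
      idx <- snv_by_variant[[i]]
      gt <- unname(c(hom_alt = "1/1", het = "0/1",
                     missing = "./.")[state[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = snvs$chrom[idx], pos = snvs$pos[idx], ref = snvs$ref[idx],
        alt = snvs$alt[idx], gt = gt)
    }
    vcf_paths[acc] <- file.path(vcf_dir, paste0(acc, ".vcf"))
    .write_sample_vcf(if (length(rows)) do.call(rbind, rows) else NULL,
                      acc, ground_truth$chrom_lengths, vcf_paths[acc])
  }
  geno <- if (length(geno)) do.call(rbind, geno) else
    data.frame(accession = character(), species = character(),
               gene = character(), label = character(), state = character())
  rownames(geno) <- NULL

  shared <- geno$state == "hom_alt"
  expected <- matrix(0, nrow = nrow(subs), ncol = length(species),
                     dimnames = list(vkey, species))
  for (sp in species) {
    sel <- geno$species == sp
    agg <- tapply(shared[sel], paste(geno$gene[sel], geno$label[sel]), mean)
    expected[names(agg), sp] <- agg
  }

  map_path <- file.path(dir, "species_map.tsv")
  write_tsv(map, map_path)

  ground_truth$genotypes <- geno
  ground_truth$expected_sharing <- expected
  ground_truth$species_map <- map
  ground_truth$vcf_paths <- vcf_paths
  ground_truth$species_map_path <- map_path
  ground_truth
}

.write_sample_vcf <- function(records, sample_id, chrom_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=WildAlleleScan-synthetic",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  body <- character()
  if (!is.null(records) && nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    records$chrom, as.integer(records$pos), records$ref,
                    records$alt, records$gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
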