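#' Read an accession-to-species map
#'
#' @param path TSV with header \code{accession_id}, \code{species},
#'   \code{group}.
#' @return data.frame.
#' @export
readSpeciesMap <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession_id", "species")
  if (!all(need %in% colnames(tab)))
    stop("species map must have columns: ", paste(need, collapse = ", "))
  if (!"group" %in% colnames(tab)) tab$group <- NA_character_
  tab
}

.gt_state <- function(gt) {
  gt <- sub("\\|", "/", gt)
  alleles <- strsplit(gt, "/")[[1]]
  if (any(alleles == ".")) return("missing")
  if (all(alleles == "1")) return("hom_alt")
  if (all(alleles == "0")) return("hom_ref")
  "het"
}

#' Scan one accession VCF for a set of SNV keys
#'
#' Matches records on exact (chrom, pos, ref, alt); multi-allelic records are
#' decomposed before matching. A key absent from the VCF is called homozygous
#' reference (resequencing VCFs record non-reference sites only) unless
#' \code{absent_as_missing} is set; a record present at a key's position whose
#' alt does not match is treated as not sharing and reported in the
#' \code{mismatched} attribute.
#'
#' @param vcf_path single-sample VCF (plain or bgzipped).
#' @param snv_keys data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param absent_as_missing strict mode: keys absent from the VCF become
#'   \code{missing} instead of \code{hom_ref}.
#' @return data.frame (\code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{state}) with one row per key, states in hom_ref / het / hom_alt /
#'   missing.
#' @export
scanAccession <- function(vcf_path, snv_keys, absent_as_missing = FALSE) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(vcf_path),
    error = function(e) stop("unreadable VCF ", vcf_path, ": ",
                             conditionMessage(e)))
  vcf <- VariantAnnotation::expand(vcf)   # decompose multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  rec <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    gt = as.character(VariantAnnotation::geno(vcf)$GT[, 1L]))
  key <- paste(snv_keys$chrom, snv_keys$pos, snv_keys$ref, snv_keys$alt)
  rkey <- paste(rec$chrom, rec$pos, rec$ref, rec$alt)
  idx <- match(key, rkey)
  state <- vapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) return(if (absent_as_missing) "missing" else "hom_ref")
    .gt_state(rec$gt[idx[i]])
  }, character(1))
  out <- data.frame(chrom = snv_keys$chrom, pos = snv_keys$pos,
                    ref = snv_keys$ref, alt = snv_keys$alt, state = state)
  # positions present with a different alt: not sharing, but worth reporting
  poskey <- paste(snv_keys$chrom, snv_keys$pos)
  mism <- which(is.na(idx) & poskey %in% paste(rec$chrom, rec$pos))
  attr(out, "mismatched") <- out[mism, c("chrom", "pos"), drop = FALSE]
  out
}

#' Scan many accession VCFs
#'
#' @param vcf_paths character vector of VCF paths named by accession id.
#' @param snvs SNV table with \code{gene}, \code{label}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (as produced by
#'   [backtranslateVariants()] or the generator).
#' @param absent_as_missing see [scanAccession()].
#' @return long data.frame of genotype calls: \code{accession}, \code{gene},
#'   \code{label}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{state}.
#' @export
scanAccessions <- function(vcf_paths, snvs, absent_as_missing = FALSE) {
  if (is.null(names(vcf_paths)))
    stop("vcf_paths must be named by accession id")
  if (nrow(snvs) == 0L)
    return(data.frame(accession = character(), gene = character(),
                      label = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      state = character()))
  calls <- lapply(names(vcf_paths), function(acc) {
    sc <- scanAccession(vcf_paths[[acc]], snvs, absent_as_missing)
    data.frame(accession = acc, gene = snvs$gene, label = snvs$label, sc)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Is a variant's full wild codon shared by one accession?
#'
#' An accession shares the wild amino acid only when it is homozygous-ALT at
#' every SNV making up the codon change (all-or-nothing rule); a heterozygous,
#' missing or reference call at any constituent SNV means not shared.
#'
#' @param states character vector of genotype states at the variant's SNVs.
#' @return logical.
#' @export
variantShared <- function(states) {
  length(states) > 0L && all(states == "hom_alt")
}

# per-accession, per-variant shared flags from a long call table
.shared_table <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(accession = character(), gene = character(),
                      label = character(), shared = logical()))
  k <- paste(calls$accession, calls$gene, calls$label, sep = "\r")
  agg <- tapply(calls$state, k, variantShared)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(accession = vapply(parts, `[`, "", 1L),
             gene = vapply(parts, `[`, "", 2L),
             label = vapply(parts, `[`, "", 3L),
             shared = as.logical(agg))
}

#' Keep variants with homozygous evidence; report eliminated genes
#'
#' A variant is retained when at least one accession is homozygous-ALT at all
#' of its SNVs; a gene is eliminated when none of its variants is retained.
#'
#' @param variants data.frame with \code{gene} and \code{label} (the variants
#'   that were scanned).
#' @param calls long call table from [scanAccessions()].
#' @return list with \code{retained} (subset of \code{variants}),
#'   \code{dropped_variants} and \code{dropped_genes}.
#' @export
homozygousGeneFilter <- function(variants, calls) {
  sh <- .shared_table(calls)
  key <- paste(variants$gene, variants$label)
  ever <- tapply(sh$shared, paste(sh$gene, sh$label), any)
  keep <- !is.na(ever[key]) & ever[key]
  retained <- variants[keep, , drop = FALSE]
  dropped <- variants[!keep, , drop = FALSE]
  list(retained = retained, dropped_variants = dropped,
       dropped_genes = setdiff(unique(variants$gene), unique(retained$gene)))
}

#' Build the species-level allele-sharing matrix
#'
#' For every variant and species, the proportion of the species' accessions
#' sharing the full wild codon (homozygous-ALT at all constituent SNVs). The
#' denominator is all accessions of the species: missing genotypes count as
#' not sharing.
#'
#' @param calls long call table from [scanAccessions()].
#' @param species_map data.frame with \code{accession_id}, \code{species} and
#'   optionally \code{group}.
#' @return a [SharingMatrix].
#' @export
buildSharingMatrix <- function(calls, species_map) {
  missing_acc <- setdiff(unique(calls$accession), species_map$accession_id)
  if (length(missing_acc))
    stop("accessions missing from species map: ",
         paste(missing_acc, collapse = ", "))
  sh <- .shared_table(calls)
  sh$species <- species_map$species[match(sh$accession,
                                          species_map$accession_id)]
  vkeys <- unique(sh[, c("gene", "label")])
  vkeys <- vkeys[order(vkeys$gene, vkeys$label), , drop = FALSE]
  species <- unique(species_map$species)
  n_acc <- vapply(species, function(sp)
    sum(species_map$species == sp), integer(1))
  mat <- matrix(0, nrow = nrow(vkeys), ncol = length(species),
                dimnames = list(paste(vkeys$gene, vkeys$label, sep = ":"),
                                species))
  for (j in seq_along(species)) {
    sel <- sh$species == species[j]
    cnt <- tapply(sh$shared[sel], paste(sh$gene[sel], sh$label[sel],
                                        sep = ":"), sum)
    rows <- match(names(cnt), paste(vkeys$gene, vkeys$label, sep = ":"))
    mat[rows, j] <- cnt / n_acc[j]
  }
  cd <- S4Vectors::DataFrame(
    species = species,
    group = species_map$group[match(species, species_map$species)],
    n_accessions = unname(n_acc), row.names = species)
  rd <- S4Vectors::DataFrame(gene = vkeys$gene, label = vkeys$label,
                             row.names = rownames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(sharing = mat), rowData = rd, colData = cd)
  new("SharingMatrix", se)
}
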