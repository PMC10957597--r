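#' Read gene models from a GFF3 annotation
#'
#' Builds one [GeneModel] per gene from the CDS features of a GFF3 file
#' (1-based inclusive coordinates). CDS features are grouped by their
#' \code{Parent} transcript and assigned to the gene via the transcript's own
#' \code{Parent}; segments are ordered in transcription order.
#'
#' @param gff path to a GFF3 file, or a \code{GRanges} already imported.
#' @return named list of \code{GeneModel} objects (one transcript per gene is
#'   assumed, as in the generated annotations; for multi-transcript genes the
#'   first transcript is used with a message).
#' @export
readGeneModels <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
        else gff
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in annotation")
  mrna <- gr[tolower(as.character(gr$type)) %in% c("mrna", "transcript")]
  tx2gene <- stats::setNames(
    as.character(unlist(mrna$Parent)), mrna$ID)
  parent <- as.character(unlist(cds$Parent))
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  models <- list()
  for (g in unique(gene_of)) {
    sub <- cds[gene_of == g]
    txs <- unique(as.character(unlist(sub$Parent)))
    if (length(txs) > 1L) {
      message("gene ", g, ": ", length(txs),
              " transcripts, using the first (", txs[1], ")")
      sub <- sub[as.character(unlist(sub$Parent)) == txs[1]]
    }
    strand <- as.character(GenomicRanges::strand(sub))[1]
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    o <- if (strand == "+") order(st) else order(-st)
    ph <- sub$phase
    ph <- if (is.null(ph) || all(is.na(ph))) 0L else as.integer(ph[o][1])
    models[[g]] <- GeneModel(
      geneId = g,
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = strand,
      segments = cbind(start = st[o], end = en[o]),
      phase = ph)
  }
  models
}

#' Genomic coordinates of the codon encoding one protein position
#'
#' Maps a 1-based protein position to the three genomic coordinates of its
#' codon, in 5'-to-3' transcript order. On minus-strand genes the genomic
#' positions descend; codons spanning exon junctions give non-contiguous
#' coordinates.
#'
#' @param model a [GeneModel].
#' @param aa_pos 1-based protein position (the stop codon is not addressable).
#' @return data.frame with columns \code{chrom}, \code{pos} (three rows, codon
#'   base order).
#' @export
proteinPosToCodon <- function(model, aa_pos) {
  plen <- proteinLength(model)
  if (aa_pos < 1L || aa_pos > plen)
    stop("aa_pos ", aa_pos, " outside protein of gene ", geneId(model),
         " (length ", plen, ")")
  pos <- genomicPositions(model)[(3L * (aa_pos - 1L) + 1L):(3L * aa_pos)]
  data.frame(chrom = model@chrom, pos = pos)
}

# Wild codon index aligned to reference position p: the count of ungapped
# wild residues up to the alignment column holding reference residue p. The
# correspondence follows the protein alignment, so indels shift it correctly.
.aligned_wild_index <- function(alignment, ref_pos) {
  r <- strsplit(alignment$ref, "")[[1]]
  w <- strsplit(alignment$wild, "")[[1]]
  col <- which(cumsum(r != "-") == ref_pos & r != "-")[1]
  if (is.na(col)) stop("reference position ", ref_pos, " not in alignment")
  if (w[col] == "-") return(NA_integer_)
  sum(w[seq_len(col)] != "-")
}

#' Back-translate an amino acid substitution to genomic SNVs
#'
#' The reverse-translation step: the reference codon at the variant's protein
#' position is compared base-by-base with the wild codon aligned to it (codon
#' correspondence taken from the protein alignment, so indels elsewhere in the
#' pair do not shift it), and one SNV is emitted per differing base. Ref and
#' alt alleles are expressed on the reference genome's forward strand
#' (reverse-complemented for minus-strand genes); VCF-style 1-based positions.
#'
#' @param model the reference [GeneModel].
#' @param ref_cds,wild_cds unspliced-free coding sequences (character or
#'   \code{DNAString}) of the reference and wild gene (spliced CDS including
#'   the stop codon for the reference; the wild CDS must encode the wild row
#'   of \code{alignment}).
#' @param alignment the \code{ProteinAlignment} the variant was extracted
#'   from.
#' @param variant one-row data.frame with \code{gene}, \code{kind},
#'   \code{position}, \code{wild_aa}, \code{ref_aa}, \code{label}.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene}, \code{label}, \code{codon_base}; zero rows when
#'   the aligned codons are identical.
#' @export
aaVariantToSNVs <- function(model, ref_cds, wild_cds, alignment, variant) {
  if (variant$kind != "substitution")
    stop("unsupported variant kind: ", variant$kind,
         " (only substitutions are back-translated)")
  ref_cds <- as.character(ref_cds); wild_cds <- as.character(wild_cds)
  p <- variant$position
  q <- .aligned_wild_index(alignment, p)
  if (is.na(q))
    stop("wild row is gapped at reference position ", p)
  ref_codon <- substr(ref_cds, 3L * (p - 1L) + 1L, 3L * p)
  wild_codon <- substr(wild_cds, 3L * (q - 1L) + 1L, 3L * q)
  if (translate_cds(wild_codon) != variant$wild_aa)
    stop("inconsistent inputs: wild codon ", wild_codon, " translates to ",
         translate_cds(wild_codon), ", not ", variant$wild_aa)
  rb <- strsplit(ref_codon, "")[[1]]
  wb <- strsplit(wild_codon, "")[[1]]
  diff <- which(rb != wb)
  if (length(diff) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      label = character(), codon_base = integer()))
  codon <- proteinPosToCodon(model, p)
  minus <- model@strand == "-"
  data.frame(
    chrom = codon$chrom[diff],
    pos = codon$pos[diff],
    ref = if (minus) unname(comp_base(rb[diff])) else rb[diff],
    alt = if (minus) unname(comp_base(wb[diff])) else wb[diff],
    gene = variant$gene, label = variant$label, codon_base = diff)
}

#' Splice the CDS of a gene out of the reference genome
#'
#' Extracts the spliced coding sequence (5' to 3', including the stop codon)
#' of a gene model from a set of chromosome sequences. Minus-strand genes are
#' complemented (the positions returned by [genomicPositions()] already run
#' 3' to 5' on the forward strand, so no reversal is needed).
#'
#' @param model a [GeneModel].
#' @param genome named \code{DNAStringSet} (or a single \code{DNAString} for
#'   the model's chromosome).
#' @return character CDS.
#' @export
spliceCDS <- function(model, genome) {
  chrom <- if (methods::is(genome, "DNAString")) genome
           else genome[[model@chrom]]
  s <- as.character(chrom[genomicPositions(model)])
  if (model@strand == "-") s <- chartr("ACGT", "TGCA", s)
  s
}

#' Validate back-translated SNVs by reconstruction
#'
#' Applies the SNVs to the reference genome, re-splices the gene's CDS through
#' its model and translates: returns \code{TRUE} iff the edited protein
#' carries the wild residue at the variant position and the reference residue
#' everywhere else.
#'
#' @param model the [GeneModel].
#' @param genome a named \code{DNAStringSet} of reference chromosomes.
#' @param snvs output of [aaVariantToSNVs()].
#' @param variant the variant row the SNVs came from.
#' @return logical.
#' @export
roundtripCheck <- function(model, genome, snvs, variant) {
  chrom <- genome[[model@chrom]]
  if (nrow(snvs)) {
    for (i in seq_len(nrow(snvs))) {
      if (as.character(chrom[snvs$pos[i]]) != snvs$ref[i]) return(FALSE)
      chrom <- Biostrings::replaceLetterAt(chrom, snvs$pos[i], snvs$alt[i])
    }
  }
  edited <- sub("\\*$", "", translate_cds(spliceCDS(model, chrom)))
  ref_prot <- sub("\\*$", "", translate_cds(spliceCDS(model, genome)))
  p <- variant$position
  if (nchar(edited) != nchar(ref_prot)) return(FALSE)
  if (nrow(snvs) == 0L)
    return(edited == ref_prot)
  substr(edited, p, p) == variant$wild_aa &&
    substr(edited, 1L, p - 1L) == substr(ref_prot, 1L, p - 1L) &&
    (p == nchar(edited) ||
       substr(edited, p + 1L, nchar(edited)) ==
         substr(ref_prot, p + 1L, nchar(ref_prot)))
}

#' Write SNVs as a minimal sites-only VCF v4.2
#'
#' @param snvs data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (extra columns ignored).
#' @param path output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return the path, invisibly.
#' @export
writeSnvVcf <- function(snvs, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=WildAlleleScan")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  o <- order(snvs$chrom, snvs$pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snvs$chrom[o], as.integer(snvs$pos[o]), snvs$ref[o],
                  snvs$alt[o])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Back-translate a table of substitutions for many genes
#'
#' Convenience wrapper used by the pipeline: runs [aaVariantToSNVs()] for
#' every substitution, validates each result with [roundtripCheck()] when a
#' genome is supplied, and drops (with a logged reason) variants whose codon
#' cannot be retrieved.
#'
#' @param variants substitution table (columns gene, kind, position, wild_aa,
#'   ref_aa, label).
#' @param models named list of [GeneModel]s.
#' @param ref_cds,wild_cds named \code{DNAStringSet}s of reference and wild
#'   CDS.
#' @param alignments named list of \code{ProteinAlignment}s keyed by gene.
#' @param genome optional reference genome for round-trip validation.
#' @return list with \code{snvs} (data.frame) and \code{dropped} (data.frame
#'   gene, label, reason).
#' @export
backtranslateVariants <- function(variants, models, ref_cds, wild_cds,
                                  alignments, genome = NULL) {
  snv_list <- list(); dropped <- list()
  subs <- variants[variants$kind == "substitution", , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    v <- subs[i, , drop = FALSE]
    g <- v$gene
    res <- tryCatch(
      aaVariantToSNVs(models[[g]], ref_cds[[g]], wild_cds[[g]],
                      alignments[[g]], v),
      error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene = g, label = v$label, reason = conditionMessage(res))
      next
    }
    if (!is.null(genome) && !roundtripCheck(models[[g]], genome, res, v)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene = g, label = v$label,
                   reason = "round-trip validation failed")
      next
    }
    snv_list[[length(snv_list) + 1L]] <- res
  }
  snvs <- if (length(snv_list)) do.call(rbind, snv_list) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), label = character(),
               codon_base = integer())
  rownames(snvs) <- NULL
  list(snvs = snvs,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(gene = character(), label = character(),
                    reason = character()))
}
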