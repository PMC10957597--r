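# Random DNA of a given length over ACGT.
.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Split a CDS of length L into n exon lengths, each >= min_len.
.split_exons <- function(L, n, min_len) {
  if (n == 1L) return(L)
  for (try in 1:200) {
    bp <- sort(sample(seq.int(min_len + 1L, L - min_len + 1L), n - 1L))
    lens <- diff(c(1L, bp, L + 1L))
    if (all(lens >= min_len)) return(lens)
  }
  lens <- rep(L %/% n, n)
  lens[n] <- lens[n] + L - sum(lens)
  lens
}

#' Simulate an annotated reference genome
#'
#' Generates a small reference for the whole pipeline: multi-exon
#' protein-coding genes on both strands placed on two chromosomes, written as
#' genome FASTA, GFF3 annotation (1-based inclusive, gene/mRNA/CDS with
#' phase), spliced CDS FASTA, protein FASTA and a GO annotation table in which
#' a configurable fraction of genes carries water/salt/drought-related terms
#' and the remainder decoy terms. Every spliced CDS starts with ATG, ends with
#' a stop codon and has length divisible by 3; proteins are the standard-code
#' translation of the CDS minus the stop.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @return object of class \code{SyntheticReference}: list with \code{config},
#'   \code{paths} (genome, gff, cds, proteins, go_table), \code{models}
#'   (named list of [GeneModel]), \code{cds}/\code{proteins} (named character
#'   vectors), \code{go_table} (data.frame), \code{keyword_genes} and
#'   \code{chrom_lengths}.
#' @export
simulateReference <- function(config, dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  validateSyntheticConfig(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  by_aa <- codons_by_aa()
  coding <- setdiff(names(by_aa), "*")
  chroms <- c("chr1", "chr2")
  pieces <- stats::setNames(vector("list", length(chroms)), chroms)
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  models <- list(); cds_v <- character(); prot_v <- character()

  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("g%03d", i)
    P <- sample(seq.int(config$protein_length_range[1],
                        config$protein_length_range[2]), 1L)
    aas <- c("M", sample(AA_ALPHABET20, P - 1L, replace = TRUE))
    codons <- vapply(aas, function(a) sample(by_aa[[a]], 1L), character(1))
    codons <- c(codons, sample(stop_codons(), 1L))
    cds <- paste(codons, collapse = "")
    L <- nchar(cds)
    n_ex <- sample(seq.int(config$n_exons_range[1], config$n_exons_range[2]),
                   1L)
    lens <- .split_exons(L, n_ex, config$min_exon_length)
    strand <- if (stats::runif(1) < config$strand_mix) "-" else "+"
    introns <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(j)
        .rand_dna(sample(seq.int(config$intron_length_range[1],
                                 config$intron_length_range[2]), 1L)),
        character(1)) else character()

    # gene region in transcription orientation: exon1 intron1 ... exonN
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    region_parts <- character(); off <- 0L
    exon_region <- matrix(0L, n_ex, 2L)   # exon spans within region
    for (j in seq_len(n_ex)) {
      exon_seq <- substr(cds, starts[j], ends[j])
      exon_region[j, ] <- c(off + 1L, off + lens[j])
      region_parts <- c(region_parts, exon_seq)
      off <- off + lens[j]
      if (j < n_ex) {
        region_parts <- c(region_parts, introns[j])
        off <- off + nchar(introns[j])
      }
    }
    region <- paste(region_parts, collapse = "")
    rl <- nchar(region)

    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    spacer <- .rand_dna(config$intergenic_length)
    gene_start <- cursor[chrom] + config$intergenic_length + 1L
    genomic <- if (strand == "+") region else revcomp(region)
    pieces[[chrom]] <- c(pieces[[chrom]], spacer, genomic)
    cursor[chrom] <- cursor[chrom] + config$intergenic_length + rl

    seg <- matrix(0L, n_ex, 2L)
    for (j in seq_len(n_ex)) {
      a <- exon_region[j, 1L]; b <- exon_region[j, 2L]
      if (strand == "+") seg[j, ] <- c(gene_start + a - 1L, gene_start + b - 1L)
      else seg[j, ] <- c(gene_start + rl - b, gene_start + rl - a)
    }
    colnames(seg) <- c("start", "end")
    models[[gid]] <- GeneModel(gid, chrom, strand, seg, 0L)
    cds_v[gid] <- cds
    prot_v[gid] <- paste(aas, collapse = "")
  }

  # trailing spacers so genes never touch the chromosome end
  for (ch in chroms)
    pieces[[ch]] <- c(pieces[[ch]], .rand_dna(config$intergenic_length))
  genome <- Biostrings::DNAStringSet(vapply(pieces, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms

  # GO annotation: keyword-bearing terms for a subset of genes, decoys for
  # the rest
  catalogue <- read_tsv(system.file("extdata", "go_term_catalogue.tsv",
                                    package = "WildAlleleScan"))
  hit_terms <- searchGOTerms(catalogue, config$keywords)
  decoys <- catalogue[!catalogue$go_id %in% hit_terms$go_id, , drop = FALSE]
  gene_ids <- names(models)
  n_kw <- round(config$go_keyword_fraction * length(gene_ids))
  kw_genes <- sort(sample(gene_ids, n_kw))
  go_rows <- lapply(gene_ids, function(g) {
    pool <- if (g %in% kw_genes) hit_terms else decoys
    k <- sample(1:2, 1L)
    idx <- sample(nrow(pool), min(k, nrow(pool)))
    data.frame(gene_id = g, go_id = pool$go_id[idx],
               go_name = pool$go_name[idx])
  })
  go_table <- do.call(rbind, go_rows)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    cds = file.path(dir, "cds.fa"),
    proteins = file.path(dir, "proteins.fa"),
    go_table = file.path(dir, "go_annotations.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds_v), paths$cds)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot_v), paths$proteins)
  write_tsv(go_table, paths$go_table)
  .write_gff3(models, stats::setNames(Biostrings::width(genome), chroms),
              paths$gff)

  structure(list(config = config, dir = dir, paths = paths, models = models,
                 cds = cds_v, proteins = prot_v, go_table = go_table,
                 keyword_genes = kw_genes,
                 chrom_lengths = stats::setNames(Biostrings::width(genome),
                                                 chroms)),
            class = "SyntheticReference")
}

# Emit gene/mRNA/CDS features with phase as GFF3 (1-based inclusive).
.write_gff3 <- function(models, chrom_lengths, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                     chrom_lengths))
  for (m in models) {
    seg <- cdsSegments(m)
    span <- c(min(seg), max(seg))
    tid <- paste0(geneId(m), ".t1")
    lines <- c(lines,
      sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m@chrom, span[1], span[2], m@strand, geneId(m)),
      sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m@chrom, span[1], span[2], m@strand, tid, geneId(m)))
    done <- 0L
    for (j in seq_len(nrow(seg))) {
      phase <- (3L - done %% 3L) %% 3L
      lines <- c(lines,
        sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                m@chrom, min(seg[j, ]), max(seg[j, ]), m@strand, phase,
                geneId(m), j, tid))
      done <- done + seg[j, 2L] - seg[j, 1L] + 1L
    }
  }
  writeLines(lines, path)
  invisible(path)
}
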