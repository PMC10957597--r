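#' Read a pipeline configuration from YAML
#'
#' The configuration names every input path (GO table, reference genome /
#' GFF3 / CDS / protein FASTAs, wild CDS and protein FASTAs, score TSV, VCF
#' directory and species map), the keyword set, and the thresholds
#' (\code{min_qcov} 90, \code{provean} −2.5, \code{sift} 0.05, \code{ppved}
#' 0.5 by default). See [runPipeline()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .fill_pipeline_defaults(cfg)
}

.fill_pipeline_defaults <- function(cfg) {
  thr <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    min_qcov = thr$min_qcov %||% 90,
    provean = thr$provean %||% -2.5,
    sift = thr$sift %||% 0.05,
    ppved = thr$ppved %||% 0.5)
  with(cfg$thresholds, {
    if (min_qcov < 0 || min_qcov > 100) stop("min_qcov outside [0, 100]")
    if (sift < 0 || sift > 1 || ppved < 0 || ppved > 1)
      stop("sift/ppved thresholds outside [0, 1]")
  })
  cfg$keywords <- cfg$keywords %||% c("salt", "salinity", "water", "drought")
  cfg$cluster <- list(linkage = cfg$cluster$linkage %||% "average",
                      metric = cfg$cluster$metric %||% "euclidean")
  cfg
}

#' Build a pipeline config from a synthetic bundle
#'
#' Convenience wrapper wiring the outputs of [simulateReference()],
#' [simulateWildProteome()] and [simulateAccessions()] into a [runPipeline()]
#' configuration.
#'
#' @param reference a \code{SyntheticReference}.
#' @param ground_truth a \code{SyntheticGroundTruth} (after
#'   [simulateAccessions()]).
#' @param ... overrides merged into the config (e.g. \code{keywords},
#'   \code{thresholds}).
#' @return config list for [runPipeline()].
#' @export
syntheticPipelineConfig <- function(reference, ground_truth, ...) {
  cfg <- list(
    go_table = reference$paths$go_table,
    reference = list(genome = reference$paths$genome,
                     gff = reference$paths$gff,
                     cds = reference$paths$cds,
                     proteins = reference$paths$proteins),
    wild = list(cds = ground_truth$paths$wild_cds,
                proteins = ground_truth$paths$wild_proteins),
    scores = ground_truth$paths$scores,
    vcf_paths = as.list(ground_truth$vcf_paths),
    species_map = ground_truth$species_map_path)
  cfg <- utils::modifyList(cfg, list(...))
  .fill_pipeline_defaults(cfg)
}

.stage <- function(manifest, name, paths, rows) {
  manifest$stages[[name]] <- list(name = name, outputs = unname(unlist(paths)),
                                  rows = rows)
  manifest
}

.write_manifest <- function(manifest, out_dir) {
  tab <- do.call(rbind, lapply(manifest$stages, function(s)
    data.frame(stage = s$name,
               artifact = basename(s$outputs),
               rows = rep(s$rows, length.out = length(s$outputs)))))
  write_tsv(tab, file.path(out_dir, "manifest.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full wild-allele prioritisation pipeline
#'
#' Executes every stage in order: GO keyword selection, sequence extraction
#' and ortholog matching under the query-coverage floor, protein alignment and
#' variant extraction, the PROVEAN screen, the triple-threshold impact
#' classification, back-translation of substitutions to genomic SNVs,
#' scanning of all accession VCFs with the homozygous-evidence filter, the
#' species sharing matrix, and clustering with the heatmap report. All
#' intermediates are headers-and-tabs TSV files under \code{out_dir}; a
#' manifest records every artefact, its row count and the thresholds used.
#' Re-running on identical inputs reproduces identical TSVs; with
#' \code{resume = TRUE} stages whose outputs already exist are loaded instead
#' of recomputed.
#'
#' @param config list from [readPipelineConfig()] or
#'   [syntheticPipelineConfig()].
#' @param out_dir output directory.
#' @param resume skip stages whose outputs already exist.
#' @param verbose print stage progress.
#' @return list with \code{status} (\code{"ok"} or \code{"empty_selection"}),
#'   the key tables (\code{selected_genes}, \code{hits}, \code{variants},
#'   \code{classified}, \code{snvs}, \code{retained}, \code{dropped_genes}),
#'   the [SharingMatrix], the [SpeciesClustering] and the manifest.
#' @export
runPipeline <- function(config, out_dir, resume = FALSE, verbose = TRUE) {
  config <- .fill_pipeline_defaults(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  manifest <- list(thresholds = config$thresholds,
                   keywords = config$keywords, cluster = config$cluster,
                   stages = list())

  # -- stage 1: GO term search and gene selection ---------------------------
  go_tab <- readGOTable(config$go_table)
  terms <- searchGOTerms(go_tab, config$keywords)
  genes <- selectGenes(go_tab, terms$go_id)
  p_terms <- file.path(out_dir, "selected_terms.tsv")
  p_genes <- file.path(out_dir, "selected_genes.tsv")
  write_tsv(terms, p_terms)
  write_tsv(data.frame(gene_id = genes), p_genes)
  manifest <- .stage(manifest, "select", list(p_terms, p_genes),
                     length(genes))
  say("select: ", nrow(terms), " terms, ", length(genes), " genes")
  if (length(genes) == 0L) {
    .write_manifest(manifest, out_dir)
    say("no genes selected; stopping after stage 1")
    return(list(status = "empty_selection", selected_genes = genes,
                manifest = manifest))
  }

  # -- stage 2: extract wild sequences, match to reference ------------------
  wild_cds_all <- Biostrings::readDNAStringSet(config$wild$cds)
  ref_cds_all <- Biostrings::readDNAStringSet(config$reference$cds)
  ext <- extractSequences(wild_cds_all, genes)
  p_hits <- file.path(out_dir, "ortholog_hits.tsv")
  if (resume && file.exists(p_hits)) {
    hits <- read_tsv(p_hits)
    say("match: loaded ", nrow(hits), " hits (resume)")
  } else {
    mo <- matchOrthologs(ext$sequences, ref_cds_all,
                         min_qcov = config$thresholds$min_qcov,
                         mode = "nucleotide")
    hits <- mo$hits
    write_tsv(hits, p_hits)
    say("match: ", nrow(hits), " of ", length(genes), " genes matched")
  }
  manifest <- .stage(manifest, "match", list(p_hits), nrow(hits))

  # -- stage 3: align protein pairs, extract variants -----------------------
  wild_prot <- Biostrings::readAAStringSet(config$wild$proteins)
  ref_prot <- Biostrings::readAAStringSet(config$reference$proteins)
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  p_var <- file.path(out_dir, "variants.tsv")
  alignments <- list()
  var_list <- list()
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_id[i]; s <- hits$subject_id[i]
    p_aln <- file.path(aln_dir, paste0(q, ".fa"))
    if (resume && file.exists(p_aln)) {
      # rows are tagged by role: query and subject ids may coincide
      aln <- readProteinAlignment(p_aln, ref_name = paste0("ref|", s),
                                  wild_name = paste0("wild|", q))
      aln$ref_name <- s; aln$wild_name <- q
    } else {
      aln <- alignProteinPair(ref_prot[[s]], wild_prot[[q]],
                              ref_name = s, wild_name = q)
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(stats::setNames(
          c(aln$ref, aln$wild),
          c(paste0("ref|", s), paste0("wild|", q)))), p_aln)
    }
    alignments[[q]] <- aln
    var_list[[q]] <- extractAAVariants(aln, gene_id = q)
  }
  variants <- do.call(rbind, var_list)
  rownames(variants) <- NULL
  write_tsv(variants, p_var)
  manifest <- .stage(manifest, "extract", list(p_var), nrow(variants))
  say("extract: ", nrow(variants), " variants (",
      sum(variants$kind == "substitution"), " substitutions)")

  # -- stage 4: PROVEAN screen ----------------------------------------------
  scores <- readScoreTable(config$scores)
  subs <- variants[variants$kind == "substitution", , drop = FALSE]
  screen <- proveanScreen(subs, scores,
                          threshold = config$thresholds$provean)
  p_screen <- file.path(out_dir, "provean_screen.tsv")
  write_tsv(screen$variants, p_screen)
  manifest <- .stage(manifest, "screen", list(p_screen),
                     sum(screen$variants$pass))
  say("screen: ", sum(screen$variants$pass), " variants pass PROVEAN < ",
      config$thresholds$provean, " in ", length(screen$genes), " genes")
  screened <- screen$variants[screen$variants$pass, , drop = FALSE]

  # -- stage 5: triple-threshold classification -----------------------------
  classified <- classifyImpactful(
    screen$variants[, c("gene", "label", "provean", "sift4g", "ppved")],
    provean_thr = config$thresholds$provean,
    sift_thr = config$thresholds$sift, ppved_thr = config$thresholds$ppved)
  p_class <- file.path(out_dir, "impact_classification.tsv")
  write_tsv(classified, p_class)
  manifest <- .stage(manifest, "classify", list(p_class),
                     sum(classified$impactful))
  say("classify: ", sum(classified$impactful), " impactful variants")

  # -- stage 6: back-translate screened substitutions to SNVs ---------------
  genome <- Biostrings::readDNAStringSet(config$reference$genome)
  models <- readGeneModels(config$reference$gff)
  # gene models are keyed by reference gene; back-translation runs on the
  # matched reference gene of each wild query
  ref_of <- stats::setNames(hits$subject_id, hits$query_id)
  bt_variants <- screened
  bt <- list(snvs = NULL, dropped = NULL)
  snv_rows <- list(); dropped_rows <- list()
  wild_cds_seq <- stats::setNames(as.character(ext$sequences),
                                  names(ext$sequences))
  for (i in seq_len(nrow(bt_variants))) {
    v <- bt_variants[i, , drop = FALSE]
    rg <- ref_of[[v$gene]]
    res <- tryCatch({
      snv <- aaVariantToSNVs(models[[rg]], as.character(ref_cds_all[[rg]]),
                             wild_cds_seq[[v$gene]], alignments[[v$gene]], v)
      if (!roundtripCheck(models[[rg]], genome, snv, v))
        stop("round-trip validation failed")
      snv
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped_rows[[length(dropped_rows) + 1L]] <- data.frame(
        gene = v$gene, label = v$label, reason = conditionMessage(res))
    } else snv_rows[[length(snv_rows) + 1L]] <- res
  }
  snvs <- if (length(snv_rows)) do.call(rbind, snv_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), label = character(),
               codon_base = integer())
  rownames(snvs) <- NULL
  p_snv <- file.path(out_dir, "snvs.tsv")
  p_vcf <- file.path(out_dir, "snvs.vcf")
  write_tsv(snvs, p_snv)
  writeSnvVcf(snvs, p_vcf,
              contigs = stats::setNames(Biostrings::width(genome),
                                        names(genome)))
  manifest <- .stage(manifest, "backtranslate", list(p_snv, p_vcf),
                     nrow(snvs))
  say("backtranslate: ", nrow(snvs), " SNVs from ",
      length(unique(snvs$label)), " variants; ", length(dropped_rows),
      " dropped")

  # -- stage 7: scan accessions ---------------------------------------------
  vcf_paths <- if (!is.null(config$vcf_paths)) unlist(config$vcf_paths)
    else {
      files <- list.files(config$vcf_dir, pattern = "\\.vcf(\\.gz|\\.bgz)?$",
                          full.names = TRUE)
      stats::setNames(files, sub("\\.vcf(\\.gz|\\.bgz)?$", "",
                                 basename(files)))
    }
  calls <- scanAccessions(vcf_paths, snvs)
  p_calls <- file.path(out_dir, "genotype_calls.tsv")
  write_tsv(calls, p_calls)
  # presence/absence twin: variant x accession shared flags
  sh <- .shared_table(calls)
  pres <- stats::xtabs(shared ~ paste(gene, label, sep = ":") + accession,
                       data = sh)
  pres_df <- data.frame(variant = rownames(pres),
                        as.data.frame.matrix(pres), check.names = FALSE)
  p_pres <- file.path(out_dir, "presence_matrix.tsv")
  write_tsv(pres_df, p_pres)
  manifest <- .stage(manifest, "scan", list(p_calls, p_pres), nrow(calls))
  say("scan: ", length(vcf_paths), " accessions, ", nrow(calls), " calls")

  # -- stage 8: homozygous-evidence filter ----------------------------------
  scanned_variants <- unique(snvs[, c("gene", "label")])
  hf <- homozygousGeneFilter(scanned_variants, calls)
  p_ret <- file.path(out_dir, "retained_variants.tsv")
  p_drop <- file.path(out_dir, "dropped_genes.tsv")
  write_tsv(hf$retained, p_ret)
  write_tsv(data.frame(gene = hf$dropped_genes), p_drop)
  manifest <- .stage(manifest, "homozygous_filter", list(p_ret, p_drop),
                     nrow(hf$retained))
  say("homozygous filter: ", nrow(hf$retained), " variants retained, ",
      length(hf$dropped_genes), " genes eliminated")

  # -- stage 9: sharing matrix, clustering, heatmap -------------------------
  species_map <- readSpeciesMap(config$species_map)
  keep_keys <- paste(hf$retained$gene, hf$retained$label)
  calls_kept <- calls[paste(calls$gene, calls$label) %in% keep_keys, ,
                      drop = FALSE]
  result <- list(status = "ok", selected_genes = genes, hits = hits,
                 variants = variants, screened = screened,
                 classified = classified, snvs = snvs,
                 retained = hf$retained, dropped_genes = hf$dropped_genes,
                 sharing = NULL, clustering = NULL)
  if (nrow(calls_kept)) {
    sharing <- buildSharingMatrix(calls_kept, species_map)
    clustering <- clusterSpecies(sharing,
                                 linkage = config$cluster$linkage,
                                 metric = config$cluster$metric)
    p_share <- file.path(out_dir, "sharing_matrix.tsv")
    share_df <- data.frame(variant = rownames(sharingValues(sharing)),
                           sharingValues(sharing), check.names = FALSE)
    write_tsv(share_df, p_share)
    hm <- renderHeatmap(sharing, clustering,
                        out_prefix = file.path(out_dir, "sharing_heatmap"))
    manifest <- .stage(manifest, "report",
                       c(list(p_share), hm), nrow(sharing))
    say("report: ", nrow(sharing), " x ", ncol(sharing),
        " sharing matrix; leaf order ",
        paste(leafOrder(clustering), collapse = " "))
    result$sharing <- sharing
    result$clustering <- clustering
  }

  .write_manifest(manifest, out_dir)
  result$manifest <- manifest
  result
}
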