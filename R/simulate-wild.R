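`.MIN_EVENT_GAP` <- 6L  # residues between planted events: keeps the optimal
                        # global alignment unique around each event

# Draw planted event positions for one protein, enforcing separation.
.plant_events <- function(P, sub_rate, ins_rate, del_rate) {
  cand <- list()
  for (p in 2:(P - 2L)) {
    u <- stats::runif(3)
    if (u[1] < sub_rate) cand[[length(cand) + 1L]] <- list(kind = "substitution", pos = p)
    else if (u[2] < ins_rate) cand[[length(cand) + 1L]] <- list(kind = "insertion", pos = p)
    else if (u[3] < del_rate) cand[[length(cand) + 1L]] <- list(kind = "deletion", pos = p)
  }
  kept <- list(); last <- -Inf
  for (ev in cand) {
    if (ev$pos - last >= `.MIN_EVENT_GAP`) {
      kept[[length(kept) + 1L]] <- ev
      last <- ev$pos + (if (ev$kind == "deletion") 2L else 0L)
    }
  }
  kept
}

#' Simulate the wild-relative gene set with planted variants
#'
#' Derives a diverged wild proteome from a [simulateReference()] output by
#' planting, per gene, amino acid substitutions (one codon changed each) and
#' in-frame insertions/deletions (multiples of 3 nt), and records the ground
#' truth: each variant's label (wild residue, reference position, reference
#' residue, e.g. \code{P63A}), the genomic SNVs the substitution corresponds
#' to, and a deleteriousness score triple per substitution in which a
#' configured fraction passes all three thresholds.
#'
#' @param reference a \code{SyntheticReference}.
#' @param config the same [syntheticConfig()] (rates are read from it).
#' @param dir output directory.
#' @return object of class \code{SyntheticGroundTruth}: list with
#'   \code{variants} (gene, kind, position, wild_aa, ref_aa, label,
#'   impactful), \code{snvs} (gene, label, chrom, pos, ref, alt),
#'   \code{scores} (score triples), \code{wild_cds}/\code{wild_proteins}
#'   (named character), \code{paths} and \code{chrom_lengths}.
#' @export
simulateWildProteome <- function(reference, config, dir) {
  stopifnot(inherits(reference, "SyntheticReference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  by_aa <- codons_by_aa()

  variants <- list(); snvs <- list()
  wild_cds <- character(); wild_prot <- character()

  for (gid in names(reference$models)) {
    model <- reference$models[[gid]]
    cds <- reference$cds[[gid]]
    prot <- reference$proteins[[gid]]
    P <- nchar(prot)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    gpos <- genomicPositions(model)
    minus <- model@strand == "-"
    events <- .plant_events(P, config$sub_rate, config$ins_rate,
                            config$del_rate)

    wild_codons <- codons
    for (ev in events) {
      p <- ev$pos
      if (ev$kind == "substitution") {
        ref_aa <- substr(prot, p, p)
        wild_aa <- sample(setdiff(AA_ALPHABET20, ref_aa), 1L)
        wcod <- sample(by_aa[[wild_aa]], 1L)
        wild_codons[p] <- wcod
        rb <- strsplit(codons[p], "")[[1]]
        wb <- strsplit(wcod, "")[[1]]
        d <- which(rb != wb)
        label <- paste0(wild_aa, p, ref_aa)
        variants[[length(variants) + 1L]] <- data.frame(
          gene = gid, kind = "substitution", position = p,
          wild_aa = wild_aa, ref_aa = ref_aa, label = label)
        cpos <- gpos[(3L * (p - 1L) + 1L):(3L * p)]
        snvs[[length(snvs) + 1L]] <- data.frame(
          gene = gid, label = label, chrom = model@chrom, pos = cpos[d],
          ref = if (minus) unname(comp_base(rb[d])) else rb[d],
          alt = if (minus) unname(comp_base(wb[d])) else wb[d])
      } else if (ev$kind == "insertion") {
        len <- sample(1:2, 1L)
        ins_aa <- sample(AA_ALPHABET20, len, replace = TRUE)
        variants[[length(variants) + 1L]] <- data.frame(
          gene = gid, kind = "insertion", position = p,
          wild_aa = paste(ins_aa, collapse = ""), ref_aa = "",
          label = NA_character_)
        wild_codons[p] <- paste0(
          wild_codons[p],
          paste(vapply(ins_aa, function(a) sample(by_aa[[a]], 1L),
                       character(1)), collapse = ""))
      } else {
        len <- sample(1:2, 1L)
        del_aa <- substr(prot, p, p + len - 1L)
        variants[[length(variants) + 1L]] <- data.frame(
          gene = gid, kind = "deletion", position = p, wild_aa = "",
          ref_aa = del_aa, label = NA_character_)
        wild_codons[p:(p + len - 1L)] <- ""
      }
    }
    wcds <- paste(wild_codons, collapse = "")
    wild_cds[gid] <- wcds
    wild_prot[gid] <- sub("\\*$", "", translate_cds(wcds))
  }

  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(gene = character(), kind = character(), position = integer(),
               wild_aa = character(), ref_aa = character(),
               label = character())
  snvs <- if (length(snvs)) do.call(rbind, snvs) else
    data.frame(gene = character(), label = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character())
  rownames(variants) <- rownames(snvs) <- NULL

  # score triples for substitutions: a configured fraction passes all three
  # thresholds, the rest fail at least one
  is_sub <- variants$kind == "substitution"
  variants$impactful <- rep(FALSE, nrow(variants))
  scores <- NULL
  if (any(is_sub)) {
    sub <- variants[is_sub, , drop = FALSE]
    n <- nrow(sub)
    impact <- stats::runif(n) < config$impact_fraction
    provean <- ifelse(impact, stats::runif(n, -9, -3),
                      stats::runif(n, -2.4, 0))
    sift <- ifelse(impact, stats::runif(n, 0, 0.04),
                   stats::runif(n, 0.06, 0.8))
    ppved <- ifelse(impact, stats::runif(n, 0.55, 0.95),
                    stats::runif(n, 0.05, 0.45))
    # some non-impactful variants still pass one or two thresholds, as real
    # predictors disagree
    mix <- !impact & stats::runif(n) < 0.5
    provean[mix] <- stats::runif(sum(mix), -8, -2.6)
    scores <- data.frame(gene = sub$gene, label = sub$label,
                         provean = round(provean, 2),
                         sift4g = round(sift, 2), ppved = round(ppved, 2))
    # rounding must not move a score across its strict threshold
    scores$sift4g[impact] <- pmin(scores$sift4g[impact], 0.04)
    scores$ppved[impact] <- pmax(scores$ppved[impact], 0.55)
    scores$provean[impact] <- pmin(scores$provean[impact], -2.6)
    variants$impactful[is_sub] <- impact
  } else {
    scores <- data.frame(gene = character(), label = character(),
                         provean = numeric(), sift4g = numeric(),
                         ppved = numeric())
  }

  paths <- list(
    wild_cds = file.path(dir, "wild_cds.fa"),
    wild_proteins = file.path(dir, "wild_proteins.fa"),
    scores = file.path(dir, "scores.tsv"),
    variants = file.path(dir, "ground_truth_variants.tsv"),
    snvs = file.path(dir, "ground_truth_snvs.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(wild_cds),
                              paths$wild_cds)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(wild_prot),
                              paths$wild_proteins)
  write_tsv(scores, paths$scores)
  write_tsv(variants, paths$variants)
  write_tsv(snvs, paths$snvs)

  structure(list(config = config, variants = variants, snvs = snvs,
                 scores = scores, wild_cds = wild_cds,
                 wild_proteins = wild_prot, paths = paths,
                 chrom_lengths = reference$chrom_lengths),
            class = "SyntheticGroundTruth")
}
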