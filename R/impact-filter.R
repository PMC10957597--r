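#' Read a deleteriousness score table
#'
#' Loads the per-variant score triples consumed by the filtering stage:
#' tab-separated with header \code{gene}, \code{label}, \code{provean},
#' \code{sift4g}, \code{ppved}; empty fields are missing scores. SIFT4G and
#' PPVED values must lie in [0, 1] when present.
#'
#' @param path TSV path.
#' @return data.frame with the five columns, scores numeric with NA for
#'   missing.
#' @export
readScoreTable <- function(path) {
  tab <- read_tsv(path)
  need <- c("gene", "label", "provean", "sift4g", "ppved")
  if (!all(need %in% colnames(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  for (s in c("provean", "sift4g", "ppved")) tab[[s]] <- as.numeric(tab[[s]])
  for (s in c("sift4g", "ppved")) {
    bad <- !is.na(tab[[s]]) & (tab[[s]] < 0 | tab[[s]] > 1)
    if (any(bad)) stop(s, " scores outside [0, 1]")
  }
  tab
}

#' Parse raw PROVEAN output
#'
#' Reads the two-column (variant, score) tab-separated output of the PROVEAN
#' protein batch tool, skipping \code{#} comment lines, and returns a
#' (label, provean) data.frame.
#'
#' @param path PROVEAN output file.
#' @param gene gene id to attach.
#' @export
readProveanOutput <- function(path, gene = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  data.frame(gene = gene, label = tab[[1]], provean = as.numeric(tab[[2]]))
}

#' Parse SIFT4G tabular output
#'
#' Reads a SIFT4G-style tab-separated prediction table, taking the amino acid
#' change column and the SIFT score column (matched case-insensitively on
#' header names containing \code{variant}/\code{substitution}/\code{aa} and
#' \code{sift}).
#'
#' @param path SIFT4G output file with header.
#' @param gene gene id to attach.
#' @export
readSift4gOutput <- function(path, gene = NA_character_) {
  tab <- read_tsv(path)
  nm <- tolower(colnames(tab))
  vcol <- which(grepl("variant|substitution|aa[_ ]?change", nm))[1]
  scol <- which(grepl("sift", nm))[1]
  if (is.na(vcol) || is.na(scol))
    stop("cannot locate variant / SIFT score columns in ", path)
  data.frame(gene = gene, label = tab[[vcol]],
             sift4g = as.numeric(tab[[scol]]))
}

.join_scores <- function(variants, scores) {
  key <- paste(variants$gene, variants$label)
  skey <- paste(scores$gene, scores$label)
  idx <- match(key, skey)
  if (anyNA(idx)) {
    miss <- unique(paste0(variants$gene[is.na(idx)], ":",
                          variants$label[is.na(idx)]))
    warning(length(miss), " variant(s) without scores (treated as missing): ",
            paste(utils::head(miss, 5), collapse = ", "))
  }
  cbind(variants,
        provean = scores$provean[idx],
        sift4g = if ("sift4g" %in% colnames(scores)) scores$sift4g[idx] else
          NA_real_,
        ppved = if ("ppved" %in% colnames(scores)) scores$ppved[idx] else
          NA_real_)
}

#' PROVEAN deleteriousness screen
#'
#' First filtering stage: a variant passes when its PROVEAN score is strictly
#' below the threshold (default −2.5, the conventional deleteriousness
#' cutoff); a missing score fails. A gene is retained when at least one of its
#' variants passes.
#'
#' @param variants data.frame with \code{gene} and \code{label} columns (as
#'   from [extractAAVariants()], substitutions).
#' @param scores score table joinable by (gene, label), e.g. from
#'   [readScoreTable()].
#' @param threshold strict PROVEAN cutoff.
#' @return list with \code{variants} (input plus \code{provean} and logical
#'   \code{pass}), \code{genes} (sorted retained gene ids) and
#'   \code{dropped_genes}.
#' @export
proveanScreen <- function(variants, scores, threshold = -2.5) {
  joined <- .join_scores(variants, scores)
  joined$pass <- !is.na(joined$provean) & joined$provean < threshold
  genes <- sort(unique(joined$gene[joined$pass]))
  list(variants = joined, genes = genes,
       dropped_genes = setdiff(sort(unique(joined$gene)), genes))
}

#' Triple-threshold impact classification
#'
#' Final filtering stage: a substitution is called impactful when all three
#' predictors agree, under strict inequalities — PROVEAN strictly below
#' \code{provean_thr}, SIFT4G strictly below \code{sift_thr} and PPVED
#' strictly above \code{ppved_thr}. Any missing score is a conservative
#' failure.
#'
#' @param scores data.frame with \code{gene}, \code{label}, \code{provean},
#'   \code{sift4g}, \code{ppved}.
#' @param provean_thr,sift_thr,ppved_thr the three strict thresholds
#'   (defaults −2.5, 0.05, 0.5).
#' @return the input with logical columns \code{provean_pass},
#'   \code{sift_pass}, \code{ppved_pass} and \code{impactful}; summary counts
#'   (variants, impactful variants, genes with an impactful variant, variants
#'   with missing scores) attached as attribute \code{"summary"}.
#' @examples
#' scores <- readScoreTable(system.file("extdata", "tomato_impact_scores.tsv",
#'                                      package = "WildAlleleScan"))
#' cls <- classifyImpactful(scores)
#' cls$label[cls$impactful]
#' @export
classifyImpactful <- function(scores, provean_thr = -2.5, sift_thr = 0.05,
                              ppved_thr = 0.5) {
  scores$provean_pass <- !is.na(scores$provean) & scores$provean < provean_thr
  scores$sift_pass <- !is.na(scores$sift4g) & scores$sift4g < sift_thr
  scores$ppved_pass <- !is.na(scores$ppved) & scores$ppved > ppved_thr
  scores$impactful <- scores$provean_pass & scores$sift_pass &
    scores$ppved_pass
  attr(scores, "summary") <- c(
    n_variants = nrow(scores),
    n_impactful = sum(scores$impactful),
    n_genes_impactful = length(unique(scores$gene[scores$impactful])),
    n_missing_any = sum(is.na(scores$provean) | is.na(scores$sift4g) |
                          is.na(scores$ppved)))
  scores
}
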