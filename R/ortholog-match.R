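#' Extract sequences from a FASTA set by id
#'
#' Returns the requested records in id order; ids absent from the set are
#' reported rather than silently dropped.
#'
#' @param fasta an \code{XStringSet} (or path to a FASTA file, read as DNA).
#' @param ids unique sequence ids to extract.
#' @return list with \code{sequences} (XStringSet in id order) and
#'   \code{missing} (ids not found).
#' @export
extractSequences <- function(fasta, ids) {
  if (is.character(fasta) && length(fasta) == 1L)
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (anyDuplicated(ids)) stop("ids must be unique")
  found <- ids[ids %in% names(fasta)]
  missing <- setdiff(ids, found)
  if (length(missing))
    warning("ids absent from FASTA: ", paste(missing, collapse = ", "))
  list(sequences = fasta[found], missing = missing)
}

# Alignment parameter sets mirroring common blast defaults: blastn-like
# +2/-3 with gap open 5 extend 2 for nucleotide mode, BLOSUM62 with gap open
# 11 extend 1 for protein mode.
.hit_params <- function(mode) {
  if (mode == "nucleotide") {
    list(substitutionMatrix =
           Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE),
         gapOpening = 5, gapExtension = 2)
  } else {
    list(substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  }
}

.percent_identity <- function(aln) {
  Biostrings::pid(aln, type = "PID1")
}

#' Best local-alignment hit with a query-coverage floor
#'
#' Aligns a query against every subject with affine-gap local (Smith-Waterman)
#' alignment and returns the highest-scoring subject among those whose single
#' best local alignment spans at least \code{min_qcov} percent of the query
#' (per-HSP query-coverage semantics). Ties are broken by higher percent
#' identity, then by lexicographically smallest subject id.
#'
#' @param query a single \code{DNAString}/\code{AAString} (or character).
#' @param subjects an \code{XStringSet} of candidate subjects.
#' @param min_qcov minimum query coverage in percent (default 90).
#' @param mode \code{"nucleotide"} (blastn-like scoring) or
#'   \code{"protein"} (BLOSUM62).
#' @return one-row data.frame (\code{query_id}, \code{subject_id},
#'   \code{score}, \code{qcov}, \code{pident}) or \code{NULL} when no subject
#'   passes the coverage floor.
#' @export
bestHit <- function(query, subjects, min_qcov = 90, mode = c("nucleotide",
                                                             "protein")) {
  mode <- match.arg(mode)
  if (length(subjects) == 0L) {
    warning("empty subject set")
    return(NULL)
  }
  p <- .hit_params(mode)
  qid <- if (!is.null(names(query))) names(query)[1L] else NA_character_
  if (methods::is(query, "XStringSet")) {
    if (length(query) != 1L) stop("'query' must be a single sequence")
    query <- query[[1L]]
  }
  qlen <- if (is.character(query)) nchar(query) else length(query)
  hits <- lapply(seq_along(subjects), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      query, subjects[[i]], type = "local",
      substitutionMatrix = p$substitutionMatrix,
      gapOpening = p$gapOpening, gapExtension = p$gapExtension)
    span <- Biostrings::width(Biostrings::pattern(aln))
    data.frame(query_id = qid, subject_id = names(subjects)[i],
               score = Biostrings::score(aln),
               qcov = 100 * span / qlen,
               pident = .percent_identity(aln))
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$qcov >= min_qcov, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$score, -hits$pident, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[1L, , drop = FALSE]
}

#' Match each query sequence to its counterpart in a reference set
#'
#' Runs [bestHit()] for every query and assembles a hit table; queries with no
#' passing hit are listed separately. A reciprocal-best flag is set when the
#' matched subject's own best hit (against the query set) is the query.
#'
#' @param queries,subjects \code{XStringSet}s (e.g. wild-species CDS vs
#'   reference CDS).
#' @param min_qcov coverage floor in percent.
#' @param mode alignment mode, see [bestHit()].
#' @param reciprocal also compute the reciprocal-best flag (slower).
#' @return list with \code{hits} (data.frame query_id, subject_id, score,
#'   qcov, pident and, when requested, reciprocal_best) and \code{unmatched}
#'   (query ids with no passing hit).
#' @export
matchOrthologs <- function(queries, subjects, min_qcov = 90,
                           mode = c("nucleotide", "protein"),
                           reciprocal = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  unmatched <- character()
  for (qid in names(queries)) {
    q <- queries[qid]
    h <- bestHit(q, subjects, min_qcov = min_qcov, mode = mode)
    if (is.null(h)) unmatched <- c(unmatched, qid)
    else {
      h$query_id <- qid
      rows[[qid]] <- h
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), subject_id = character(),
               score = numeric(), qcov = numeric(), pident = numeric())
  rownames(hits) <- NULL
  if (reciprocal && nrow(hits)) {
    hits$reciprocal_best <- vapply(seq_len(nrow(hits)), function(i) {
      back <- bestHit(subjects[hits$subject_id[i]], queries,
                      min_qcov = min_qcov, mode = mode)
      !is.null(back) && back$subject_id == hits$query_id[i]
    }, logical(1))
  }
  list(hits = hits, unmatched = unmatched)
}

#' Import precomputed tabular hits
#'
#' Accepts a 6-column tab-separated hit file (query, subject, score, qcov,
#' pident, optional extra columns ignored) as the alternative to the internal
#' aligner, applies the coverage floor and keeps the best hit per query under
#' the same tie-breaking as [bestHit()].
#'
#' @param path tabular hit file (no header or header starting with
#'   \code{query}).
#' @param min_qcov coverage floor in percent.
#' @return data.frame as in [matchOrthologs()]'s \code{hits}.
#' @export
importHits <- function(path, min_qcov = 90) {
  first <- readLines(path, n = 1L)
  header <- grepl("^query", first)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  tab <- tab[, 1:5]
  colnames(tab) <- c("query_id", "subject_id", "score", "qcov", "pident")
  tab <- tab[tab$qcov >= min_qcov, , drop = FALSE]
  tab <- tab[order(tab$query_id, -tab$score, -tab$pident, tab$subject_id), ,
             drop = FALSE]
  tab <- tab[!duplicated(tab$query_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
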