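#' Read a GO annotation table
#'
#' Loads a tab-separated annotation table with columns \code{gene_id},
#' \code{go_id} and \code{go_name}, drops duplicated (gene_id, go_id) pairs
#' and checks that GO identifiers are syntactically valid
#' (\code{GO:} followed by seven digits).
#'
#' @param path TSV file with header \code{gene_id}, \code{go_id},
#'   \code{go_name}.
#' @return data.frame with the three columns above.
#' @export
readGOTable <- function(path) {
  tab <- read_tsv(path)
  need <- c("gene_id", "go_id", "go_name")
  if (!all(need %in% colnames(tab)))
    stop("GO table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  bad <- !grepl("^GO:[0-9]{7}$", tab$go_id)
  if (any(bad))
    stop("malformed GO ids: ", paste(unique(tab$go_id[bad]), collapse = ", "))
  tab[!duplicated(tab[, c("gene_id", "go_id")]), , drop = FALSE]
}

#' Keyword search over GO term names
#'
#' Returns the GO terms whose name contains at least one keyword as a
#' case-insensitive substring. This is the term-selection step of the
#' pipeline: searching for salt-, salinity-, water- and drought-related terms
#' in a flat annotation catalogue (no GO-graph traversal).
#'
#' @param table data.frame with at least \code{go_id} and \code{go_name}
#'   columns (a full annotation table from [readGOTable()] or a plain term
#'   catalogue).
#' @param keywords character vector of non-empty keywords.
#' @return data.frame (\code{go_id}, \code{go_name}) of the unique matching
#'   terms, sorted by \code{go_id}.
#' @examples
#' cat_path <- system.file("extdata", "go_term_catalogue.tsv",
#'                         package = "WildAlleleScan")
#' catalogue <- read.delim(cat_path)
#' searchGOTerms(catalogue, c("salt", "salinity", "water", "drought"))
#' @export
searchGOTerms <- function(table, keywords) {
  if (nrow(table) == 0L) {
    warning("empty GO table")
    return(data.frame(go_id = character(), go_name = character()))
  }
  keywords <- keywords[nzchar(keywords)]
  terms <- unique(table[, c("go_id", "go_name")])
  if (length(keywords) == 0L)
    return(data.frame(go_id = character(), go_name = character()))
  nm <- tolower(terms$go_name)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
    grepl(k, nm, fixed = TRUE)))
  out <- terms[hit, , drop = FALSE]
  out <- out[order(out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the genes annotated with any of a set of GO terms
#'
#' @param table annotation data.frame from [readGOTable()].
#' @param go_ids character vector of selected GO ids.
#' @return sorted character vector of unique gene ids annotated with at least
#'   one selected term.
#' @export
selectGenes <- function(table, go_ids) {
  if (length(go_ids) == 0L) return(character())
  sort(unique(table$gene_id[table$go_id %in% go_ids]))
}
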