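.check_protein <- function(x, what) {
  ok <- c(AA_ALPHABET20, "X", "*")
  bad <- setdiff(strsplit(as.character(x), "")[[1]], ok)
  if (length(bad))
    stop(what, " contains non-amino-acid symbols: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Globally align a reference/wild protein pair
#'
#' Affine-gap global alignment (BLOSUM62, gap opening 10, gap extension 0.5),
#' the in-package stand-in for an external protein aligner. Pre-aligned FASTA
#' can be supplied instead through [readProteinAlignment()].
#'
#' @param ref,wild single amino-acid sequences (character or \code{AAString});
#'   the 20 standard residues plus \code{X} are accepted.
#' @param ref_name,wild_name row names recorded in the alignment.
#' @return a \code{ProteinAlignment}: a list with \code{ref}/\code{wild}
#'   gapped character rows (equal length) and the two names, class
#'   \code{"ProteinAlignment"}.
#' @examples
#' alignProteinPair("MKTE", "MRTE")
#' @export
alignProteinPair <- function(ref, wild, ref_name = "ref", wild_name = "wild") {
  ref <- as.character(ref); wild <- as.character(wild)
  if (!nzchar(ref) || !nzchar(wild)) stop("empty protein sequence")
  .check_protein(ref, "reference protein")
  .check_protein(wild, "wild protein")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(wild), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  out <- list(ref = as.character(Biostrings::alignedPattern(aln)),
              wild = as.character(Biostrings::alignedSubject(aln)),
              ref_name = ref_name, wild_name = wild_name,
              score = Biostrings::score(aln))
  class(out) <- "ProteinAlignment"
  out
}

#' Read a pre-aligned protein pair from aligned FASTA
#'
#' Import path for alignments produced externally (e.g. by an MSA program):
#' the file must contain the designated reference and wild rows, gapped with
#' \code{-}, of equal length.
#'
#' @param path aligned FASTA.
#' @param ref_name,wild_name record ids of the reference and wild rows.
#' @return a \code{ProteinAlignment} (see [alignProteinPair()]).
#' @export
readProteinAlignment <- function(path, ref_name, wild_name) {
  aa <- Biostrings::readAAStringSet(path)
  if (!all(c(ref_name, wild_name) %in% names(aa)))
    stop("alignment must contain rows '", ref_name, "' and '", wild_name, "'")
  r <- as.character(aa[[ref_name]]); w <- as.character(aa[[wild_name]])
  if (nchar(r) != nchar(w)) stop("aligned rows differ in length")
  out <- list(ref = r, wild = w, ref_name = ref_name, wild_name = wild_name,
              score = NA_real_)
  class(out) <- "ProteinAlignment"
  out
}

#' Extract amino acid variants from a pairwise protein alignment
#'
#' Walks the alignment columns and reports, in reference-protein coordinates:
#' one substitution per mismatch column (both residues present), one insertion
#' per maximal run of gaps in the reference (anchored to the preceding
#' reference position), and one deletion per maximal run of gaps in the wild
#' row. Columns containing \code{X} in either row are skipped and counted.
#' Substitution labels put the wild residue first, then the 1-based reference
#' position, then the reference residue (e.g. \code{P63A}: proline in the wild
#' species where the reference has alanine at position 63).
#'
#' @param alignment a \code{ProteinAlignment}.
#' @param gene_id gene identifier attached to every variant.
#' @return data.frame with columns \code{gene}, \code{kind}
#'   (substitution/insertion/deletion), \code{position} (1-based ungapped
#'   reference position; for insertions, the reference position immediately
#'   before the insertion, 0 for an N-terminal insertion), \code{wild_aa},
#'   \code{ref_aa} and \code{label} (substitutions only). The number of
#'   skipped X-containing columns is attached as attribute
#'   \code{"skipped_x_columns"}.
#' @export
extractAAVariants <- function(alignment, gene_id = NA_character_) {
  stopifnot(inherits(alignment, "ProteinAlignment"))
  r <- strsplit(alignment$ref, "")[[1]]
  w <- strsplit(alignment$wild, "")[[1]]
  if (length(r) != length(w)) stop("malformed alignment: unequal row lengths")
  if (any(r == "-" & w == "-")) stop("malformed alignment: all-gap column")
  n <- length(r)
  refpos <- cumsum(r != "-")          # ungapped reference position per column
  skip <- (r == "X" | w == "X")
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (skip[i]) { i <- i + 1L; next }
    if (r[i] != "-" && w[i] != "-") {
      if (r[i] != w[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene_id, kind = "substitution", position = refpos[i],
          wild_aa = w[i], ref_aa = r[i],
          label = paste0(w[i], refpos[i], r[i]))
      }
      i <- i + 1L
    } else if (r[i] == "-") {         # insertion in wild
      j <- i
      while (j < n && r[j + 1L] == "-" && !skip[j + 1L]) j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene_id, kind = "insertion", position = refpos[i],
        wild_aa = paste(w[i:j], collapse = ""), ref_aa = "",
        label = NA_character_)
      i <- j + 1L
    } else {                          # gap in wild: deletion
      j <- i
      while (j < n && w[j + 1L] == "-" && !skip[j + 1L]) j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene_id, kind = "deletion", position = refpos[i],
        wild_aa = "", ref_aa = paste(r[i:j], collapse = ""),
        label = NA_character_)
      i <- j + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), kind = character(), position = integer(),
               wild_aa = character(), ref_aa = character(),
               label = character())
  rownames(out) <- NULL
  attr(out, "skipped_x_columns") <- sum(skip)
  out
}
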