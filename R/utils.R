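# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV conventions used for every intermediate: tab-separated, header, no
# quoting, "" for NA, so outputs are diffable and byte-stable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE, ...)
}

# Amino acids a protein sequence may contain (X = unknown, handled specially
# by variant extraction).
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Codons of the standard genetic code, grouped by amino acid; derived once
# from Biostrings' GENETIC_CODE.
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

# Translate a character CDS (no ambiguity letters) to a character protein.
# no.init.codon: a lone CTG/TTG codon must translate as L, not as an
# alternative initiator M.
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}
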