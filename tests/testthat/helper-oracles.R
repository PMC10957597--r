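# Independent oracles, deliberately written without the package's (or
# Biostrings') machinery wherever the point is to cross-check it.

# --- standard genetic code, hand-coded -------------------------------------
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(ORACLE_CODON_TABLE[codons], collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# --- brute-force affine-gap alignment (Gotoh), quadratic -------------------
# Gap of length L costs open + L * ext, matching the package's aligner
# convention. submat is a lookup matrix; type "global" or "local".
oracle_align_score <- function(a, b, submat, open, ext, type = "global") {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      if (type == "local") {
        M[i + 1, j + 1] <- max(M[i + 1, j + 1], s, 0)
        best_local <- max(best_local, M[i + 1, j + 1])
      }
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else best_local
}

oracle_nuc_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

oracle_blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
}

# --- reconstruction of the wild protein from an extracted variant list ----
# Applies substitutions / insertions / deletions right-to-left in reference
# coordinates; independent of the extraction's internal column walk.
oracle_apply_variants <- function(ref, variants) {
  s <- strsplit(ref, "")[[1]]
  if (nrow(variants) == 0L) return(ref)
  ord <- order(-variants$position)
  for (i in ord) {
    v <- variants[i, ]
    p <- v$position
    if (v$kind == "substitution") {
      s[p] <- v$wild_aa
    } else if (v$kind == "deletion") {
      s <- s[-(p:(p + nchar(v$ref_aa) - 1L))]
    } else {
      ins <- strsplit(v$wild_aa, "")[[1]]
      s <- append(s, ins, after = p)
    }
  }
  paste(s, collapse = "")
}

random_protein <- function(n) {
  paste(c("M", sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                      n - 1, replace = TRUE)), collapse = "")
}
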