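test_that("identical sequences give a gap-free alignment and no variants", {
  aln <- alignProteinPair("MKTEAA", "MKTEAA")
  expect_false(grepl("-", aln$ref))
  expect_false(grepl("-", aln$wild))
  expect_equal(nrow(extractAAVariants(aln, "g")), 0L)
})

test_that("global alignment score matches the exhaustive DP oracle on small pairs", {
  bl <- oracle_blosum62()
  aln <- alignProteinPair("MKTE", "MRTE")
  expect_equal(aln$score,
               oracle_align_score("MKTE", "MRTE", bl, 10, 0.5, "global"))
  expect_false(grepl("-", aln$ref))
  set.seed(5)
  for (i in 1:5) {
    a <- random_protein(sample(20:60, 1))
    b <- random_protein(sample(20:60, 1))
    expect_equal(alignProteinPair(a, b)$score,
                 oracle_align_score(a, b, bl, 10, 0.5, "global"),
                 info = paste("pair", i))
  }
})

test_that("ungapping the aligned rows reproduces the inputs", {
  set.seed(6)
  for (i in 1:5) {
    a <- random_protein(40)
    b <- random_protein(45)
    aln <- alignProteinPair(a, b)
    expect_equal(gsub("-", "", aln$ref), a)
    expect_equal(gsub("-", "", aln$wild), b)
  }
})

test_that("non-amino-acid symbols are rejected, X is tolerated", {
  expect_error(alignProteinPair("MK1TE", "MKTE"), "non-amino-acid")
  expect_silent(alignProteinPair("MKXTE", "MKTE"))
})

test_that("a hand-checked column walk yields single indel events with reference coordinates", {
  mk_aln <- function(r, w) structure(list(ref = r, wild = w,
                                          ref_name = "ref",
                                          wild_name = "wild"),
                                     class = "ProteinAlignment")
  # deletion of A at reference position 3
  del <- extractAAVariants(mk_aln("MKATE", "MK-TE"), "g")
  expect_equal(del$kind, "deletion")
  expect_equal(del$position, 3L)
  expect_equal(del$ref_aa, "A")
  # insertion of A after reference position 2
  ins <- extractAAVariants(mk_aln("MK-TE", "MKATE"), "g")
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$position, 2L)
  expect_equal(ins$wild_aa, "A")
  # multi-residue run collapses to one event
  ins2 <- extractAAVariants(mk_aln("MK--TE", "MKAGTE"), "g")
  expect_equal(nrow(ins2), 1L)
  expect_equal(ins2$wild_aa, "AG")
  # all-gap column is malformed
  expect_error(extractAAVariants(mk_aln("MK-TE", "MK-TE"), "g"), "all-gap")
})

test_that("substitution labels put the wild residue first (wild P over reference A at 63 is P63A)", {
  ref <- random_protein(80)
  substr(ref, 63, 63) <- "A"
  wild <- ref
  substr(wild, 63, 63) <- "P"
  aln <- alignProteinPair(ref, wild)
  v <- extractAAVariants(aln, "g")
  expect_equal(nrow(v), 1L)
  expect_equal(v$label, "P63A")
  expect_equal(v$wild_aa, "P")
  expect_equal(v$ref_aa, "A")
})

test_that("columns containing X are skipped and counted", {
  mk_aln <- function(r, w) structure(list(ref = r, wild = w,
                                          ref_name = "ref",
                                          wild_name = "wild"),
                                     class = "ProteinAlignment")
  v <- extractAAVariants(mk_aln("MKXTE", "MKRTE"), "g")
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "skipped_x_columns"), 1L)
})

test_that("applying the extracted variants reconstructs the wild protein (round trip)", {
  set.seed(12)
  for (i in 1:10) {
    ref <- random_protein(sample(60:150, 1))
    v <- strsplit(ref, "")[[1]]
    # plant well-separated events
    pos <- sort(sample(5:(length(v) - 5), 4))
    pos <- pos[c(TRUE, diff(pos) >= 8)]
    wild <- v
    ops <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE)
    for (k in rev(seq_along(pos))) {
      p <- pos[k]
      if (ops[k] == "sub")
        wild[p] <- sample(setdiff(c("A", "R", "N", "D", "E"), wild[p]), 1)
      else if (ops[k] == "del") wild <- wild[-p]
      else wild <- append(wild, sample(c("G", "H", "W"), 1), after = p)
    }
    wild <- paste(wild, collapse = "")
    aln <- alignProteinPair(ref, wild)
    vars <- extractAAVariants(aln, "g")
    expect_equal(oracle_apply_variants(ref, vars), wild, info = paste("it", i))
  }
})

test_that("pre-aligned FASTA import preserves the external alignment verbatim", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">refseq", "MKA-TE", ">wildseq", "MK-GTE"), tmp)
  aln <- readProteinAlignment(tmp, "refseq", "wildseq")
  expect_equal(aln$ref, "MKA-TE")
  expect_equal(aln$wild, "MK-GTE")
  v <- extractAAVariants(aln, "g")
  expect_setequal(v$kind, c("deletion", "insertion"))
})
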