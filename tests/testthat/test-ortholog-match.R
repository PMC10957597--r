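test_that("extractSequences returns records byte-identical in id order and reports missing ids", {
  fa <- Biostrings::DNAStringSet(c(a = "ACGT", b = "GGGTT", c = "TTTT"))
  out <- extractSequences(fa, c("c", "a"))
  expect_equal(names(out$sequences), c("c", "a"))
  expect_equal(as.character(out$sequences[["a"]]), "ACGT")
  expect_length(out$missing, 0)

  expect_warning(out2 <- extractSequences(fa, c("a", "zz", "b")), "zz")
  expect_equal(names(out2$sequences), c("a", "b"))
  expect_equal(out2$missing, "zz")

  # round-trip through FASTA preserves id and sequence
  tmp <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(out$sequences, tmp)
  back <- Biostrings::readDNAStringSet(tmp)
  expect_equal(as.character(back), as.character(out$sequences))
})

test_that("bestHit finds the identical subject with full coverage and identity", {
  subjects <- Biostrings::DNAStringSet(c(
    s1 = "ATGGCATTTGCGCCTAGATAG", s2 = "ATGCCCAAATTTGGGCCCTAA"))
  h <- bestHit(Biostrings::DNAString("ATGGCATTTGCGCCTAGATAG"), subjects)
  expect_equal(h$subject_id, "s1")
  expect_equal(h$qcov, 100)
  expect_equal(h$pident, 100)
})

test_that("bestHit ranks subjects by planted identity and matches the DP oracle score", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  mutate <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), n)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  subjects <- Biostrings::DNAStringSet(c(
    near = mutate(base, 6), mid = mutate(base, 24), far = mutate(base, 48)))
  h <- bestHit(Biostrings::DNAString(base), subjects, min_qcov = 90)
  expect_equal(h$subject_id, "near")
  # oracle: quadratic Smith-Waterman with the same scoring scheme
  osc <- oracle_align_score(base, as.character(subjects[["near"]]),
                            oracle_nuc_matrix(), open = 5, ext = 2,
                            type = "local")
  expect_equal(h$score, osc)
})

test_that("protein-mode local alignment equals the brute-force oracle on random toys", {
  set.seed(7)
  bl <- oracle_blosum62()
  for (i in 1:5) {
    a <- random_protein(sample(30:80, 1))
    b <- random_protein(sample(30:80, 1))
    h <- bestHit(Biostrings::AAString(a),
                 Biostrings::AAStringSet(c(s = b)),
                 min_qcov = 0, mode = "protein")
    osc <- oracle_align_score(a, b, bl, open = 11, ext = 1, type = "local")
    expect_equal(h$score, osc, info = paste("toy", i))
  }
})

test_that("the query-coverage floor rejects partial hits and lowering it never lowers the score", {
  set.seed(9)
  q <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
             collapse = "")
  # subject contains only 85% of the query
  subjects <- Biostrings::DNAStringSet(c(part = substr(q, 1, 85)))
  expect_null(bestHit(Biostrings::DNAString(q), subjects, min_qcov = 90))
  h <- bestHit(Biostrings::DNAString(q), subjects, min_qcov = 50)
  expect_false(is.null(h))
  expect_lt(h$qcov, 90)
  h0 <- bestHit(Biostrings::DNAString(q), subjects, min_qcov = 0)
  expect_gte(h0$score, h$score)
})

test_that("reciprocal-best flag is set on a mutually-best toy pair", {
  set.seed(11)
  a <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  b <- chartr("A", "C", a)  # diverged partner
  other <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
  queries <- Biostrings::DNAStringSet(c(qa = a))
  subjects <- Biostrings::DNAStringSet(c(sa = a, sx = other))
  mo <- matchOrthologs(queries, subjects, min_qcov = 90, reciprocal = TRUE)
  expect_equal(mo$hits$subject_id, "sa")
  expect_true(mo$hits$reciprocal_best)
})

test_that("importHits applies the coverage floor and best-per-query tie-breaking", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t100\t95\t98", "q1\ts2\t100\t95\t99",
               "q1\ts3\t120\t85\t99", "q2\ts1\t80\t91\t90"), tmp)
  hits <- importHits(tmp, min_qcov = 90)
  expect_equal(nrow(hits), 2L)
  # s3 excluded by coverage; tie on score broken by higher identity
  expect_equal(hits$subject_id[hits$query_id == "q1"], "s2")
})
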