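test_that("feature TSV reading gives the printed organization table's structure", {
  g <- read_feature_tsv(table2_path())
  expect_s3_class(g, "mitogenome")
  expect_true(is.na(g$sequence))
  counts <- table(g$features$category)
  expect_equal(unname(counts[c("PCG", "tRNA", "rRNA", "control")]),
               c(13L, 22L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(g$length_bp, 16933L)
  # sorted by start, coordinates within bounds
  expect_true(!is.unsorted(g$features$start))
  expect_true(all(g$features$end <= 16933L))
})

test_that("feature TSV edge cases: single row, shuffled rows, bad coordinates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tStrand\tStart\tEnd\tCategory\tAnticodon",
               "ND1\tH\t100\t500\tPCG\t-"), tmp)
  g <- read_feature_tsv(tmp)
  expect_equal(nrow(g$features), 1L)

  writeLines(c("Gene\tStrand\tStart\tEnd\tCategory\tAnticodon",
               "B\tH\t300\t400\trRNA\t-",
               "A\tH\t1\t100\ttRNA\tGAA"), tmp)
  g <- read_feature_tsv(tmp)
  expect_equal(g$features$name, c("A", "B"))  # re-sorted by start

  writeLines(c("Gene\tStrand\tStart\tEnd\tCategory\tAnticodon",
               "A\tH\txx\t100\ttRNA\tGAA"), tmp)
  expect_error(read_feature_tsv(tmp), "coordinates")

  writeLines(c("Gene\tStrand\tStart\tEnd\tCategory\tAnticodon",
               "A\tH\t1\t100\ttRNA\tGAA",
               "A\tH\t200\t300\ttRNA\tGAA"), tmp)
  expect_error(read_feature_tsv(tmp), "duplicate")
})

test_that("GenBank parsing maps complement features to the L strand", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST 60 bp    DNA     circular   UNA 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(10..30)",
    '                     /gene="ND6"',
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), tmp)
  g <- read_genbank(tmp)
  f <- g$features
  expect_equal(f$name, "ND6")
  expect_equal(f$category, "PCG")
  expect_equal(f$strand, "L")
  expect_equal(c(f$start, f$end), c(10L, 30L))
  expect_equal(nchar(g$sequence), 60L)
})

test_that("GenBank degenerate and malformed records", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 4 bp DNA circular", "ORIGIN",
               "        1 acgt", "//"), tmp)
  g <- read_genbank(tmp)
  expect_equal(nrow(g$features), 0L)

  writeLines(c("LOCUS       X 4 bp DNA circular",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..30"), tmp)
  expect_error(read_genbank(tmp), "ORIGIN")

  writeLines(c("LOCUS       X 4 bp DNA circular",
               "FEATURES             Location/Qualifiers",
               "     CDS             botched",
               '                     /gene="Z"',
               "ORIGIN", "        1 acgt", "//"), tmp)
  expect_error(read_genbank(tmp), "malformed")
})

test_that("sequence extraction respects strand and inclusive coordinates", {
  toy <- toy_genome()
  g <- toy$genome
  expect_equal(extract_feature_seq(g, "PCGH"), toy$pcg_h)
  expect_equal(extract_feature_seq(g, "PCGL"), toy$pcg_l_sense)
  expect_equal(extract_feature_seq(g, "tRNA-Met"), toy$trna$seq)
  # length identity on every feature
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, , drop = FALSE]
    expect_equal(nchar(extract_feature_seq(g, f)), f$end - f$start + 1L)
  }
  gf <- mitogenome(features = g$features, length_bp = g$length_bp)
  expect_error(extract_feature_seq(gf, "PCGH"), "sequence-free")
})

test_that("GenBank and FASTA round trips are the identity", {
  toy <- toy_genome()
  gb <- withr::local_tempfile(fileext = ".gb")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genbank(toy$genome, gb)
  g2 <- read_genbank(gb)
  expect_identical(g2$sequence, toy$genome$sequence)
  expect_identical(g2$features, toy$genome$features)
  write_fasta_genome(toy$genome, fa)
  expect_identical(read_fasta_genome(fa)$sequence, toy$genome$sequence)
})

test_that("mitogenome validation rejects bad input", {
  expect_error(mitogenome(sequence = "ACGTX"), "outside")
  expect_error(mitogenome(sequence = ""), "non-empty")
  f <- data.frame(name = "A", category = "PCG", strand = "H",
                  start = 10, end = 5)
  expect_error(mitogenome(sequence = "ACGT", features = f))
  f2 <- data.frame(name = "A", category = "tRNA", strand = "Q",
                   start = 1, end = 4)
  expect_error(mitogenome(sequence = "ACGT", features = f2), "strand")
})

test_that("revcomp is an involution and handles N", {
  expect_equal(revcomp("ATGC"), "GCAT")
  expect_equal(revcomp("AANTT"), "AANTT")
  set.seed(5)
  s <- rand_dna(200)
  expect_equal(revcomp(revcomp(s)), s)
})
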