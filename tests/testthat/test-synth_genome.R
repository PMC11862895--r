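test_that("default spec reproduces the published-style layout field for field", {
  sp <- genome_spec(seed = 3)
  gm <- generate_mitogenome(sp)
  g <- gm$genome
  expect_equal(g$length_bp, 16933L)
  expect_equal(sum(g$features$category == "PCG"), 13L)
  expect_equal(sum(g$features$category == "tRNA"), 22L)
  tab <- build_table(g)
  to <- gm$truth_organization
  expect_equal(tab$gene, to$gene)
  expect_equal(tab$size_bp, to$size_bp)
  expect_equal(tab$continuity, to$continuity)
  pc <- tab$category == "PCG"
  expect_equal(tab$start_codon[pc], to$start_codon[pc])
  expect_equal(tab$stop_codon[pc], to$stop_codon[pc])
  expect_false(any(tab$flagged))
  # the planted ATP8/ATP6-style overlap comes out at -43
  expect_equal(tab$continuity[tab$gene == "ATP6"], -43L)
})

test_that("coordinates derive correctly from Size + Continuity specs", {
  f <- data.frame(Gene = c("A", "B", "C"), Category = c("rRNA", "PCG", "tRNA"),
                  Strand = c("H", "H", "H"),
                  Size = c(100L, 300L, 68L), Continuity = c(4L, 0L, -1L),
                  Anticodon = c(NA, NA, "CAT"),
                  StartCodon = c(NA, "ATG", NA), StopCodon = c(NA, "TAA", NA))
  sp <- genome_spec(features = f, seed = 1)
  expect_equal(sp$features$Start, c(5L, 105L, 404L))
  expect_equal(sp$features$End, c(104L, 404L, 471L))
  gm <- generate_mitogenome(sp)
  expect_equal(build_table(gm$genome)$continuity, c(4L, 0L, -1L))
})

test_that("single-gene and infeasible specs", {
  f1 <- data.frame(Gene = "solo", Category = "PCG", Strand = "H",
                   Size = 90L, Continuity = 0L,
                   StartCodon = "ATG", StopCodon = "TAA")
  gm <- generate_mitogenome(genome_spec(features = f1, seed = 2))
  expect_equal(nrow(gm$genome$features), 1L)
  expect_equal(extract_feature_seq(gm$genome, "solo") |> substr(1, 3), "ATG")

  f2 <- data.frame(Gene = c("A", "B"), Category = "PCG", Strand = "H",
                   Size = c(30L, 300L), Continuity = c(0L, -45L),
                   StartCodon = "ATG", StopCodon = "TAA")
  expect_error(genome_spec(features = f2), "infeasible overlap")

  f3 <- data.frame(Gene = "X", Category = "PCG", Strand = "H",
                   Size = 91L, Continuity = 0L,
                   StartCodon = "ATG", StopCodon = "TAA")
  expect_error(genome_spec(features = f3), "length mod 3")
})

test_that("generation is deterministic in the seed", {
  g1 <- generate_mitogenome(genome_spec(seed = 11))
  g2 <- generate_mitogenome(genome_spec(seed = 11))
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  g3 <- generate_mitogenome(genome_spec(seed = 12))
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("planted composition bias is recovered at large gene length", {
  # law of large numbers: a 30 kb gene's empirical composition approaches
  # the spec bias within 1%
  f <- data.frame(Gene = "big", Category = "rRNA", Strand = "H",
                  Size = 30000L, Continuity = 0L)
  bias <- c(A = 0.33, C = 0.25, G = 0.13, T = 0.29)
  gm <- generate_mitogenome(genome_spec(features = f, bias = bias, seed = 5))
  st <- composition_stats(gm$genome$sequence)
  emp <- c(A = st$a, C = st$c, G = st$g, T = st$t) / st$length
  expect_lt(max(abs(emp - bias)), 0.01)
})

test_that("truth codon counts equal the pipeline's counts over random specs", {
  for (seed in c(101, 202)) {
    gm <- generate_mitogenome(random_genome_spec(seed))
    cnt <- extract_codons(gm$genome)
    expect_identical(cnt[order(names(cnt))],
                     gm$truth_codons[order(names(gm$truth_codons))])
    # per-gene truth composition matches extraction
    for (i in seq_len(nrow(gm$truth_composition))) {
      r <- gm$truth_composition[i, ]
      cs <- composition_stats(extract_feature_seq(gm$genome, r$gene))
      expect_equal(c(cs$a, cs$c, cs$g, cs$t), c(r$a, r$c, r$g, r$t))
    }
  }
})

test_that("synthetic GenBank output re-read gives the identical mitogenome", {
  gm <- generate_mitogenome(genome_spec(seed = 21))
  tmp <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gm$genome, tmp)
  g2 <- read_genbank(tmp)
  expect_identical(g2$sequence, gm$genome$sequence)
  expect_identical(g2$features, gm$genome$features)
})
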