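test_that("p-distance with pairwise deletion matches hand counts", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance(strrep("A", 10), paste0("C", strrep("A", 9))), 0.1)
  # gap and ambiguity sites drop out of the comparison only for that pair
  expect_equal(p_distance("AC-GT", "ACAGA"), 0.25)
  expect_equal(p_distance("ACNGT", "ACAGT"), 0)
  expect_error(p_distance("---", "AAA"), "comparable")
  expect_error(p_distance("ACG", "ACGT"), "length")
})

test_that("JC69 distance equals the closed form to 1e-9 across p in [0, 0.7]", {
  for (p in seq(0, 0.70, by = 0.01)) {
    n <- 1000L
    k <- round(p * n)
    a <- strrep("A", n)
    b <- paste0(strrep("G", k), strrep("A", n - k))
    expect_equal(ml_distance(a, b, "JC69"), -3 / 4 * log(1 - 4 * (k / n) / 3),
                 tolerance = 1e-9)
  }
  expect_equal(ml_distance("ACGT", "ACGT", "JC69"), 0)
})

test_that("K2P closed form: transitions only at P = 0.1 gives 0.11157", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))  # A->G transitions
  expect_equal(ml_distance(a, b, "K2P"), -0.5 * log(0.8), tolerance = 1e-9)
  expect_equal(ml_distance(a, b, "K2P"), 0.11157, tolerance = 1e-4)
  expect_equal(ml_distance(a, a, "K2P"), 0)
  expect_equal(ml_distance(a, a, "TN93"), 0)
})

test_that("all three estimators agree with ape::dist.dna (pairwise deletion)", {
  set.seed(61)
  for (rep in 1:5) {
    a <- rand_dna(1500)
    b <- mutate_seq(a, runif(1, 0.02, 0.25))
    bin <- ape::as.DNAbin(strsplit(c(x = a, y = b), ""))
    ape_model <- c(JC69 = "JC69", K2P = "K80", TN93 = "TN93")
    for (mod in names(ape_model)) {
      ref <- as.numeric(ape::dist.dna(bin, model = ape_model[[mod]],
                                      pairwise.deletion = TRUE))
      expect_equal(ml_distance(a, b, mod), ref, tolerance = 1e-9)
    }
  }
})

test_that("saturation yields Inf with a warning, never an exception", {
  a <- strrep("ACGT", 25)
  b <- strrep("CATG", 25)  # p = 1, beyond every model's bound
  expect_warning(d <- ml_distance(a, b, "JC69"), "saturated")
  expect_identical(d, Inf)
})

test_that("multiple-hit correction is monotone: ml >= p on random pairs", {
  set.seed(62)
  for (rep in 1:25) {
    a <- rand_dna(800)
    b <- mutate_seq(a, runif(1, 0, 0.4))
    p <- p_distance(a, b)
    for (mod in c("JC69", "K2P", "TN93")) {
      d <- suppressWarnings(ml_distance(a, b, mod))
      expect_gte(d, p - 1e-12)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal and stamped metadata", {
  set.seed(63)
  base <- rand_dna(600)
  aln <- alignment(c(A = base, B = mutate_seq(base, 0.05),
                     C = mutate_seq(base, 0.15)))
  d <- dist_matrix(aln, "ML", "K2P")
  expect_true(isSymmetric(unname(d)))
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(attr(d, "model"), "K2P")
  expect_equal(attr(dist_matrix(aln, "p"), "method"), "p")
})

test_that("NJ recovers the generating topology of additive matrices (brute-force oracle)", {
  set.seed(64)
  for (rep in 1:8) {
    n_taxa <- sample(4:5, 1)
    taxa <- paste0("t", seq_len(n_taxa))
    # random topology + positive branch lengths -> additive distances
    gen <- all_unrooted_topologies(taxa)[[sample(
      length(all_unrooted_topologies(taxa)), 1)]]
    gen$edge.length <- runif(nrow(gen$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(gen)[taxa, taxa]
    njt <- nj_tree(d)
    expect_true(same_topology(njt, gen))
    # independent check: brute-force least-squares over all topologies
    expect_true(same_topology(best_topology_brute(d), gen))
    expect_true(all(njt$edge.length >= 0))
  }
})

test_that("3-taxon NJ gives the three-point branch lengths", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["B"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["C"]], (0.4 + 0.5 - 0.3) / 2)
  d2 <- d; d2[1, 2] <- 0.9
  expect_error(nj_tree(d2), "symmetric")
})

test_that("bootstrap: determinism, {0,100} at one replicate, strong-signal support", {
  set.seed(65)
  base <- rand_dna(800)
  clade2 <- mutate_seq(base, 0.35)
  aln <- alignment(c(A = base, B = mutate_seq(base, 0.02),
                     C = clade2, D = mutate_seq(clade2, 0.02)))
  t1 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  # the AB|CD split carries >= 95% support
  expect_gte(max(attr(t1, "support")), 95)
  expect_true(same_topology(t1, ape::read.tree(text = "((A,B),(C,D));")))
  s1 <- attr(bootstrap_support(aln, n_reps = 1, seed = 2), "support")
  expect_true(all(s1 %in% c(0, 100)))
})

test_that("alignment IO and the dual-triangle table writer", {
  set.seed(66)
  base <- rand_dna(300)
  seqs <- c(sp1 = base, sp2 = mutate_seq(base, 0.1), sp3 = mutate_seq(base, 0.2))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  aln <- read_alignment(fa)
  expect_equal(aln$taxa, names(seqs))
  dp <- dist_matrix(aln, "p")
  dm <- dist_matrix(aln, "ML", "TN93")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_dual_triangle_tsv(dm, dp, out)
  tab <- read.delim(out, check.names = FALSE)
  expect_equal(tab$Species, names(seqs))
  # below diagonal: p-distance in percent to one decimal
  expect_equal(as.numeric(tab[2, "sp1"]), round(100 * dp[2, 1], 1),
               tolerance = 0.051)
  expect_equal(tab[1, "sp1"], "-")
  expect_error(alignment(c(A = "ACG", B = "AC")), "length")
  expect_error(alignment(c(A = "ACG")), "2 taxa")
})
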