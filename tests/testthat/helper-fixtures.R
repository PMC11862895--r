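# Shared fixtures and small independent oracles, built in code.

table2_path <- function() {
  system.file("extdata", "bcaspica_mtgenome_features.tsv", package = "mitocall")
}

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# point mutations at per-site probability p
mutate_seq <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < p
  ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# a tiny sequence-bearing mitogenome with two hand-placed PCGs (one on
# each strand), one tRNA and a spacer; built base-by-base so every
# expected value is readable from the construction
toy_genome <- function() {
  set.seed(404)
  trna <- synth_trna("CAT", 68)
  pcg_h <- paste0("ATG", "AAACCTGGA", "TAA")            # 15 nt, H strand
  pcg_l_sense <- paste0("ATA", "GGATTTAAACCC", "TA")    # 17 nt, coding sense
  spacer <- "TTTT"
  seqs <- paste0(pcg_h, spacer, revcomp(pcg_l_sense), trna$seq)
  feats <- data.frame(
    name = c("PCGH", "PCGL", "tRNA-Met"),
    category = c("PCG", "PCG", "tRNA"),
    strand = c("H", "L", "H"),
    start = c(1L, 20L, 37L),
    end = c(15L, 36L, 36L + 68L),
    anticodon = c(NA, NA, "CAT"),
    stringsAsFactors = FALSE)
  list(genome = mitogenome(sequence = seqs, features = feats),
       pcg_h = pcg_h, pcg_l_sense = pcg_l_sense, trna = trna)
}

# enumerate all unrooted binary topologies on the given taxa by
# sequential insertion into every edge (3 taxa -> 1, 4 -> 3, 5 -> 15)
all_unrooted_topologies <- function(taxa) {
  trees <- list(ape::read.tree(
    text = sprintf("(%s,%s,%s);", taxa[1], taxa[2], taxa[3])))
  for (k in seq_along(taxa)[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        nxt[[length(nxt) + 1L]] <- phytools::bind.tip(
          tr, taxa[k], edge.length = 1, where = tr$edge[e, 2L], position = 0.5)
      }
    }
    trees <- nxt
  }
  trees
}

# least-squares additivity fit of a distance matrix on one topology:
# returns the residual sum of squares (0 for the generating topology of
# an exactly additive matrix)
topology_rss <- function(tr, d) {
  taxa <- rownames(d)
  tr <- ape::unroot(tr)
  ne <- nrow(tr$edge)
  pairs <- t(combn(taxa, 2))
  X <- matrix(0, nrow(pairs), ne)
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1], tr$tip.label)
    j <- match(pairs[r, 2], tr$tip.label)
    # edges on the i-j path via node paths to the root of the edge table
    path_to_base <- function(tip) {
      p <- integer(0); node <- tip
      repeat {
        e <- which(tr$edge[, 2] == node)
        if (!length(e)) break
        p <- c(p, e); node <- tr$edge[e, 1]
      }
      p
    }
    pi <- path_to_base(i); pj <- path_to_base(j)
    onpath <- union(setdiff(pi, pj), setdiff(pj, pi))
    X[r, onpath] <- 1
    y[r] <- d[pairs[r, 1], pairs[r, 2]]
  }
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# independent brute-force tree selection: topology with minimal
# additivity residual
best_topology_brute <- function(d) {
  taxa <- rownames(d)
  trees <- all_unrooted_topologies(taxa)
  rss <- vapply(trees, topology_rss, numeric(1), d = d)
  trees[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
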