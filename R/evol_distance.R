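# Pairwise evolutionary distances on aligned marker genes, distance
# matrices, neighbor-joining trees and bootstrap support.
#
# p-distances use pairwise deletion: a site with a gap or ambiguity in
# either sequence of the pair is excluded from that comparison only.
# Model-corrected ("ML") distances are the closed-form maximum-likelihood
# estimators: JC69  d = -3/4 ln(1 - 4p/3);
#             K2P   d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q);
#             TN93  the Tamura-Nei estimator with empirical base
#                   frequencies averaged over the pair.
# Saturated pairs (a logarithm argument <= 0) are reported as Inf, not an
# error.  The model name is stamped into every matrix and table written.

aln_pair_sites <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stop("sequences differ in aligned length")
  keep <- ca %in% DNA_BASES & cb %in% DNA_BASES
  list(a = ca[keep], b = cb[keep], n = sum(keep))
}

#' p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites (pairwise
#' deletion of gaps/ambiguities).
#'
#' @param a,b equal-length gapped DNA strings.
#' @return proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  s <- aln_pair_sites(a, b)
  if (s$n == 0L) stop("no comparable sites between the two sequences")
  sum(s$a != s$b) / s$n
}

#' Model-corrected pairwise distance
#'
#' @param a,b equal-length gapped DNA strings.
#' @param model `"JC69"`, `"K2P"` or `"TN93"` (default).
#' @return substitutions per site; `Inf` (with a warning) when the pair is
#'   saturated under the model.
#' @export
ml_distance <- function(a, b, model = c("TN93", "JC69", "K2P")) {
  model <- match.arg(model)
  s <- aln_pair_sites(a, b)
  if (s$n == 0L) stop("no comparable sites between the two sequences")
  n <- s$n
  slog <- function(x) {
    if (x <= 0) { warning("saturated pair under ", model); return(-Inf) }
    log(x)
  }
  if (model == "JC69") {
    p <- sum(s$a != s$b) / n
    return(-3 / 4 * slog(1 - 4 * p / 3))
  }
  # transition / transversion partition
  purine <- function(x) x %in% c("A", "G")
  diff <- s$a != s$b
  ts_ag <- diff & purine(s$a) & purine(s$b)
  ts_ct <- diff & !purine(s$a) & !purine(s$b)
  P1 <- sum(ts_ag) / n   # A<->G
  P2 <- sum(ts_ct) / n   # C<->T
  Q <- sum(diff & (purine(s$a) != purine(s$b))) / n
  if (model == "K2P") {
    P <- P1 + P2
    return(-1 / 2 * slog(1 - 2 * P - Q) - 1 / 4 * slog(1 - 2 * Q))
  }
  # TN93 with base frequencies averaged over the pair; terms whose
  # frequency class is absent from the data contribute nothing (their
  # substitution count is then necessarily zero)
  if (P1 + P2 + Q == 0) return(0)
  freq <- (table(factor(s$a, DNA_BASES)) + table(factor(s$b, DNA_BASES))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gT * gC / gY else 0
  k3 <- 2 * (gR * gY - (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gT * gC * gR / gY else 0))
  d <- 0
  if (k1 > 0) d <- d - k1 * slog(1 - P1 / k1 - Q / (2 * gR))
  if (k2 > 0) d <- d - k2 * slog(1 - P2 / k2 - Q / (2 * gY))
  if (k3 > 0 && gR > 0 && gY > 0) d <- d - k3 * slog(1 - Q / (2 * gR * gY))
  d
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all rows must have equal length.
#' @return list of class `alignment`: `taxa`, `seqs` (named character).
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  alignment(seqs)
}

#' Construct an alignment from named sequences
#'
#' @param seqs named character vector of equal-length gapped DNA strings.
#' @return list of class `alignment`.
#' @export
alignment <- function(seqs) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 taxa")
  if (length(unique(nchar(seqs))) != 1L) stop("aligned rows differ in length")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences need unique names")
  structure(list(taxa = names(seqs), seqs = toupper(seqs),
                 n_sites = nchar(seqs[[1L]])),
            class = "alignment")
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln an [alignment].
#' @param method `"p"` for p-distance or `"ML"` for a model-corrected
#'   distance.
#' @param model substitution model for `method = "ML"`.
#' @return symmetric matrix with zero diagonal; attributes `method` and
#'   `model` record what was computed.
#' @export
dist_matrix <- function(aln, method = c("p", "ML"),
                        model = c("TN93", "JC69", "K2P")) {
  method <- match.arg(method); model <- match.arg(model)
  n <- length(aln$taxa)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (method == "p")
        p_distance(aln$seqs[[i]], aln$seqs[[j]])
      else ml_distance(aln$seqs[[i]], aln$seqs[[j]], model)
    }
  }
  attr(d, "method") <- method
  attr(d, "model") <- if (method == "ML") model else NA_character_
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via ape), with negative
#' branch lengths clamped to zero and the deficit moved to the sister
#' branch so path lengths between tips are preserved.
#'
#' @param d symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix is not symmetric")
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  clamp_negative_edges(tr)
}

# set negative edge lengths to 0, adding the (negative) deficit to the
# sister edge sharing the same parent node
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
    if (all(tr$edge.length >= 0) || length(sibs) == 0L) {
      tr$edge.length[tr$edge.length < 0] <- 0
      break
    }
  }
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate under the same distance method, and reports per-split
#' support (percent of replicates containing the split) on the point
#' estimate tree as node labels.
#'
#' @param aln an [alignment].
#' @param method,model distance choice, as in [dist_matrix()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return the point-estimate `phylo` tree; internal `node.label` carry
#'   support percentages (root label empty), also in
#'   `attr(, "support")`.
#' @export
bootstrap_support <- function(aln, method = "p", model = "TN93",
                              n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  point <- nj_tree(dist_matrix(aln, method, model))
  set.seed(seed)
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$taxa
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    reps[[r]] <- nj_tree(dist_matrix(alignment(res), method, model))
  }
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps, 1)
  point$node.label <- as.character(support)
  point$node.label[1L] <- ""  # root of the unrooted display
  attr(point, "support") <- support
  point
}

#' Write a dual-triangle distance table
#'
#' The layout of published marker-gene distance tables: one method above
#' the diagonal, another below, with a two-gene variant (e.g. ND1 / Cytb
#' values packed as "x / y" per cell) supported by passing matrix pairs.
#'
#' @param upper,lower symmetric matrices over the same taxa (upper shown
#'   above the diagonal, lower below).  Each may be a list of two
#'   matrices for the two-gene "a / b" cell layout.
#' @param path output TSV path.
#' @param percent multiply values by 100 (distance tables are
#'   conventionally printed in %).
#' @param header_comment optional provenance lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_dual_triangle_tsv <- function(upper, lower, path, percent = TRUE,
                                    header_comment = NULL) {
  as_pair <- function(x) if (is.list(x)) x else list(x)
  up <- as_pair(upper); lo <- as_pair(lower)
  taxa <- rownames(up[[1L]])
  stopifnot(!is.null(taxa), all(vapply(c(up, lo), function(m)
    identical(rownames(m), taxa), logical(1))))
  fmt <- function(ms, i, j) {
    vals <- vapply(ms, function(m) m[i, j] * if (percent) 100 else 1, numeric(1))
    paste(sprintf("%.1f", vals), collapse = " / ")
  }
  n <- length(taxa)
  cells <- matrix("-", n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) cells[i, j] <- fmt(up, i, j)
    if (i > j) cells[i, j] <- fmt(lo, i, j)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(data.frame(Species = taxa, cells, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param d matrix from [dist_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "), con)
  invisible(path)
}
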