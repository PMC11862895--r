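# Codon counting and relative synonymous codon usage (RSCU) over the
# concatenated protein-coding genes, under the vertebrate mitochondrial
# genetic code (NCBI translation table 2): AGA/AGG are stops, ATA = Met,
# TGA = Trp.  Met (ATA/ATG) and Trp (TGA/TGG) therefore each form a
# two-codon synonymous family.
#
# RSCU(c) = count(c) * k / sum(family counts), k = family size; a family
# with zero observations gets RSCU 0 for all members.

# DNA codon -> amino acid under translation table 2, via Biostrings
mito_genetic_code <- function() {
  Biostrings::getGeneticCode("2")
}

#' Count codons over the protein-coding genes
#'
#' Each PCG is taken on coding sense (L-strand genes reverse-complemented),
#' split into consecutive triplets; a trailing incomplete codon (the
#' truncated-stop residue) is dropped.  Codons that are stops under the
#' vertebrate mitochondrial code (TAA/TAG/AGA/AGG) are excluded from the
#' counts, wherever they occur; start codons are counted as ordinary
#' codons.
#'
#' @param g a sequence-bearing [mitogenome] with PCG annotations.
#' @return named integer vector of counts over DNA codons (sense codons
#'   only; absent codons are present with count 0).
#' @export
extract_codons <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  if (is.na(g$sequence)) stop("sequence-bearing mitogenome required")
  pcgs <- g$features[g$features$category == "PCG", , drop = FALSE]
  if (!nrow(pcgs)) stop("mitogenome has no PCG features")
  code <- mito_genetic_code()
  sense <- names(code)[code != "*"]
  counts <- setNames(integer(length(sense)), sense)
  for (i in seq_len(nrow(pcgs))) {
    s <- extract_feature_seq(g, pcgs[i, , drop = FALSE])
    if (nchar(s) < 3L) stop("PCG '", pcgs$name[i], "' shorter than one codon")
    cod <- split_codons(s)
    cod <- cod[cod %in% sense]  # drop stops and any N-containing triplet
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Relative synonymous codon usage
#'
#' @param counts named integer vector of codon counts (DNA or RNA
#'   alphabet); every name must be a sense codon of the vertebrate
#'   mitochondrial code.  Missing sense codons are treated as count 0.
#' @return data frame of class `codon_usage_table` with columns `codon`
#'   (RNA alphabet), `aa` (one-letter), `count`, `family_size`, `rscu`,
#'   sorted by amino acid then codon.
#' @examples
#' rscu(c(GCA = 4L, GCC = 2L, GCG = 1L, GCT = 1L))  # 4-fold family
#' @export
rscu <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  code <- mito_genetic_code()
  dna_names <- chartr("U", "T", toupper(names(counts)))
  unknown <- setdiff(dna_names, names(code))
  if (length(unknown))
    stop("codon(s) not in the genetic code: ", paste(unknown, collapse = ", "))
  if (any(code[dna_names] == "*"))
    stop("stop codon(s) in counts: ",
         paste(dna_names[code[dna_names] == "*"], collapse = ", "))
  sense <- names(code)[code != "*"]
  full <- setNames(integer(length(sense)), sense)
  full[dna_names] <- full[dna_names] + as.integer(counts)
  aa <- code[sense]
  fam_total <- tapply(full, aa, sum)[aa]
  fam_size <- tapply(full, aa, length)[aa]
  rscu_val <- ifelse(fam_total == 0, 0, full * fam_size / fam_total)
  out <- data.frame(codon = chartr("T", "U", sense),
                    aa = unname(aa),
                    count = unname(full),
                    family_size = as.integer(unname(fam_size)),
                    rscu = unname(rscu_val),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Codon usage table of a mitogenome
#'
#' Convenience wrapper: [extract_codons()] then [rscu()].
#'
#' @param g a sequence-bearing [mitogenome] with PCG annotations.
#' @return a `codon_usage_table`.
#' @export
codon_usage <- function(g) {
  rscu(extract_codons(g))
}

#' @export
summary.codon_usage_table <- function(object, ...) {
  cat(sprintf("codon usage: %d codons counted; %d of %d sense codons with RSCU > 1\n",
              sum(object$count), sum(object$rscu > 1), nrow(object)))
  top <- object[order(-object$count), ][1:5, ]
  cat("  most frequent:",
      paste(sprintf("%s-%s (%d)", top$codon, top$aa, top$count), collapse = ", "),
      "\n")
  invisible(object)
}

#' Write a codon usage table as TSV
#'
#' @param tab a `codon_usage_table`.
#' @param path output path.
#' @param header_comment optional provenance lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_codon_tsv <- function(tab, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  out <- data.frame(Codon = tab$codon, AA = tab$aa, Count = tab$count,
                    RSCU = round(tab$rscu, 2), stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
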