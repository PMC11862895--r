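# Composition-and-organization table: the per-feature summary a mitogenome
# announcement prints — size, start/stop codon class, and "continuity", the
# signed nucleotide count separating consecutive features in coordinate
# order (negative = overlap, positive = intergenic spacer, 0 = abutting).

# stop codons of the vertebrate mitochondrial code (translation table 2)
MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Feature size in base pairs
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return `end - start + 1` (vectorized).
#' @examples
#' feature_size(11759, 13579)  # 1821
#' @export
feature_size <- function(start, end) {
  if (any(start > end)) stop("start > end")
  as.integer(end) - as.integer(start) + 1L
}

#' Continuity between consecutive features
#'
#' Signed count of nucleotides strictly between the previous feature's end
#' and this feature's start: `start - prev_end - 1`.  Zero means abutting,
#' negative values are overlaps, positive values intergenic spacers.
#' Computed in genome coordinate order regardless of strand, so L-strand
#' features participate in the same chain.
#'
#' @param prev_end end coordinate of the previous feature.
#' @param start start coordinate of this feature.
#' @return integer (vectorized).
#' @examples
#' continuity(7983, 7941)  # -43: ATP6 begins inside ATP8
#' @export
continuity <- function(prev_end, start) {
  as.integer(start) - as.integer(prev_end) - 1L
}

#' Classify start and stop codons of a coding sequence
#'
#' The CDS is taken 5'→3' on coding sense.  The start codon is the first
#' three nucleotides.  The stop class follows the length modulo 3:
#' remainder 0 means a complete terminal codon (which must belong to the
#' vertebrate mitochondrial stop set TAA/TAG/AGA/AGG, otherwise the row is
#' flagged); remainder 2 a truncated `"TA"`; remainder 1 a truncated `"T"`.
#' Truncated stops are completed to UAA by post-transcriptional
#' polyadenylation in vivo; they are reported as printed, not repaired.
#'
#' @param cds coding-sense DNA string, length >= 3.
#' @return list with `start_codon`, `stop_codon`, `stop_truncated`
#'   (logical) and `flagged` (TRUE when a complete terminal codon is not a
#'   recognized stop).
#' @export
classify_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  start_codon <- substring(cds, 1L, 3L)
  r <- n %% 3L
  if (r == 0L) {
    stop_codon <- substring(cds, n - 2L, n)
    flagged <- !(stop_codon %in% MITO_STOPS)
    truncated <- FALSE
  } else {
    stop_codon <- if (r == 2L) "TA" else "T"
    expected <- substring(cds, n - r + 1L, n)
    # a truncated stop must still be the residue of TAA
    flagged <- expected != stop_codon
    truncated <- TRUE
  }
  list(start_codon = start_codon, stop_codon = stop_codon,
       stop_truncated = truncated, flagged = flagged)
}

#' Build the composition-and-organization table
#'
#' One row per feature in coordinate order with size, start/stop codon
#' class (PCGs only, and only when the mitogenome carries a sequence) and
#' continuity.  The first row's continuity is `start - 1`, the offset from
#' position 1.  Aggregates (feature counts per category, summed PCG and
#' tRNA bp, genome length) are attached as attributes and printed by the
#' summary method.
#'
#' @param g a [mitogenome] (sequence optional).
#' @return a data frame of class `organization_table` with columns
#'   `gene`, `strand`, `start`, `end`, `size_bp`, `start_codon`,
#'   `stop_codon`, `anticodon`, `continuity`, `flagged`; aggregates in
#'   `attr(, "aggregates")`.
#' @export
build_table <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  f <- g$features
  n <- nrow(f)
  tab <- data.frame(gene = f$name, category = f$category, strand = f$strand,
                    start = f$start, end = f$end,
                    size_bp = if (n) feature_size(f$start, f$end) else integer(0),
                    start_codon = rep(NA_character_, n),
                    stop_codon = rep(NA_character_, n),
                    anticodon = f$anticodon,
                    continuity = rep(NA_integer_, n),
                    flagged = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n) {
    tab$continuity <- continuity(c(0L, f$end[-n]), f$start)
    if (!is.na(g$sequence)) {
      for (i in which(f$category == "PCG")) {
        cls <- classify_codons(extract_feature_seq(g, f[i, , drop = FALSE]))
        tab$start_codon[i] <- cls$start_codon
        tab$stop_codon[i] <- cls$stop_codon
        tab$flagged[i] <- cls$flagged
      }
    }
  }
  agg <- list(
    n_features = n,
    n_by_category = as.list(table(factor(tab$category, levels = FEATURE_CATEGORIES))),
    pcg_bp = sum(tab$size_bp[tab$category == "PCG"]),
    trna_bp = sum(tab$size_bp[tab$category == "tRNA"]),
    rrna_bp = sum(tab$size_bp[tab$category == "rRNA"]),
    genome_length = g$length_bp
  )
  structure(tab, aggregates = agg, class = c("organization_table", "data.frame"))
}

#' @export
summary.organization_table <- function(object, ...) {
  a <- attr(object, "aggregates")
  cat(sprintf("Organization table: %d features (%d PCG, %d tRNA, %d rRNA, %d control)\n",
              a$n_features, a$n_by_category$PCG, a$n_by_category$tRNA,
              a$n_by_category$rRNA, a$n_by_category$control))
  cat(sprintf("  PCG total %d bp | tRNA total %d bp | rRNA total %d bp | genome %s bp\n",
              a$pcg_bp, a$trna_bp, a$rrna_bp,
              format(a$genome_length, big.mark = ",")))
  invisible(a)
}

#' Write an organization table as TSV
#'
#' @param tab an `organization_table` from [build_table()].
#' @param path output path.
#' @param header_comment optional provenance lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_organization_tsv <- function(tab, path, header_comment = NULL) {
  out <- data.frame(Gene = tab$gene, Strand = tab$strand,
                    Location = sprintf("%d-%d", tab$start, tab$end),
                    `Size(bp)` = tab$size_bp,
                    StartCodon = ifelse(is.na(tab$start_codon), "-", tab$start_codon),
                    StopCodon = ifelse(is.na(tab$stop_codon), "-", tab$stop_codon),
                    Anticodon = ifelse(is.na(tab$anticodon), "-", tab$anticodon),
                    Continuity = tab$continuity,
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
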