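# Base composition, A+T / G+C / A+G content, and strand-asymmetry skews.
#
# AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C).  Contents are
# percentages of unambiguous bases: N and other ambiguity codes count
# toward length but never enter a denominator.  A skew whose denominator
# is zero is defined as 0.

#' Nucleotide composition and skew of a sequence
#'
#' @param seq non-empty DNA string (A/C/G/T plus ambiguity codes).
#' @return list of class `composition_stats`: integer counts `a`, `c`,
#'   `g`, `t`, `n_ambiguous`, `length`; percentages `at_content`,
#'   `gc_content`, `ag_content`; and `at_skew`, `gc_skew` in `[-1, 1]`.
#' @examples
#' composition_stats("AAT")$at_skew  # (2-1)/3
#' @export
composition_stats <- function(seq) {
  seq <- toupper(seq)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("composition_stats needs one non-empty sequence")
  ch <- seq_chars(seq)
  a <- sum(ch == "A"); c_ <- sum(ch == "C")
  g <- sum(ch == "G"); t <- sum(ch == "T")
  tot <- a + c_ + g + t
  if (tot == 0L) stop("sequence contains no unambiguous bases")
  skew <- function(x, y) if ((x + y) == 0L) 0 else (x - y) / (x + y)
  structure(list(
    a = a, c = c_, g = g, t = t,
    n_ambiguous = nchar(seq) - tot, length = nchar(seq),
    at_content = 100 * (a + t) / tot,
    gc_content = 100 * (g + c_) / tot,
    ag_content = 100 * (a + g) / tot,
    at_skew = skew(a, t),
    gc_skew = skew(g, c_)
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "composition: %d bp | A+T %.2f%% G+C %.2f%% A+G %.2f%% | AT skew %.4f GC skew %.4f\n",
    x$length, x$at_content, x$gc_content, x$ag_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Per-PCG composition summary
#'
#' Composition of the coding-sense sequence of each protein-coding gene,
#' plus a summary giving the minimum, maximum and mean A+T content.  Both
#' the unweighted mean of per-gene percentages and the length-weighted
#' value (composition of the concatenated PCGs) are reported, since
#' published "average PCG A+T content" figures rarely say which was used.
#'
#' @param g a sequence-bearing [mitogenome] with PCG annotations.
#' @return list with `per_gene` (data frame, one row per PCG),
#'   `mean_at` (unweighted), `concat` (composition of concatenated PCGs),
#'   `min_gene`, `max_gene`.
#' @export
pcg_composition_summary <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  if (is.na(g$sequence)) stop("sequence-bearing mitogenome required")
  pcgs <- g$features[g$features$category == "PCG", , drop = FALSE]
  if (!nrow(pcgs)) stop("mitogenome has no PCG features")
  seqs <- vapply(seq_len(nrow(pcgs)),
                 function(i) extract_feature_seq(g, pcgs[i, , drop = FALSE]),
                 character(1))
  stats <- lapply(seqs, composition_stats)
  per_gene <- data.frame(
    gene = pcgs$name,
    size_bp = nchar(seqs),
    at_content = vapply(stats, `[[`, numeric(1), "at_content"),
    gc_content = vapply(stats, `[[`, numeric(1), "gc_content"),
    ag_content = vapply(stats, `[[`, numeric(1), "ag_content"),
    at_skew = vapply(stats, `[[`, numeric(1), "at_skew"),
    gc_skew = vapply(stats, `[[`, numeric(1), "gc_skew"),
    stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       mean_at = mean(per_gene$at_content),
       concat = composition_stats(paste(seqs, collapse = "")),
       min_gene = per_gene$gene[which.min(per_gene$at_content)],
       max_gene = per_gene$gene[which.max(per_gene$at_content)])
}

#' Region-by-region composition table
#'
#' One row per region: whole genome, each feature, the concatenated PCGs,
#' and the pooled rRNA / tRNA / control classes.
#'
#' @param g a sequence-bearing [mitogenome].
#' @return data frame with columns `region`, `length`, `at_content`,
#'   `gc_content`, `ag_content`, `at_skew`, `gc_skew`.
#' @export
composition_table <- function(g) {
  stopifnot(inherits(g, "mitogenome"), !is.na(g$sequence))
  f <- g$features
  regions <- c(list(genome = g$sequence),
               setNames(lapply(seq_len(nrow(f)), function(i)
                 extract_feature_seq(g, f[i, , drop = FALSE])), f$name))
  for (cat_ in intersect(unique(f$category), FEATURE_CATEGORIES)) {
    idx <- which(f$category == cat_)
    pooled <- paste(vapply(idx, function(i)
      extract_feature_seq(g, f[i, , drop = FALSE]), character(1)),
      collapse = "")
    regions[[paste0("all_", cat_)]] <- pooled
  }
  rows <- lapply(names(regions), function(nm) {
    st <- composition_stats(regions[[nm]])
    data.frame(region = nm, length = st$length,
               at_content = round(st$at_content, 2),
               gc_content = round(st$gc_content, 2),
               ag_content = round(st$ag_content, 2),
               at_skew = round(st$at_skew, 4),
               gc_skew = round(st$gc_skew, 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
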