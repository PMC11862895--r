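# Reading, writing and validating annotated mitogenomes.
#
# The package-wide coordinate convention lives here: 1-based inclusive
# positions on the H (reference) strand; L-strand features are stored with
# H-strand coordinates and reverse-complemented on extraction.  Features
# that would wrap the circular origin are rejected (none occur in typical
# vertebrate mitogenome annotation tables, where the tRNA-Phe start defines
# position 1).

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control")

#' Construct an annotated mitogenome
#'
#' The central container consumed by every genomic stage.  A mitogenome is
#' a (possibly absent) nucleotide sequence plus an ordered feature table.
#' Sequence-free mitogenomes support all coordinate-only computations
#' (organization tables, continuity), which is how a published annotation
#' table can be analyzed without the deposited sequence.
#'
#' @param sequence single DNA string over A/C/G/T/N, or `NA` for a
#'   sequence-free (coordinate-only) mitogenome.
#' @param features data frame with columns `name`, `category` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`), `strand` (`"H"` or `"L"`),
#'   `start`, `end` (1-based inclusive) and optionally `anticodon`
#'   (3-nt string for tRNAs, `NA` otherwise).  Rows are re-sorted by start.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param length_bp genome length; required when `sequence` is absent and
#'   otherwise inferred from it.
#' @return an object of class `mitogenome`.
#' @export
mitogenome <- function(sequence = NA_character_, features = NULL,
                       topology = c("circular", "linear"),
                       length_bp = NULL) {
  topology <- match.arg(topology)
  has_seq <- !is.na(sequence)
  if (has_seq) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (nchar(sequence) == 0L) stop("mitogenome sequence must be non-empty")
    bad <- gsub("[ACGTN]", "", sequence)
    if (nchar(bad) > 0L)
      stop("sequence contains characters outside A/C/G/T/N: ",
           paste(unique(seq_chars(bad)), collapse = ""))
    length_bp <- nchar(sequence)
  } else if (is.null(length_bp)) {
    length_bp <- if (!is.null(features) && nrow(features)) max(features$end) else 0L
  }
  features <- validate_features(features, length_bp)
  structure(list(sequence = if (has_seq) sequence else NA_character_,
                 topology = topology,
                 length_bp = as.integer(length_bp),
                 features = features),
            class = "mitogenome")
}

validate_features <- function(features, length_bp) {
  if (is.null(features) || nrow(features) == 0L) {
    return(data.frame(name = character(0), category = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), anticodon = character(0),
                      stringsAsFactors = FALSE))
  }
  need <- c("name", "category", "strand", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  features <- features[, c(need, "anticodon")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end))
    stop("non-numeric feature coordinates")
  if (any(!features$category %in% FEATURE_CATEGORIES))
    stop("unknown feature category: ",
         paste(setdiff(features$category, FEATURE_CATEGORIES), collapse = ", "))
  if (any(!features$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'")
  if (any(features$start < 1L) || any(features$start > features$end))
    stop("feature with start < 1 or start > end (origin-wrapping features are not supported)")
  if (length_bp > 0L && any(features$end > length_bp))
    stop("feature end beyond genome length")
  if (anyDuplicated(features$name))
    stop("duplicate feature name(s): ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  is_trna <- features$category == "tRNA"
  ac <- features$anticodon
  ac[!is.na(ac) & ac %in% c("", "-")] <- NA_character_
  features$anticodon <- ac
  if (any(is_trna & !is.na(ac) & nchar(ac) != 3L))
    stop("tRNA anticodons must be 3 nt")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  features
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s, %s bp%s, %d features\n",
              x$topology, format(x$length_bp, big.mark = ","),
              if (is.na(x$sequence)) " (sequence-free)" else "",
              nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(factor(x$features$category, levels = FEATURE_CATEGORIES))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the coding-sense sequence of one feature
#'
#' Returns the inclusive substring `[start, end]`, reverse-complemented for
#' L-strand features so that the result reads 5'→3' on the coding sense.
#'
#' @param g a [mitogenome] carrying a sequence.
#' @param f a feature name, or a single-row slice of `g$features`.
#' @return a DNA string of length `end - start + 1`.
#' @export
extract_feature_seq <- function(g, f) {
  stopifnot(inherits(g, "mitogenome"))
  if (is.na(g$sequence))
    stop("cannot extract sequence from a sequence-free mitogenome")
  if (is.character(f)) {
    i <- match(f, g$features$name)
    if (is.na(i)) stop("no feature named '", f, "'")
    f <- g$features[i, , drop = FALSE]
  }
  s <- substring(g$sequence, f$start, f$end)
  if (f$strand == "L") s <- revcomp(s)
  s
}

# GenBank flat file ----------------------------------------------------------

#' Read a GenBank flat file into a mitogenome
#'
#' A minimal flat-file reader covering the record structure of organelle
#' genome submissions: the LOCUS line (length, topology), the FEATURES
#' table (`CDS`, `tRNA`, `rRNA`, `D-loop`/`misc_feature` keys with
#' `n..m` or `complement(n..m)` locations and `/gene`, `/product`,
#' `/anticodon` qualifiers) and the ORIGIN sequence block.  Joins and
#' origin-spanning locations are rejected.
#'
#' @param path path to a GenBank flat file.
#' @return a [mitogenome].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("GenBank record has no ORIGIN block: ", path)
  origin_at <- origin_at[1L]

  topology <- "circular"
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) && grepl("\\blinear\\b", locus[1L])) topology <- "linear"

  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("ORIGIN block contains no sequence: ", path)

  feat_at <- grep("^FEATURES", lines)
  features <- NULL
  if (length(feat_at)) {
    block <- lines[(feat_at[1L] + 1L):(origin_at - 1L)]
    features <- parse_genbank_features(block)
  }
  mitogenome(sequence = sequence, features = features, topology = topology)
}

parse_genbank_features <- function(block) {
  # feature lines have the key in columns 6-20; continuation/qualifier
  # lines are indented past column 21
  key_idx <- grep("^ {5}\\S", block)
  if (!length(key_idx)) return(NULL)
  ends <- c(key_idx[-1L] - 1L, length(block))
  rows <- list()
  for (j in seq_along(key_idx)) {
    ln <- block[key_idx[j]]
    key <- sub("^ {5}(\\S+).*", "\\1", ln)
    loc <- sub("^ {5}\\S+\\s+", "", ln)
    chunk <- block[key_idx[j]:ends[j]]
    category <- switch(key,
                       CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       `D-loop` = "control",
                       NA_character_)
    if (key == "misc_feature" &&
        any(grepl("D-loop|control region", chunk, ignore.case = TRUE)))
      category <- "control"
    if (is.na(category)) next
    if (grepl("join|order", loc))
      stop("GenBank location '", trimws(loc), "' (line ", key_idx[j],
           " of FEATURES): joined/origin-spanning features are not supported")
    strand <- if (grepl("^complement", loc)) "L" else "H"
    m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1L]]
    if (length(m) != 3L)
      stop("malformed GenBank location '", trimws(loc), "' at FEATURES line ",
           key_idx[j])
    name <- gb_qualifier(chunk, "gene") %||% gb_qualifier(chunk, "product") %||%
      if (category == "control") "D-loop" else NA_character_
    if (is.na(name)) next
    anticodon <- NA_character_
    if (category == "tRNA") {
      ac <- gb_qualifier(chunk, "anticodon")
      if (!is.na(ac)) {
        acm <- regmatches(ac, regexec("seq\\s*:\\s*([A-Za-z]{3})", ac))[[1L]]
        anticodon <- if (length(acm) == 2L) toupper(acm[2L]) else toupper(ac)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, category = category, strand = strand,
      start = as.integer(m[2L]), end = as.integer(m[3L]),
      anticodon = anticodon, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  feats <- do.call(rbind, rows)
  # CDS + gene records describe the same interval twice; keep one per name
  feats[!duplicated(feats[c("name", "start", "end")]), , drop = FALSE]
}

gb_qualifier <- function(chunk, what) {
  pat <- paste0("^\\s+/", what, "=")
  hit <- grep(pat, chunk, value = TRUE)
  if (!length(hit)) return(NA_character_)
  val <- sub(pat, "", hit[1L])
  gsub('"', "", trimws(val))
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a minimal record (LOCUS, FEATURES, ORIGIN) that [read_genbank()]
#' reads back identically; the round trip is the identity on sequence and
#' features.
#'
#' @param g a sequence-bearing [mitogenome].
#' @param path output path.
#' @param accession accession string for the LOCUS/ACCESSION lines.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path, accession = "SYNTHETIC") {
  stopifnot(inherits(g, "mitogenome"))
  if (is.na(g$sequence)) stop("cannot write a sequence-free mitogenome to GenBank")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2000",
     accession, g$length_bp, g$topology)
  wl("DEFINITION  synthetic mitochondrial genome.")
  wl("ACCESSION   %s", accession)
  wl("FEATURES             Location/Qualifiers")
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "D-loop")
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "L") loc <- sprintf("complement(%s)", loc)
    wl("     %-16s%s", key_of[[f$category]], loc)
    wl("                     /gene=\"%s\"", f$name)
    if (f$category == "tRNA" && !is.na(f$anticodon))
      wl("                     /anticodon=\"(pos:0..0,aa:Xxx,seq:%s)\"",
         tolower(f$anticodon))
  }
  wl("ORIGIN")
  s <- g$sequence
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substring(s, off, min(off + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L, nchar(chunk)))
    wl("%9d %s", off, tolower(paste(groups, collapse = " ")))
  }
  wl("//")
  invisible(path)
}

# Feature TSV ----------------------------------------------------------------

#' Read an annotation table (feature TSV) into a mitogenome
#'
#' The TSV schema mirrors a published mitogenome organization table:
#' required columns `Gene`, `Strand`, `Start`, `End`, `Category`, and
#' optional `Anticodon` (plus any extra columns, which are ignored).  This
#' lets a printed table be used directly as input without the sequence.
#'
#' @param path path to a UTF-8, tab-delimited file with a header row.
#' @param sequence optional DNA string to attach.
#' @return a [mitogenome]; sequence-free unless `sequence` is given.
#' @export
read_feature_tsv <- function(path, sequence = NA_character_) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
  need <- c("Gene", "Strand", "Start", "End", "Category")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("feature TSV lacks columns: ", paste(miss, collapse = ", "))
  st <- suppressWarnings(as.integer(tab$Start))
  en <- suppressWarnings(as.integer(tab$End))
  if (anyNA(st) || anyNA(en))
    stop("non-numeric coordinates in feature TSV rows: ",
         paste(which(is.na(st) | is.na(en)), collapse = ", "))
  features <- data.frame(name = as.character(tab$Gene),
                         category = as.character(tab$Category),
                         strand = as.character(tab$Strand),
                         start = st, end = en,
                         anticodon = if ("Anticodon" %in% names(tab))
                           as.character(tab$Anticodon) else NA_character_,
                         stringsAsFactors = FALSE)
  mitogenome(sequence = sequence, features = features)
}

#' Write a mitogenome's feature table as TSV
#'
#' @param g a [mitogenome].
#' @param path output path.
#' @param header_comment optional `# `-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(g, path, header_comment = NULL) {
  stopifnot(inherits(g, "mitogenome"))
  f <- g$features
  out <- data.frame(Gene = f$name, Strand = f$strand, Start = f$start,
                    End = f$end, Category = f$category,
                    Anticodon = ifelse(is.na(f$anticodon), "-", f$anticodon),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings for single-sequence genome FASTA files.
#'
#' @param path FASTA path.
#' @return `read_fasta_genome`: a sequence-only [mitogenome].
#' @export
read_fasta_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected exactly one sequence in ", path)
  mitogenome(sequence = as.character(ss[[1L]]))
}

#' @rdname read_fasta_genome
#' @param g a sequence-bearing [mitogenome].
#' @param name FASTA header.
#' @export
write_fasta_genome <- function(g, path, name = "mitogenome") {
  stopifnot(inherits(g, "mitogenome"), !is.na(g$sequence))
  ss <- Biostrings::DNAStringSet(setNames(g$sequence, name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
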