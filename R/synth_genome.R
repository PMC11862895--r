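# Seeded generation of annotated synthetic mitogenomes with known ground
# truth.  The generator lays features out left to right at the coordinates
# the spec demands (so planted overlaps and truncated stops reproduce a
# published organization table exactly), pins every PCG's start and stop
# codon into the sequence first, writes tRNAs as arm-by-arm cloverleafs,
# fills remaining positions from a base-composition bias, and finally
# repairs any in-frame stop codon in any PCG reading frame.  Overlap
# regions keep the earlier-starting gene's sequence; the later gene adapts
# (stem partners re-complemented, bodies repaired) or the spec is rejected
# as infeasible.

# mammal mitochondrial H-strand-like default bias (A-rich, G-poor)
DEFAULT_BIAS <- c(A = 0.33, C = 0.25, G = 0.13, T = 0.29)

#' Specify a synthetic mitogenome
#'
#' A genome spec is a feature layout (name/category/strand plus either
#' explicit `Start`/`End` coordinates or `Size` + `Continuity` targets,
#' from which coordinates are derived left to right), per-PCG start/stop
#' codon choices (including truncated `"TA"`/`"T"` stops), per-tRNA
#' anticodons, and a base-composition bias.  The default layout is the
#' 37-feature organization of the *Barbastella caspica*-style vertebrate
#' mitogenome shipped with the package, so the generated genome reproduces
#' that table's sizes, overlaps and codon classes field for field.
#'
#' @param features data frame with columns `Gene`, `Category`, `Strand`,
#'   and either `Start` + `End` or `Size` + `Continuity`; optional
#'   `Anticodon`, `StartCodon`, `StopCodon`.  `NULL` selects the packaged
#'   default layout.
#' @param bias named base probabilities (A/C/G/T), the target composition
#'   of unconstrained positions.
#' @param seed integer seed; the whole generation is deterministic in it.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(features = NULL, bias = DEFAULT_BIAS, seed = 1L) {
  if (is.null(features)) {
    path <- system.file("extdata", "bcaspica_mtgenome_features.tsv",
                        package = "mitocall")
    features <- read.delim(path, stringsAsFactors = FALSE)
  }
  f <- features
  norm <- function(x) ifelse(is.na(x) | x %in% c("", "-"), NA_character_, x)
  if (!"Anticodon" %in% names(f)) f$Anticodon <- NA_character_
  if (!"StartCodon" %in% names(f)) f$StartCodon <- NA_character_
  if (!"StopCodon" %in% names(f)) f$StopCodon <- NA_character_
  f$Anticodon <- norm(toupper(as.character(f$Anticodon)))
  f$StartCodon <- norm(toupper(as.character(f$StartCodon)))
  f$StopCodon <- norm(toupper(as.character(f$StopCodon)))

  if (!all(c("Start", "End") %in% names(f))) {
    if (!all(c("Size", "Continuity") %in% names(f)))
      stop("features need either Start/End or Size/Continuity columns")
    start <- integer(nrow(f)); end <- integer(nrow(f))
    prev_end <- 0L
    for (i in seq_len(nrow(f))) {
      start[i] <- prev_end + as.integer(f$Continuity[i]) + 1L
      end[i] <- start[i] + as.integer(f$Size[i]) - 1L
      prev_end <- end[i]
    }
    f$Start <- start; f$End <- end
  }
  f$Start <- as.integer(f$Start); f$End <- as.integer(f$End)
  f <- f[order(f$Start, f$End), , drop = FALSE]
  rownames(f) <- NULL

  sizes <- f$End - f$Start + 1L
  if (any(sizes < 1L)) stop("feature with non-positive size")
  n <- nrow(f)
  if (n > 1L) {
    ov <- f$End[-n] - f$Start[-1L] + 1L  # positive = overlap
    bad <- which(ov > 0L & (ov >= sizes[-n] | ov >= sizes[-1L]))
    if (length(bad))
      stop("infeasible overlap at ", f$Gene[bad[1L] + 1L],
           ": overlap spans a whole gene")
  }
  is_pcg <- f$Category == "PCG"
  if (any(is_pcg & (is.na(f$StartCodon) | is.na(f$StopCodon))))
    stop("every PCG needs StartCodon and StopCodon")
  r <- sizes %% 3L
  want <- ifelse(r == 0L, 3L, r)
  badstop <- which(is_pcg & nchar(f$StopCodon) != want)
  if (length(badstop))
    stop("stop codon of ", f$Gene[badstop[1L]],
         " inconsistent with its length mod 3")
  if (any(is_pcg & nchar(f$StartCodon) != 3L))
    stop("start codons must be 3 nt")
  cstop <- which(is_pcg & nchar(f$StopCodon) == 3L & !f$StopCodon %in% MITO_STOPS)
  if (length(cstop))
    stop("complete stop codon of ", f$Gene[cstop[1L]],
         " is not in the vertebrate-mito stop set")
  if (any(f$Category == "tRNA" & is.na(f$Anticodon)))
    stop("every tRNA needs an anticodon")

  bias <- bias[DNA_BASES]
  if (anyNA(bias) || any(bias < 0) || abs(sum(bias) - 1) > 1e-8)
    stop("bias must be probabilities over A/C/G/T summing to 1")
  structure(list(features = f, bias = bias, seed = as.integer(seed)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d features, %d bp, seed %d\n",
              nrow(x$features), max(x$features$End), x$seed))
  invisible(x)
}

comp1 <- function(b) chartr("ACGT", "TGCA", b)

#' Generate a synthetic mitogenome with ground truth
#'
#' @param spec a [genome_spec].
#' @param tail_bp extra unannotated sequence appended after the last
#'   feature (0 by default; the default layout ends in the control
#'   region, so none is needed).
#' @return list of class `synthetic_mitogenome`:
#'   \describe{
#'     \item{genome}{a sequence-bearing [mitogenome];}
#'     \item{truth_organization}{per-feature size / codon class /
#'       continuity as constructed (the oracle for [build_table()]);}
#'     \item{truth_composition}{per-feature base counts tallied from the
#'       planted gene strings;}
#'     \item{truth_codons}{codon counts over PCG bodies as planted
#'       (stops excluded, trailing residues dropped);}
#'     \item{truth_trna}{per-tRNA planted layout (stem lengths,
#'       canonical flag).}
#'   }
#' @export
generate_mitogenome <- function(spec, tail_bp = 0L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  f <- spec$features
  n <- nrow(f)
  L <- max(f$End) + as.integer(tail_bp)
  seqv <- rep(NA_character_, L)
  pinned <- rep(FALSE, L)   # immutable: codon pins
  locked <- rep(FALSE, L)   # immutable for repair: pins + tRNA spans

  gpos <- function(i, k) if (f$Strand[i] == "H") f$Start[i] + k - 1L else f$End[i] - k + 1L
  put <- function(i, k, base) {            # write gene-sense base k of feature i
    gp <- gpos(i, k)
    gb <- if (f$Strand[i] == "H") base else comp1(base)
    if (!is.na(seqv[gp]) && seqv[gp] != gb)
      stop("pin conflict at position ", gp, " (", f$Gene[i], ")")
    seqv[gp] <<- gb
  }
  get_gene_base <- function(i, k) {
    gb <- seqv[gpos(i, k)]
    if (is.na(gb)) NA_character_ else if (f$Strand[i] == "H") gb else comp1(gb)
  }
  sizes <- f$End - f$Start + 1L

  # 1. pin start/stop codons of every PCG ------------------------------------
  for (i in which(f$Category == "PCG")) {
    sc <- seq_chars(f$StartCodon[i])
    for (k in 1:3) { put(i, k, sc[k]); pinned[gpos(i, k)] <- TRUE }
    st <- seq_chars(f$StopCodon[i])
    for (j in seq_along(st)) {
      k <- sizes[i] - length(st) + j
      put(i, k, st[j]); pinned[gpos(i, k)] <- TRUE
    }
  }
  locked <- pinned

  # 2. write features in start order ------------------------------------------
  draw <- function(m) sample(DNA_BASES, m, replace = TRUE, prob = spec$bias)
  trna_truth <- list()
  for (i in seq_len(n)) {
    cat_ <- f$Category[i]
    if (cat_ == "tRNA") {
      trna_truth[[f$Gene[i]]] <- write_trna(i, f, sizes, seqv, locked,
                                            get_gene_base, put, gpos)
      locked[f$Start[i]:f$End[i]] <- TRUE
    } else if (cat_ == "PCG") {
      # body: codon-wise fill of fully-free codons, avoiding stops;
      # partially fixed codons are left to the repair pass
      K <- sizes[i] %/% 3L - (sizes[i] %% 3L == 0L)
      for (cc in if (K >= 2L) 2:K else integer(0)) {
        ks <- (3L * cc - 2L):(3L * cc)
        if (all(vapply(ks, function(k) is.na(seqv[gpos(i, k)]), logical(1)))) {
          repeat {
            cod <- draw(3L)
            if (!paste(cod, collapse = "") %in% MITO_STOPS) break
          }
          for (j in 1:3) put(i, ks[j], cod[j])
        }
      }
      # any stray free base (shouldn't occur for in-frame bodies)
      for (k in seq_len(sizes[i]))
        if (is.na(seqv[gpos(i, k)])) put(i, k, draw(1L))
    } else {  # rRNA / control: unconstrained fill
      span <- f$Start[i]:f$End[i]
      free <- span[is.na(seqv[span])]
      if (length(free)) seqv[free] <- draw(length(free))
    }
  }
  free <- which(is.na(seqv))
  if (length(free)) seqv[free] <- draw(length(free))  # spacers / tail

  # 3. repair in-frame stops across all PCG frames ----------------------------
  seqv <- repair_frames(seqv, f, sizes, locked, gpos)

  sequence <- paste(seqv, collapse = "")
  genome <- mitogenome(sequence = sequence,
                       features = data.frame(name = f$Gene,
                                             category = f$Category,
                                             strand = f$Strand,
                                             start = f$Start, end = f$End,
                                             anticodon = f$Anticodon,
                                             stringsAsFactors = FALSE))

  # ground truth, tallied directly from the construction ---------------------
  gene_str <- function(i) {
    s <- paste(vapply(seq_len(sizes[i]),
                      function(k) seqv[gpos(i, k)], character(1)), collapse = "")
    if (f$Strand[i] == "H") s else chartr("ACGT", "TGCA", s)
  }
  truth_org <- data.frame(
    gene = f$Gene, category = f$Category, strand = f$Strand,
    start = f$Start, end = f$End, size_bp = sizes,
    start_codon = f$StartCodon, stop_codon = f$StopCodon,
    anticodon = f$Anticodon,
    continuity = c(f$Start[1L] - 1L,
                   if (n > 1L) f$Start[-1L] - f$End[-n] - 1L),
    stringsAsFactors = FALSE)

  comp_rows <- lapply(seq_len(n), function(i) {
    ch <- seq_chars(gene_str(i))
    data.frame(gene = f$Gene[i],
               a = sum(ch == "A"), c = sum(ch == "C"),
               g = sum(ch == "G"), t = sum(ch == "T"),
               stringsAsFactors = FALSE)
  })
  truth_comp <- do.call(rbind, comp_rows)

  code <- mito_genetic_code()
  sense <- names(code)[code != "*"]
  truth_codons <- setNames(integer(length(sense)), sense)
  for (i in which(f$Category == "PCG")) {
    s <- gene_str(i)
    cods <- substring(s, seq(1L, 3L * (nchar(s) %/% 3L), by = 3L),
                      seq(3L, 3L * (nchar(s) %/% 3L), by = 3L))
    cods <- cods[!cods %in% MITO_STOPS]
    tb <- table(cods)
    truth_codons[names(tb)] <- truth_codons[names(tb)] + as.integer(tb)
  }

  truth_trna <- if (length(trna_truth)) do.call(rbind, lapply(names(trna_truth),
    function(nm) {
      tt <- trna_truth[[nm]]
      data.frame(name = nm, length = tt$length, canonical = tt$canonical,
                 d_stem = tt$d_stem, ac_stem = tt$ac_stem, t_stem = tt$t_stem,
                 stringsAsFactors = FALSE)
    })) else NULL

  structure(list(genome = genome, spec = spec,
                 truth_organization = truth_org,
                 truth_composition = truth_comp,
                 truth_codons = truth_codons,
                 truth_trna = truth_trna),
            class = "synthetic_mitogenome")
}

#' @export
print.synthetic_mitogenome <- function(x, ...) {
  cat("synthetic mitogenome (seed ", x$spec$seed, ")\n", sep = "")
  print(x$genome)
  invisible(x)
}

# write one tRNA feature, adapting the planted cloverleaf to bases already
# fixed by earlier features or codon pins
write_trna <- function(i, f, sizes, seqv_ignored, locked_ignored,
                       get_gene_base, put, gpos) {
  len <- sizes[i]
  for (try in 1:25) {
    st <- synth_trna(f$Anticodon[i], len)
    planted <- seq_chars(st$seq)
    partner <- trna_partner_map(st$truth, len)
    fixed <- which(!vapply(seq_len(len),
                           function(k) is.na(get_gene_base(i, k)), logical(1)))
    mism_acceptor <- 0L
    ok <- TRUE
    for (k in fixed) {
      fb <- get_gene_base(i, k)
      if (planted[k] == fb) next
      # the anticodon itself cannot be rewritten
      a0 <- st$truth$anticodon_start
      if (k >= a0 && k <= a0 + 2L) { ok <- FALSE; break }
      planted[k] <- fb
      j <- partner[k]
      if (!is.na(j)) {
        if (j %in% fixed) {
          if (!can_pair(planted[k], get_gene_base(i, j))) {
            if (k <= 7L || j <= 7L) mism_acceptor <- mism_acceptor + 1L
            else { ok <- FALSE; break }
          }
        } else planted[j] <- comp1(fb)
      }
    }
    if (!ok || mism_acceptor > 1L) next
    # the adapted sequence must still fold to the planted layout
    cl <- try(fold_cloverleaf(paste(planted, collapse = ""), f$Anticodon[i]),
              silent = TRUE)
    if (inherits(cl, "try-error") || !cl$is_canonical) next
    for (k in seq_len(len)) if (!k %in% fixed) put(i, k, planted[k])
    return(st$truth)
  }
  stop("could not place tRNA ", f$Gene[i], " under its overlap constraints")
}

# gene-position -> paired partner (NA when unpaired) for a planted layout
trna_partner_map <- function(truth, len) {
  partner <- rep(NA_integer_, len)
  link <- function(i, j) { partner[i] <<- j; partner[j] <<- i }
  for (k in 1:7) link(k, len - k)                 # acceptor (discriminator at len)
  if (!is.na(truth$d_stem)) {
    s <- truth$d_stem; d0 <- truth$d_start
    dl <- (truth$anticodon_start - 2L - truth$ac_stem - 1L - 1L) - (d0 + 2L * s) + 1L
    for (k in seq_len(s)) link(d0 + k - 1L, d0 + 2L * s + dl - k)
  }
  ss <- truth$anticodon_start - 2L - truth$ac_stem
  for (k in seq_len(truth$ac_stem))
    link(ss + k - 1L, ss + 2L * truth$ac_stem + 7L - k)
  ts <- truth$t_start; s <- truth$t_stem
  tl_end <- len - 8L   # last position before the acceptor 3' half
  tloop <- (tl_end - ts + 1L) - 2L * s
  for (k in seq_len(s)) link(ts + k - 1L, ts + 2L * s + tloop - k)
  partner
}

# eliminate stop codons from every PCG body frame; pinned / tRNA-locked
# positions are immutable, everything else may be resampled
repair_frames <- function(seqv, f, sizes, locked, gpos) {
  pcgs <- which(f$Category == "PCG")
  body_rng <- function(i) {
    K <- sizes[i] %/% 3L - (sizes[i] %% 3L == 0L)
    if (K < 2L) integer(0) else 2:K
  }
  codon_str <- function(i, cc) {
    ks <- (3L * cc - 2L):(3L * cc)
    b <- vapply(ks, function(k) seqv[gpos(i, k)], character(1))
    if (f$Strand[i] == "L") b <- comp1(b)
    paste(b, collapse = "")
  }
  codon_ok_at <- function(gp) {
    # every PCG body codon covering genome position gp must be non-stop
    for (q in pcgs) {
      if (gp < f$Start[q] || gp > f$End[q]) next
      k <- if (f$Strand[q] == "H") gp - f$Start[q] + 1L else f$End[q] - gp + 1L
      cc <- (k + 2L) %/% 3L
      if (cc %in% body_rng(q) && codon_str(q, cc) %in% MITO_STOPS) return(FALSE)
    }
    TRUE
  }
  for (iter in 1:400) {
    dirty <- FALSE
    for (i in pcgs) {
      for (cc in body_rng(i)) {
        if (!codon_str(i, cc) %in% MITO_STOPS) next
        dirty <- TRUE
        ks <- (3L * cc - 2L):(3L * cc)
        gps <- vapply(ks, function(k) gpos(i, k), integer(1))
        free <- which(!locked[gps])
        if (!length(free))
          stop("infeasible spec: fully pinned stop codon in ", f$Gene[i],
               " at codon ", cc)
        combos <- expand.grid(rep(list(DNA_BASES), length(free)),
                              stringsAsFactors = FALSE)
        combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
        fixed <- FALSE
        for (r in seq_len(nrow(combos))) {
          old <- seqv[gps[free]]
          seqv[gps[free]] <- unlist(combos[r, ], use.names = FALSE)
          if (!codon_str(i, cc) %in% MITO_STOPS &&
              all(vapply(gps[free], codon_ok_at, logical(1)))) {
            fixed <- TRUE; break
          }
          seqv[gps[free]] <- old
        }
        if (!fixed)
          stop("infeasible spec: cannot clear stop codon in ", f$Gene[i],
               " at codon ", cc)
      }
    }
    if (!dirty) return(seqv)
  }
  stop("stop-codon repair did not converge")
}

#' Random small genome specs for property testing
#'
#' Draws a feature layout with a seeded mix of PCGs (truncated and
#' complete stops, one PCG-PCG overlap pair when two PCGs are adjacent),
#' tRNAs on both strands, an rRNA and a control region, with random
#' spacer sizes.  Overlap sizes are restricted to constructible
#' configurations: an overlap of 1 shares the previous gene's complete
#' TAA stop's final base with the next gene's start-codon `A`; larger
#' overlaps avoid multiples of 3 so a pinned stop codon never lands
#' frame-aligned (hence unrepairable) in the other gene's reading frame.
#'
#' @param seed integer seed.
#' @param n_pcg,n_trna feature counts.
#' @return a [genome_spec].
#' @export
random_genome_spec <- function(seed, n_pcg = 4L, n_trna = 5L) {
  set.seed(seed)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...,
    stringsAsFactors = FALSE)
  anticodons <- c("GAA", "TAC", "CAT", "TGA", "GTT", "TCG", "GTG", "TTC")
  add(Gene = "rRNA-S", Category = "rRNA", Strand = "H",
      Size = sample(300:800, 1), Continuity = sample(0:5, 1),
      Anticodon = NA, StartCodon = NA, StopCodon = NA)
  prev_cat <- "rRNA"; prev_stop <- NA_character_
  pcg_i <- 0L; trna_i <- 0L; overlap_done <- FALSE
  for (j in seq_len(n_pcg + n_trna)) {
    make_pcg <- (j %% 2L == 0L && pcg_i < n_pcg) || trna_i >= n_trna
    if (make_pcg && pcg_i < n_pcg) {
      pcg_i <- pcg_i + 1L
      stop_kind <- sample(c("TAA", "TAG", "TA", "T"), 1)
      ncod <- sample(60:220, 1)
      size <- 3L * ncod + c(TAA = 0L, TAG = 0L, TA = 2L, T = 1L)[[stop_kind]]
      cont <- sample(0:20, 1)
      if (!overlap_done && prev_cat == "PCG") {
        # o = 1 shares a TAA stop's A with the next start codon; o in
        # {7, 10, 13} keeps the previous stop off-frame in this gene
        # (o = 2 mod 3 would pin a frame-aligned stop, unrepairable)
        o <- sample(c(if (identical(prev_stop, "TAA")) 1L, 7L, 10L, 13L), 1)
        cont <- -o
        overlap_done <- TRUE
      }
      add(Gene = sprintf("PCG%d", pcg_i), Category = "PCG", Strand = "H",
          Size = size, Continuity = cont, Anticodon = NA,
          StartCodon = sample(c("ATG", "ATA"), 1), StopCodon = stop_kind)
      prev_cat <- "PCG"; prev_stop <- stop_kind
    } else if (trna_i < n_trna) {
      trna_i <- trna_i + 1L
      add(Gene = sprintf("tRNA-%d", trna_i), Category = "tRNA",
          Strand = sample(c("H", "L"), 1),
          Size = sample(59:75, 1), Continuity = sample(0:15, 1),
          Anticodon = anticodons[trna_i %% length(anticodons) + 1L],
          StartCodon = NA, StopCodon = NA)
      prev_cat <- "tRNA"; prev_stop <- NA_character_
    }
  }
  add(Gene = "CTRL", Category = "control", Strand = "H",
      Size = sample(200:600, 1), Continuity = sample(0:10, 1),
      Anticodon = NA, StartCodon = NA, StopCodon = NA)
  genome_spec(features = do.call(rbind, rows), seed = seed)
}
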