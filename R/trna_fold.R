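# Cloverleaf secondary-structure assignment for mitochondrial tRNAs.
#
# Rather than free-energy minimization, the fold is a deterministic
# constrained template search: the anticodon loop is anchored at an
# occurrence of the annotated anticodon, stems are extended greedily, and
# the D- and T-arms are searched in their flanks.  Mito-tRNAs are
# degenerate (mt tRNA-Ser(AGY) lacks the D-arm entirely), so arms that are
# searched but not found are reported absent and the structure flagged
# non-canonical, never an error.
#
# Allowed pairs: Watson-Crick plus G:T wobble (G:U in the RNA).

PAIR_SET <- c("AT", "TA", "GC", "CG", "GT", "TG")

can_pair <- function(x, y) paste0(x, y) %in% PAIR_SET

#' Fold one tRNA sequence into a cloverleaf
#'
#' Anchors the 7-nt anticodon loop at an occurrence of `anticodon` (loop
#' positions 3-5), greedily extends the anticodon stem (target 5 bp, at
#' least 4 required), pairs the 5' and 3' termini into the acceptor stem
#' (7 bp, at least 6 matching, at most 1 mismatch, with or without a 3'
#' discriminator base), then searches the 5' flank for a D-arm (stem
#' 3-4 bp, loop 4-12 nt) and the 3' flank for a T-arm (stem 4-5 bp, loop
#' 4-9 nt).  If the anticodon occurs more than once, the occurrence
#' yielding the most paired bases wins; ties go to the 5'-most.
#'
#' @param seq tRNA gene sequence, coding sense, DNA alphabet, 55-95 nt.
#' @param anticodon 3-nt DNA string as annotated (e.g. `"GAA"` for
#'   tRNA-Phe).
#' @return an object of class `cloverleaf`: fields `seq`, `length`,
#'   `anticodon`, `anticodon_start`, `acceptor`, `d_arm`,
#'   `anticodon_arm`, `t_arm` (each arm a list of positions or `NULL` when
#'   absent), `pairs` (two-column matrix of paired positions) and
#'   `is_canonical`.
#' @export
fold_cloverleaf <- function(seq, anticodon) {
  seq <- toupper(seq)
  anticodon <- toupper(anticodon)
  L <- nchar(seq)
  if (L < 55L || L > 95L)
    stop("tRNA length ", L, " outside the 55-95 nt folding range")
  if (nchar(anticodon) != 3L) stop("anticodon must be 3 nt")
  ch <- seq_chars(seq)
  occ <- gregexpr(anticodon, seq, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) stop("anticodon ", anticodon, " not found in sequence")

  cands <- lapply(as.integer(occ), function(a) fold_at_anchor(ch, L, a))
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) stop("no feasible anticodon-loop placement for ", anticodon)
  score <- vapply(cands, function(x) x$n_paired, numeric(1))
  best <- cands[[which.max(score)]]  # which.max takes the first (5'-most) tie

  best$seq <- seq
  best$length <- L
  best$anticodon <- anticodon
  best$is_canonical <- !is.null(best$acceptor) && !is.null(best$d_arm) &&
    !is.null(best$anticodon_arm) && !is.null(best$t_arm)
  class(best) <- "cloverleaf"
  best
}

# fold with the anticodon starting at position a (loop = a-2 .. a+4)
fold_at_anchor <- function(ch, L, a) {
  loop5 <- a - 3L   # last position of the anticodon-stem 5' half
  loop3 <- a + 5L   # first position of the anticodon-stem 3' half
  if (loop5 < 9L || loop3 + 4L > L - 8L) return(NULL)  # room for other arms

  # anticodon stem: greedy outward extension, target 5, cap 5
  s_ac <- 0L
  while (s_ac < 5L && loop5 - s_ac >= 1L && loop3 + s_ac <= L &&
         can_pair(ch[loop5 - s_ac], ch[loop3 + s_ac])) s_ac <- s_ac + 1L
  ac_arm <- NULL
  if (s_ac >= 4L) {
    ac_arm <- list(stem_len = s_ac, loop_start = a - 2L, anticodon_start = a,
                   pairs = cbind(loop5 - seq_len(s_ac) + 1L,
                                 loop3 + seq_len(s_ac) - 1L))
  }

  # acceptor stem: 7 terminal pairs, <=1 mismatch, discriminator optional
  acceptor <- NULL
  for (disc in c(1L, 0L)) {
    ok <- vapply(1:7, function(i) can_pair(ch[i], ch[L - disc - i + 1L]), logical(1))
    if (sum(ok) >= 6L) {
      acceptor <- list(stem_len = 7L, mismatches = 7L - sum(ok),
                       discriminator = disc == 1L,
                       pairs = cbind(1:7, L - disc + 1L - 1:7)[ok, , drop = FALSE])
      break
    }
  }

  d_arm <- NULL; t_arm <- NULL
  if (!is.null(ac_arm)) {
    stem5_start <- loop5 - s_ac + 1L
    d_arm <- search_arm(ch, from = 8L, to = stem5_start - 1L,
                        stem_range = 4:3, loop_range = 4:12)
    stem3_end <- loop3 + s_ac - 1L
    acc3_start <- L - (if (!is.null(acceptor) && acceptor$discriminator) 1L else 0L) - 6L
    t_arm <- search_arm(ch, from = stem3_end + 1L, to = acc3_start - 1L,
                        stem_range = 5:4, loop_range = 4:9)
  }

  pairs <- rbind(if (!is.null(acceptor)) acceptor$pairs,
                 if (!is.null(d_arm)) d_arm$pairs,
                 if (!is.null(ac_arm)) ac_arm$pairs,
                 if (!is.null(t_arm)) t_arm$pairs)
  list(anticodon_start = a, acceptor = acceptor, d_arm = d_arm,
       anticodon_arm = ac_arm, t_arm = t_arm,
       pairs = pairs, n_paired = if (is.null(pairs)) 0L else 2L * nrow(pairs))
}

# find a hairpin (stem + loop) wholly inside [from, to]; prefer longer
# stems, then 5'-most placements; all stem pairs must match (no mismatch)
search_arm <- function(ch, from, to, stem_range, loop_range) {
  if (to - from + 1L < 2L * min(stem_range) + min(loop_range)) return(NULL)
  for (s in stem_range) {
    for (p in from:to) {
      for (l in loop_range) {
        q <- p + s + l          # 3' half start
        if (q + s - 1L > to) next
        ok <- all(vapply(seq_len(s), function(k)
          can_pair(ch[p + k - 1L], ch[q + s - k]), logical(1)))
        if (ok) {
          return(list(start = p, stem_len = s, loop_len = l,
                      end = q + s - 1L,
                      pairs = cbind(p + seq_len(s) - 1L, q + s - seq_len(s))))
        }
      }
    }
  }
  NULL
}

#' @export
print.cloverleaf <- function(x, ...) {
  arm <- function(a) if (is.null(a)) "absent" else "present"
  cat(sprintf("<cloverleaf> %d nt, anticodon %s at %d | acceptor: %s, D-arm: %s, anticodon arm: %s, T-arm: %s | %s\n",
              x$length, x$anticodon, x$anticodon_start,
              arm(x$acceptor), arm(x$d_arm), arm(x$anticodon_arm), arm(x$t_arm),
              if (x$is_canonical) "canonical" else "NON-canonical"))
  cat(dot_bracket(x), "\n")
  invisible(x)
}

#' Dot-bracket rendering of a cloverleaf
#'
#' @param x a `cloverleaf` from [fold_cloverleaf()].
#' @return a string with `(`/`)` at paired positions and `.` elsewhere.
#' @export
dot_bracket <- function(x) {
  stopifnot(inherits(x, "cloverleaf"))
  db <- rep(".", x$length)
  if (!is.null(x$pairs) && nrow(x$pairs)) {
    db[x$pairs[, 1L]] <- "("
    db[x$pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' Fold every annotated tRNA of a mitogenome
#'
#' @param g a sequence-bearing [mitogenome] with tRNA annotations carrying
#'   anticodons.  tRNAs without an anticodon are skipped with a warning.
#' @return list with `structures` (named list of `cloverleaf`) and
#'   `summary` (data frame: name, length, per-arm presence, canonical
#'   flag), plus counts `n_canonical` / `n_noncanonical`.
#' @export
fold_all <- function(g) {
  stopifnot(inherits(g, "mitogenome"))
  if (is.na(g$sequence)) stop("sequence-bearing mitogenome required")
  trnas <- g$features[g$features$category == "tRNA", , drop = FALSE]
  structures <- list()
  rows <- list()
  for (i in seq_len(nrow(trnas))) {
    f <- trnas[i, , drop = FALSE]
    if (is.na(f$anticodon)) {
      warning("tRNA '", f$name, "' has no anticodon annotation; skipped")
      next
    }
    cl <- fold_cloverleaf(extract_feature_seq(g, f), f$anticodon)
    structures[[f$name]] <- cl
    rows[[length(rows) + 1L]] <- data.frame(
      name = f$name, length = cl$length,
      acceptor = !is.null(cl$acceptor), d_arm = !is.null(cl$d_arm),
      anticodon_arm = !is.null(cl$anticodon_arm), t_arm = !is.null(cl$t_arm),
      canonical = cl$is_canonical, stringsAsFactors = FALSE)
  }
  summ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), length = integer(0),
               acceptor = logical(0), d_arm = logical(0),
               anticodon_arm = logical(0), t_arm = logical(0),
               canonical = logical(0), stringsAsFactors = FALSE)
  list(structures = structures, summary = summ,
       n_canonical = sum(summ$canonical),
       n_noncanonical = sum(!summ$canonical))
}

#' Write a per-tRNA structure report as TSV
#'
#' @param folds result of [fold_all()].
#' @param path output path.
#' @param header_comment optional provenance lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_trna_tsv <- function(folds, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  s <- folds$summary
  s$dot_bracket <- vapply(s$name, function(nm) dot_bracket(folds$structures[[nm]]),
                          character(1))
  write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Synthetic canonical tRNA construction --------------------------------------

#' Construct a synthetic canonical tRNA arm-by-arm
#'
#' Builds a cloverleaf of a requested length with known stem positions:
#' 7-bp acceptor stem + discriminator, D-arm (3-4 bp stem), 5-bp (or 4-bp)
#' anticodon stem around a 7-nt loop carrying the given anticodon, and a
#' T-arm (4-5 bp stem).  Loop and spacer bases are drawn from {A, C} only,
#' so single-stranded regions cannot base-pair with anything (no pair in
#' the allowed set joins two of A/C); this keeps the planted structure the
#' unique cloverleaf assignment.  Stem pairs are Watson-Crick.  Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param anticodon 3-nt DNA string placed at loop positions 3-5.
#' @param length target length, 58-80 nt (the printed mito-tRNA range
#'   59-75 is covered).
#' @param d_arm if `FALSE`, the D-arm is replaced by an unpaired A/C loop
#'   of the same footprint, emulating the mt tRNA-Ser(AGY) architecture.
#' @return list: `seq` (DNA string) and `truth` (planted layout: per-arm
#'   stem lengths and positions, a `cloverleaf`-compatible description).
#' @export
synth_trna <- function(anticodon, length = 72L, d_arm = TRUE) {
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L)
  p <- fit_trna_layout(as.integer(length))
  if (!d_arm) p$d_stem <- 0L  # footprint becomes loop-only

  rand_loop <- function(n) if (n <= 0L) "" else
    paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
  rand_stem <- function(n) {
    half <- paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
    list(fwd = half, rev = revcomp(half))
  }

  d_foot_len <- 2L * p$d_stem + p$d_loop +
    if (d_arm) 0L else 2L * fit_trna_layout(as.integer(length))$d_stem - 2L * p$d_stem

  for (try in 1:25) {
    acc <- rand_stem(7L)
    dst <- if (d_arm) rand_stem(p$d_stem) else NULL
    acs <- rand_stem(p$ac_stem)
    tst <- rand_stem(p$t_stem)
    d_footprint <- if (d_arm) paste0(dst$fwd, rand_loop(p$d_loop), dst$rev)
      else rand_loop(d_foot_len)
    loop_ac <- paste0(rand_loop(2L), anticodon, rand_loop(2L))
    seq <- paste0(acc$fwd,                         # 1..7 acceptor 5'
                  rand_loop(2L),                   # spacer
                  d_footprint,                     # D arm (or its replacement)
                  rand_loop(1L),                   # spacer
                  acs$fwd, loop_ac, acs$rev,       # anticodon arm
                  rand_loop(p$var),                # variable region
                  tst$fwd, rand_loop(p$t_loop), tst$rev,  # T arm
                  acc$rev,                         # acceptor 3'
                  rand_loop(1L))                   # discriminator
    stopifnot(nchar(seq) == length)

    # a draw can by chance admit an alternative fold (e.g. a longer
    # spurious D-stem straddling a spacer); redraw until the planted
    # layout is the one the folder recovers
    cl <- fold_cloverleaf(seq, anticodon)
    ok <- !is.null(cl$acceptor) && cl$acceptor$mismatches == 0L &&
      !is.null(cl$anticodon_arm) && cl$anticodon_arm$stem_len == p$ac_stem &&
      (if (d_arm) !is.null(cl$d_arm) && cl$d_arm$stem_len == p$d_stem
       else is.null(cl$d_arm)) &&
      !is.null(cl$t_arm) && cl$t_arm$stem_len == p$t_stem &&
      cl$is_canonical == d_arm
    if (ok) break
  }
  if (!ok) stop("could not realize a clean cloverleaf of length ", length)

  d_start <- 10L
  ac_stem_start <- d_start + nchar(d_footprint) + 1L
  t_start <- ac_stem_start + 2L * p$ac_stem + 7L + p$var
  truth <- list(length = as.integer(length), anticodon = anticodon,
                anticodon_start = ac_stem_start + p$ac_stem + 2L,
                acceptor_stem = 7L,
                d_stem = if (d_arm) p$d_stem else NA_integer_,
                d_start = if (d_arm) d_start else NA_integer_,
                ac_stem = p$ac_stem,
                t_stem = p$t_stem, t_start = t_start,
                canonical = d_arm)
  list(seq = seq, truth = truth)
}

# distribute a length target over the flexible cloverleaf elements;
# base layout (d_stem 4, d_loop 8, ac_stem 5, var 4, t_stem 5, t_loop 7)
# totals 72 nt with 7-bp acceptor, 2+1 spacers and a discriminator
fit_trna_layout <- function(target) {
  p <- list(d_stem = 4L, d_loop = 8L, ac_stem = 5L, var = 4L,
            t_stem = 5L, t_loop = 7L)
  delta <- target - 72L
  if (delta > 0L) {
    for (g in list(c("d_loop", 12L), c("var", 6L), c("t_loop", 9L))) {
      room <- as.integer(g[2L]) - p[[g[1L]]]
      take <- min(room, delta); p[[g[1L]]] <- p[[g[1L]]] + take; delta <- delta - take
      if (delta == 0L) break
    }
  } else if (delta < 0L) {
    need <- -delta
    # loops can absorb at most 8 nt; each shrinkable stem sheds exactly 2,
    # so fix the number of stems to shrink first to make the loop share fit
    k <- max(0L, as.integer(ceiling((need - 8L) / 2)))
    if (k > 3L) { delta <- -1L; need <- NA_integer_ }
    else {
      for (st in head(c("d_stem", "t_stem", "ac_stem"), k))
        p[[st]] <- p[[st]] - 1L
      need <- need - 2L * k
      for (s in list(c("d_loop", 4L), c("var", 3L), c("t_loop", 4L))) {
        room <- p[[s[1L]]] - as.integer(s[2L])
        take <- min(room, need); p[[s[1L]]] <- p[[s[1L]]] - take; need <- need - take
      }
      delta <- -need
    }
  }
  if (delta != 0L)
    stop("cannot fit a canonical cloverleaf layout to length ", target)
  p
}
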