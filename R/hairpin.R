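# Secondary structure of candidate hairpins and the structure-derived
# quantities used by the calling criteria: pseudo-energy per nt, duplex
# pairing fraction, and 3' overhang geometry.

PAIR_SCORES <- c(GC = -2, CG = -2, AT = -1, TA = -1, GT = -1, TG = -1)

pair_energy <- function(a, b) {
  s <- PAIR_SCORES[paste0(a, b)]
  ifelse(is.na(s), 0, s)
}

#' Fold a candidate hairpin sequence
#'
#' Base-pair maximization in the style of Nussinov, with pair pseudo-energies
#' GC = -2, AU = -1, GU = -1 (T is read as U), a minimum hairpin loop of 3 nt,
#' and deterministic tie-breaking toward the structure whose opening pair is
#' 5'-most. The resulting energies are in pseudo-kcal/mol: comparable between
#' sequences folded by this model, but not on the thermodynamic scale of
#' nearest-neighbor folders. Thermodynamic structures computed externally can
#' be supplied instead via [read_structure()].
#'
#' @param seq DNA/RNA sequence, 20-500 nt (shorter sequences are accepted for
#'   testing; they simply have few legal pairs).
#' @param locus_id optional identifier carried on the structure.
#' @return an object of class `hairpin_structure` with fields `seq`,
#'   `dotbracket`, `pair_map` (1-based partner index or NA), `energy`
#'   (pseudo-kcal/mol, <= 0), and `backend = "internal"`.
#' @export
fold <- function(seq, locus_id = NA_character_) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  if (grepl("[^ACGTN]", seq)) stop("illegal alphabet in sequence")
  if (nchar(seq) > 500L) stop("sequence longer than 500 nt")
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  # numeric pair-score matrix: PE[i, k] = pseudo-energy of pairing i with k
  base_idx <- match(b, c("A", "C", "G", "T", "N"))
  pe_tab <- matrix(0, 5L, 5L,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("A", "C", "G", "T", "N")))
  for (p in names(PAIR_SCORES))
    pe_tab[substr(p, 1, 1), substr(p, 2, 2)] <- PAIR_SCORES[[p]]
  PE <- pe_tab[base_idx, base_idx, drop = FALSE]
  PE[PE == 0] <- Inf  # non-pairable
  E <- matrix(0, n + 1L, n + 1L)
  if (n >= 5L) {
    for (i in (n - 4L):1L) {
      Erow <- E[i + 1L, ]
      for (j in (i + 4L):n) {
        cand <- PE[i, (i + 4L):j] + Erow[(i + 3L):(j - 1L)] +
          E[(i + 5L):(j + 1L), j]
        E[i, j] <- min(Erow[j], cand)
      }
    }
  }
  pair_map <- rep(NA_integer_, n)
  # traceback, preferring to pair position i (5'-most opening pair) on ties
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (i <= j - 4L) {
      target <- E[i, j]
      ks <- (i + 4L):j
      cand <- PE[i, ks] + E[i + 1L, (i + 3L):(j - 1L)] +
        E[(i + 5L):(j + 1L), j]
      hit <- which(cand == target)
      if (length(hit)) {
        k <- ks[hit[1L]]
        pair_map[i] <- k
        pair_map[k] <- i
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        j <- k - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  db <- rep(".", n)
  db[!is.na(pair_map) & seq_len(n) < pair_map] <- "("
  db[!is.na(pair_map) & seq_len(n) > pair_map] <- ")"
  structure(list(locus_id = locus_id, seq = seq,
                 dotbracket = paste(db, collapse = ""),
                 pair_map = pair_map,
                 energy = if (n >= 5L) E[1L, n] else 0,
                 backend = "internal"),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("hairpin_structure %s (%d nt, %s, energy %.2f)\n%s\n%s\n",
              x$locus_id, nchar(x$seq), x$backend, x$energy,
              x$seq, x$dotbracket))
  invisible(x)
}

dotbracket_to_pair_map <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c(".", "(", ")"))) stop("illegal dot-bracket character")
  pair_map <- rep(NA_integer_, length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      pair_map[i] <- j
      pair_map[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  pair_map
}

#' Read an externally folded structure
#'
#' Three-line text format compatible with common RNA-folding text output:
#' line 1 the sequence, line 2 the dot-bracket string, line 3 `energy=<float>`
#' (thermodynamic kcal/mol). Use external structures when real folding
#' energies matter, e.g. to apply the -0.2 kcal/mol/nt criterion threshold.
#'
#' @param path structure file.
#' @param locus_id optional identifier.
#' @return `hairpin_structure` with `backend = "external"`.
#' @export
read_structure <- function(path, locus_id = NA_character_) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 3L) stop("structure file needs sequence, dot-bracket, energy lines")
  seq <- chartr("Uu", "Tt", toupper(trimws(ln[1L])))
  db <- trimws(ln[2L])
  if (nchar(db) != nchar(seq)) stop("dot-bracket length differs from sequence")
  if (!grepl("^energy=", ln[3L])) stop("third line must be 'energy=<float>'")
  energy <- as.numeric(sub("^energy=", "", trimws(ln[3L])))
  if (is.na(energy)) stop("unparseable energy value")
  pm <- dotbracket_to_pair_map(db)
  structure(list(locus_id = locus_id, seq = seq, dotbracket = db,
                 pair_map = pm, energy = energy, backend = "external"),
            class = "hairpin_structure")
}

#' Folding energy per nucleotide
#' @param structure a `hairpin_structure`.
#' @return energy / length (kcal/mol/nt, or pseudo-units for the internal model).
#' @export
mfe_per_nt <- function(structure) {
  structure$energy / nchar(structure$seq)
}

#' Minimum-folding-energy criterion
#'
#' Passes iff the per-nucleotide energy is strictly below the threshold.
#' The canonical threshold for thermodynamic energies is -0.2 kcal/mol/nt;
#' for the internal pseudo-energy model the recalibrated default is -0.5
#' pseudo-kcal/mol/nt (see the methods vignette).
#'
#' @param structure a `hairpin_structure`.
#' @param threshold per-nt threshold; default depends on the backend.
#' @return logical.
#' @export
passes_energy <- function(structure,
                          threshold = if (structure$backend == "internal")
                            -0.5 else -0.2) {
  mfe_per_nt(structure) < threshold
}

as_duplex <- function(mir5p, mir3p) {
  stopifnot(length(mir5p) == 2L, length(mir3p) == 2L,
            mir5p[1L] < mir5p[2L], mir3p[1L] < mir3p[2L])
  if (mir5p[2L] > mir3p[1L])
    stop("mir5p must lie entirely 5' of mir3p")
  list(mir5p = as.integer(mir5p), mir3p = as.integer(mir3p))
}

#' Fraction of duplex positions paired in the hairpin
#'
#' @param structure a `hairpin_structure`.
#' @param duplex list with `mir5p` and `mir3p` 0-based half-open intervals in
#'   hairpin-local coordinates.
#' @return fraction in 0..1 of positions within mir5p and mir3p that are
#'   paired in the structure.
#' @export
pairing_fraction <- function(structure, duplex) {
  duplex <- as_duplex(duplex$mir5p, duplex$mir3p)
  pos <- c(seq(duplex$mir5p[1L], duplex$mir5p[2L] - 1L),
           seq(duplex$mir3p[1L], duplex$mir3p[2L] - 1L))
  if (any(pos < 0L) || any(pos >= nchar(structure$seq)))
    stop("duplex intervals outside structure")
  mean(!is.na(structure$pair_map[pos + 1L]))
}

#' Duplex pairing criterion
#' @param fraction output of [pairing_fraction()].
#' @param threshold minimum fraction; inclusive (at least 60% paired).
#' @return logical.
#' @export
passes_pairing <- function(fraction, threshold = 0.60) {
  fraction >= threshold
}

# Effective pairing partner of the 5' terminus of an arm: if unpaired, scan
# inward (3'-wards) up to 3 nt for the nearest paired position, correcting
# for the offset; NA if unresolvable.
effective_partner <- function(pair_map, p) {
  for (d in 0:3) {
    q <- if (p + d + 1L <= length(pair_map)) pair_map[p + d + 1L] else NA
    if (!is.na(q)) return(q - 1L + d)  # back to 0-based, offset-corrected
  }
  NA_integer_
}

#' 3' overhangs of a miRNA duplex
#'
#' The 2-nt 3' overhang at each duplex end is the RNase III cleavage
#' signature. With 0-based hairpin-local coordinates, the overhang on the 3p
#' arm is (mir3p 3'-end index) - partner(mir5p 5'-end), and on the 5p arm
#' (mir5p 3'-end index) - partner(mir3p 5'-end). Unpaired termini are
#' resolved by scanning inward up to 3 nt; an unresolvable overhang is NA
#' (the overhang criterion then fails).
#'
#' @param structure a `hairpin_structure`.
#' @param duplex list with `mir5p` and `mir3p` intervals (0-based half-open).
#' @return integer vector `c(overhang_3p_arm3, overhang_3p_arm5)`, NA where
#'   undefined.
#' @export
overhangs <- function(structure, duplex) {
  duplex <- as_duplex(duplex$mir5p, duplex$mir3p)
  pm <- structure$pair_map
  p5 <- effective_partner(pm, duplex$mir5p[1L])
  p3 <- effective_partner(pm, duplex$mir3p[1L])
  c(overhang_3p_arm3 = if (is.na(p5)) NA_integer_ else
      (duplex$mir3p[2L] - 1L) - p5,
    overhang_3p_arm5 = if (is.na(p3)) NA_integer_ else
      (duplex$mir5p[2L] - 1L) - p3)
}
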