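#' Default stacking energy table
#'
#' The built-in folding engine uses a stacking-only nearest-neighbour model:
#' the only energetic contributions are stack terms between adjacently nested
#' base pairs, so a helix of `k` pairs scores the sum of its `k - 1` stacks
#' and an isolated (lone) pair scores zero.  The table is a 6 x 6 matrix over
#' the pair types `AU, UA, CG, GC, GU, UG`, in kcal/mol; entry `[p1, p2]` is
#' the stack formed by pair `p1` at positions `(i, j)` closing over pair `p2`
#' at `(i + 1, j - 1)`.  Defaults are Turner-style Watson-Crick stack free
#' energies with mildly stabilising G:U values; every entry is negative so
#' energies are non-positive by construction.
#'
#' @return A 6 x 6 numeric matrix with dimnames `c("AU","UA","CG","GC","GU","UG")`.
#' @export
#' @examples
#' default_stack_energies()["CG", "CG"]
default_stack_energies <- function() {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(c(
    # closing over:  AU     UA     CG     GC     GU     UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.4,  # GU
    -1.0, -1.2, -2.3, -1.9, -0.2, -0.7   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pt, pt))
  m
}

#' Read a stacking energy table from a TSV file
#'
#' Expects a 6 x 6 table with pair-type row names in the first column and the
#' pair types `AU UA CG GC GU UG` as header, values in kcal/mol.
#'
#' @param path Path to a tab-separated file.
#' @return A 6 x 6 numeric matrix usable as `energy_table`.
#' @export
read_stack_energies <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!all(pt %in% rownames(df)) || !all(pt %in% colnames(df))) {
    stop("energy table must have rows and columns AU, UA, CG, GC, GU, UG")
  }
  as.matrix(df[pt, pt])
}

# encode an RNA/DNA string as integers A=0, C=1, G=2, U/T=3 (case-insensitive)
encode_rna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  codes <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "))
  }
  codes
}

decode_rna <- function(codes) {
  paste(c("A", "C", "G", "U")[codes + 1L], collapse = "")
}

pair_type_chr <- function(a, b) {
  key <- paste0(a, b)
  c(AU = 1L, UA = 2L, CG = 3L, GC = 4L, GU = 5L, UG = 6L)[key]
}

partner_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  paired <- which(partner > 0)
  db[paired[partner[paired] > paired]] <- "("
  db[paired[partner[paired] < paired]] <- ")"
  paste(db, collapse = "")
}

#' Fold a single RNA sequence
#'
#' Computes the minimum-energy secondary structure under the built-in
#' stacking-only nearest-neighbour model (see [default_stack_energies()]).
#' Pairs are Watson-Crick or G:U, hairpin loops hold at least `min_loop`
#' unpaired bases, and pseudoknots are not considered.  Ties are broken
#' deterministically (unpaired preferred, then the 5'-most partner), so the
#' same sequence always returns the same dot-bracket; a structure with no
#' pairs has energy exactly 0.
#'
#' @param sequence RNA or DNA string (T is treated as U); length >= 10.
#' @param energy_table 6 x 6 stacking table, kcal/mol.
#' @param helix_init Initiation penalty charged once per helix, kcal/mol
#'   (default 4.1); makes isolated short chance helices unprofitable so that
#'   random sequence folds near zero while genuine hairpins fold deeply.
#' @param min_loop Minimum hairpin loop size in nt (default 3).
#' @return An object of class `rna_fold`: a list with `sequence` (as RNA),
#'   `structure` (dot-bracket), `energy` (kcal/mol, <= 0) and `partner`
#'   (integer vector, 0 = unpaired, otherwise 1-based pairing partner).
#' @export
#' @examples
#' fold_sequence("GGGGGAAACUUUUCCCCC")$energy
fold_sequence <- function(sequence, energy_table = default_stack_energies(),
                          helix_init = 4.1, min_loop = 3L) {
  codes <- encode_rna(sequence)
  if (length(codes) < 10) {
    stop("fold_sequence() needs a sequence of at least 10 nt, got ",
         length(codes))
  }
  res <- fold_mfe_cpp(codes, energy_table, as.integer(min_loop), helix_init)
  structure(
    list(
      sequence = decode_rna(codes),
      structure = partner_to_dotbracket(res$partner),
      energy = res$energy,
      partner = res$partner
    ),
    class = "rna_fold"
  )
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("energy: %.2f kcal/mol", x$energy), "\n", sep = "")
  invisible(x)
}

# exhaustive-enumeration minimum energy; validation oracle for fold_sequence()
# on short sequences (exponential in length -- keep below ~30 nt).
enumerate_min_energy <- function(sequence,
                                 energy_table = default_stack_energies(),
                                 helix_init = 4.1, min_loop = 3L,
                                 max_structures = 5e8) {
  codes <- encode_rna(sequence)
  enumerate_mfe_cpp(codes, energy_table, as.integer(min_loop), helix_init,
                    max_structures)
}

#' Fold two strands as an intermolecular duplex
#'
#' Finds the best co-axial (ungapped, antiparallel) alignment of two strands,
#' allowing no intramolecular pairs.  For each relative offset, aligned
#' positions that form Watson-Crick or G:U pairs contribute stack terms
#' between consecutive paired positions; mismatches interrupt stacking.  The
#' reported energy is the minimum over all offsets, so a strand paired with
#' its exact reverse complement attains the lowest energy possible for its
#' composition.
#'
#' @param strand_a,strand_b RNA/DNA strings, both 5' to 3'.
#' @param energy_table 6 x 6 stacking table, kcal/mol.
#' @param helix_init Initiation penalty per contiguous paired run of two or
#'   more positions, kcal/mol.
#' @return A list with `energy` (kcal/mol), `offset`, and `pairs`, a tibble
#'   with 1-based `pos_a`, `pos_b` and the pair `type` (`"WC"` or `"GU"`).
#' @export
#' @examples
#' fold_duplex("ACGUACGUACGU", "ACGUACGUACGU")$energy  # self-complementary
fold_duplex <- function(strand_a, strand_b,
                        energy_table = default_stack_energies(),
                        helix_init = 4.1) {
  a <- encode_rna(strand_a)
  b <- encode_rna(strand_b)
  if (length(a) == 0 || length(b) == 0) stop("both strands must be non-empty")
  br <- rev(b)  # reversed so aligned indices run in the same direction
  la <- length(a)
  lb <- length(b)
  pt_tab <- matrix(0L, 4, 4)
  pt_tab[1, 4] <- 1L; pt_tab[4, 1] <- 2L; pt_tab[2, 3] <- 3L
  pt_tab[3, 2] <- 4L; pt_tab[3, 4] <- 5L; pt_tab[4, 3] <- 6L

  best_energy <- 0
  best_offset <- 0L
  best_pt <- integer(0)
  best_idx <- integer(0)
  for (off in (-(la - 1L)):(lb - 1L)) {
    i <- seq_len(la)
    j <- i + off
    keep <- j >= 1L & j <= lb
    i <- i[keep]; j <- j[keep]
    if (length(i) < 2) next
    pt <- pt_tab[cbind(a[i] + 1L, br[j] + 1L)]
    # score each maximal run of consecutive paired positions: its stacks
    # plus one initiation charge (runs of a single pair contribute nothing)
    e <- 0
    runs <- rle(pt > 0L)
    stops <- cumsum(runs$lengths)
    starts_r <- stops - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      if (!runs$values[r] || runs$lengths[r] < 2L) next
      ks <- starts_r[r]:(stops[r] - 1L)
      e <- e + helix_init + sum(energy_table[cbind(pt[ks], pt[ks + 1L])])
    }
    if (e < best_energy) {
      best_energy <- e
      best_offset <- off
      best_pt <- pt
      best_idx <- i
    }
  }
  pairs <- tibble::tibble(pos_a = integer(0), pos_b = integer(0),
                          type = character(0))
  if (length(best_idx)) {
    paired <- best_pt > 0L
    pos_a <- best_idx[paired]
    pos_b <- lb - (best_idx[paired] + best_offset) + 1L
    pairs <- tibble::tibble(
      pos_a = pos_a,
      pos_b = as.integer(pos_b),
      type = ifelse(best_pt[paired] >= 5L, "GU", "WC")
    )
  }
  list(energy = best_energy, offset = best_offset, pairs = pairs)
}

# Altschul-Erickson dinucleotide-preserving shuffle of one encoded sequence.
# Returns an encoded sequence with exactly the original dinucleotide counts.
dinucleotide_shuffle <- function(codes) {
  n <- length(codes)
  if (n < 4) stop("sequence too short to shuffle (< 4 nt)")
  edges <- vector("list", 4)
  for (v in 1:4) edges[[v]] <- codes[which(codes[-n] == (v - 1L)) + 1L]
  first <- codes[1] + 1L
  last <- codes[n] + 1L
  vertices <- sort(unique(codes)) + 1L

  repeat {
    # choose a random last-exit edge for every vertex except the final one;
    # the chosen edges must form a tree pointing toward `last`
    last_edge <- rep(NA_integer_, 4)
    for (v in vertices) {
      if (v == last) next
      outs <- edges[[v]]
      if (length(outs) == 0) next
      last_edge[v] <- outs[sample.int(length(outs), 1)] + 1L
    }
    # connectivity check: every vertex with a last edge must reach `last`
    ok <- TRUE
    for (v in vertices) {
      if (v == last || is.na(last_edge[v])) next
      seen <- integer(0)
      cur <- v
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- last_edge[cur]
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # shuffle remaining edges, appending the reserved last-exit edge
  pool <- vector("list", 4)
  for (v in 1:4) {
    outs <- edges[[v]]
    if (!is.na(last_edge[v])) {
      drop <- match(last_edge[v] - 1L, outs)
      outs <- outs[-drop]
    }
    outs <- if (length(outs) > 1) outs[sample.int(length(outs))] else outs
    if (!is.na(last_edge[v])) outs <- c(outs, last_edge[v] - 1L)
    pool[[v]] <- outs
  }
  # walk the Euler path
  out <- integer(n)
  out[1] <- first - 1L
  ptr <- rep(1L, 4)
  cur <- first
  for (i in 2:n) {
    nxt <- pool[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt + 1L
  }
  out
}

#' Dinucleotide-shuffle randomization test for folding energy
#'
#' Compares the folding energy of a sequence with the energies of
#' dinucleotide-composition-preserving shuffles (Altschul-Erickson Euler-path
#' method).  The empirical P-value uses the add-one estimator
#' `P = (1 + #\{shuffle energy <= observed\}) / (n_shuffles + 1)`, so it lies
#' in `[1/(n+1), 1]`.  Used to reject pseudo-hairpins whose energy is not
#' unusually low for their composition.
#'
#' @param sequence RNA/DNA string, >= 10 nt.
#' @param n_shuffles Number of shuffles (>= 19; default 99).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @param energy_table,helix_init,min_loop Passed to [fold_sequence()].
#' @return A list with `observed` energy, `n_shuffles`, `p_value`, `seed` and
#'   the vector of `shuffled_energies`.
#' @export
shuffle_test <- function(sequence, n_shuffles = 99L, seed = 1L,
                         energy_table = default_stack_energies(),
                         helix_init = 4.1, min_loop = 3L) {
  if (n_shuffles < 19) stop("n_shuffles must be at least 19")
  codes <- encode_rna(sequence)
  if (length(codes) < 4) stop("sequence too short to shuffle (< 4 nt)")
  observed <- fold_sequence(sequence, energy_table, helix_init,
                            min_loop)$energy
  energies <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- dinucleotide_shuffle(codes)
      fold_mfe_cpp(shuf, energy_table, as.integer(min_loop), helix_init)$energy
    }, numeric(1))
  })
  p <- (1 + sum(energies <= observed + 1e-9)) / (n_shuffles + 1)
  list(observed = observed, n_shuffles = as.integer(n_shuffles),
       p_value = p, seed = as.integer(seed), shuffled_energies = energies)
}

#' Hairpin geometry of a mature miRNA within a folded precursor
#'
#' Derives, from the pairing map of a folded precursor, the quantities used
#' by the discovery criteria: which arm holds the mature sequence, the number
#' of paired bases in the mature/star duplex, the largest bulge, the duplex
#' asymmetry, and the space between the mature and star intervals.
#'
#' @param fold An `rna_fold` object from [fold_sequence()].
#' @param mature_start,mature_end 1-based inclusive interval of the mature
#'   sequence within the precursor.
#' @return A one-row tibble with columns `arm` (`"5p"`, `"3p"`,
#'   `"loop_spanning"` or `"unpaired"`), `n_pairs`, `max_bulge`, `asymmetry`,
#'   `space`, `star_start`, `star_end`.
#' @export
hairpin_geometry <- function(fold, mature_start, mature_end) {
  stopifnot(inherits(fold, "rna_fold"))
  n <- length(fold$partner)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end) {
    stop("mature interval [", mature_start, ", ", mature_end,
         "] out of range for precursor of length ", n)
  }
  mpos <- mature_start:mature_end
  partners <- fold$partner[mpos]
  paired <- partners > 0
  n_pairs <- sum(paired)
  if (n_pairs == 0) {
    return(tibble::tibble(arm = "unpaired", n_pairs = 0L, max_bulge = NA_integer_,
                          asymmetry = NA_integer_, space = NA_integer_,
                          star_start = NA_integer_, star_end = NA_integer_))
  }
  pp <- partners[paired]
  arm <- if (all(pp > mature_end)) "5p"
         else if (all(pp < mature_start)) "3p"
         else "loop_spanning"
  if (arm == "loop_spanning") {
    return(tibble::tibble(arm = arm, n_pairs = as.integer(n_pairs),
                          max_bulge = NA_integer_, asymmetry = NA_integer_,
                          space = NA_integer_, star_start = NA_integer_,
                          star_end = NA_integer_))
  }
  star_lo <- min(pp)
  star_hi <- max(pp)
  # 2 nt 3' overhang convention for the star strand
  if (arm == "5p") {
    star_start <- min(star_lo + 2L, n)
    star_end <- min(star_hi + 2L, n)
  } else {
    star_start <- max(star_lo - 2L, 1L)
    star_end <- max(star_hi - 2L, 1L)
  }
  max_run <- function(x) {
    if (!length(x) || !any(x)) return(0L)
    r <- rle(x)
    as.integer(max(r$lengths[r$values]))
  }
  bulge_mature <- max_run(!paired)
  star_partners <- fold$partner[star_lo:star_hi]
  bulge_star <- max_run(star_partners == 0)
  mature_len <- mature_end - mature_start + 1L
  star_len <- star_hi - star_lo + 1L
  space <- if (arm == "5p") star_lo - mature_end - 1L else mature_start - star_hi - 1L
  tibble::tibble(
    arm = arm,
    n_pairs = as.integer(n_pairs),
    max_bulge = as.integer(max(bulge_mature, bulge_star)),
    asymmetry = as.integer(abs(mature_len - star_len)),
    space = as.integer(space),
    star_start = as.integer(star_start),
    star_end = as.integer(star_end)
  )
}

#' Reverse complement of an RNA/DNA string
#'
#' @param sequence Input string; `rna = TRUE` returns U, otherwise T.
#' @return The reverse complement string.
#' @export
revcomp <- function(sequence, rna = FALSE) {
  codes <- rev(3L - encode_rna(sequence))
  if (rna) decode_rna(codes)
  else paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}
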