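#' Parameters for novel miRNA discovery
#'
#' The structural and expression thresholds a candidate hairpin must meet:
#' mature length 18-26 nt, at least 3 reads sharing the mature 5' end (the
#' cut-site depth), at most 20 genomic copies, precursor energy at or below
#' -18 kcal/mol, the mature confined to one arm, at least 14 mature/star
#' base pairs, bulges of at most 4 nt, duplex asymmetry of at most 5 nt, at
#' most 35 nt between mature and star, genomic context restricted to
#' intergenic regions or introns, and a final rejection of candidates whose
#' energy is above -20 kcal/mol unless a dinucleotide-shuffle test yields
#' P <= 0.05.
#'
#' @param mature_len,reference_len Length ranges (nt) for the mature and for
#'   reported candidates.
#' @param min_cut_depth Minimum reads sharing the mature 5' end.
#' @param max_copy_number Maximum genomic copies of the mature tag.
#' @param min_tag_count Minimum tag abundance considered (reads below this
#'   are dropped before excision).
#' @param max_precursor_energy Maximum (most positive) precursor folding
#'   energy, kcal/mol.
#' @param max_star_space,min_pairs,max_bulge,max_asymmetry Mature/star duplex
#'   geometry thresholds (nt / pairs / nt / nt).
#' @param flank_len Flanking sequence added around each excised window, nt.
#' @param window_range Candidate precursor spans scanned around the mature,
#'   nt.
#' @param window_step Step between scanned spans/positions, nt.
#' @param mipred_energy_cutoff,mipred_p_cutoff Energy and shuffle-test
#'   P-value cutoffs of the pseudo-hairpin rejection rule.
#' @param n_shuffles Shuffles used by the randomization test.
#' @param allowed_contexts Genomic contexts in which candidates may lie.
#' @return An object of class `discovery_params`.
#' @export
discovery_params <- function(mature_len = c(18L, 26L),
                             reference_len = c(20L, 24L),
                             min_cut_depth = 3L,
                             max_copy_number = 20L,
                             min_tag_count = 2L,
                             max_precursor_energy = -18,
                             max_star_space = 35L,
                             min_pairs = 14L,
                             max_bulge = 4L,
                             max_asymmetry = 5L,
                             flank_len = 10L,
                             window_range = c(60L, 120L),
                             window_step = 10L,
                             mipred_energy_cutoff = -20,
                             mipred_p_cutoff = 0.05,
                             n_shuffles = 99L,
                             allowed_contexts = c("intergenic", "intron")) {
  stopifnot(mature_len[1] <= mature_len[2], max_precursor_energy < 0,
            mipred_energy_cutoff < 0, window_range[1] <= window_range[2])
  structure(as.list(environment()), class = "discovery_params")
}

criterion_names <- c("mature_length", "cut_depth", "copy_number", "energy",
                     "one_arm", "pairs", "bulge", "asymmetry", "star_space",
                     "context", "mipred")

# genomic context of a locus: highest-priority overlapping feature type,
# "intergenic" when nothing with annotation value overlaps
locus_context <- function(chrom, start, end, features) {
  fx <- filter(features, .data$chrom == .env$chrom,
               .data$start < .env$end, .data$end > .env$start,
               .data$type %in% c("repeat", "exon", "intron", "ncRNA"))
  if (!nrow(fx)) return("intergenic")
  pri <- c("ncRNA", "repeat", "exon", "intron")
  pri[min(match(fx$type, pri))]
}

#' Excise candidate precursor windows around an expressed tag
#'
#' Scans precursor spans of `window_range[1]` to `window_range[2]` nt, in
#' `window_step` nt increments, positioned so that the mature tag lies
#' inside, each extended by `flank_len` nt; windows are truncated (with a
#' warning) at chromosome bounds.
#'
#' @param index A [build_genome_index()] object.
#' @param chrom,start,end Mature tag locus (0-based half-open).
#' @param strand Strand of the mapped tag.
#' @param params A [discovery_params()].
#' @return Tibble with `win_start`, `win_end` (0-based half-open, flank
#'   included), `mature_offset` (1-based position of the mature within the
#'   window on the tag strand) and `sequence` (tag-strand sequence).
#' @export
excise_precursor_windows <- function(index, chrom, start, end, strand,
                                     params = discovery_params()) {
  chrom_len <- nchar(as.character(index$seqs[[chrom]]))
  mlen <- end - start
  spans <- seq(params$window_range[1], params$window_range[2],
               by = params$window_step)
  rows <- list()
  truncated <- FALSE
  for (span in spans) {
    if (span < mlen) next
    for (lead in seq(0L, span - mlen, by = params$window_step)) {
      ws <- start - lead - params$flank_len
      we <- start - lead + span + params$flank_len
      if (ws < 0 || we > chrom_len) truncated <- TRUE
      ws <- max(ws, 0L)
      we <- min(we, chrom_len)
      if (we - ws < 50L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(win_start = ws, win_end = we)
    }
  }
  if (truncated) {
    warning("precursor window truncated at chromosome bounds near ",
            chrom, ":", start)
  }
  wins <- distinct(dplyr::bind_rows(rows))
  if (!nrow(wins)) {
    return(tibble::tibble(win_start = integer(0), win_end = integer(0),
                          mature_offset = integer(0), sequence = character(0)))
  }
  seqs <- substring(as.character(index$seqs[[chrom]]),
                    wins$win_start + 1L, wins$win_end)
  if (strand == "-") {
    seqs <- vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
    offsets <- wins$win_end - end + 1L
  } else {
    offsets <- start - wins$win_start + 1L
  }
  mutate(wins, mature_offset = as.integer(offsets), sequence = seqs)
}

#' Evaluate one precursor window as a miRNA hairpin candidate
#'
#' Folds the window and records a pass/fail verdict for every discovery
#' criterion; the candidate is accepted only if all criteria pass.  The
#' star sequence is derived geometrically from the pairing map with the
#' usual 2 nt 3' overhang; observed star reads are not required.
#'
#' @param window_seq Precursor window sequence (mature strand, 5' to 3').
#' @param mature_offset,mature_len 1-based position and length of the mature
#'   within the window.
#' @param cut_depth Reads sharing the mature 5' end.
#' @param copy_number Genomic copies of the mature tag.
#' @param context Genomic context (`"intergenic"`, `"intron"`, ...).
#' @param params A [discovery_params()].
#' @param seed Seed for the shuffle test (used only when the energy is above
#'   `mipred_energy_cutoff`).
#' @return A one-row tibble with the fold energy, structure, star interval,
#'   geometry, per-criterion verdicts (`crit_*` columns) and `accepted`.
#' @export
evaluate_candidate <- function(window_seq, mature_offset, mature_len,
                               cut_depth, copy_number, context,
                               params = discovery_params(), seed = 1L) {
  fold <- tryCatch(fold_sequence(window_seq), error = function(e) NULL)
  if (is.null(fold)) {
    crit <- setNames(as.list(rep(FALSE, length(criterion_names))),
                     paste0("crit_", criterion_names))
    return(tibble::tibble(energy = NA_real_, structure = NA_character_,
                          mature_seq = NA_character_, star_seq = NA_character_,
                          arm = NA_character_, n_pairs = NA_integer_,
                          max_bulge = NA_integer_, asymmetry = NA_integer_,
                          space = NA_integer_, shuffle_p = NA_real_,
                          !!!crit, accepted = FALSE,
                          reason = "fold_failure"))
  }
  geom <- hairpin_geometry(fold, mature_offset, mature_offset + mature_len - 1L)
  crit <- list(
    mature_length = mature_len >= params$mature_len[1] &&
      mature_len <= params$mature_len[2],
    cut_depth = cut_depth >= params$min_cut_depth,
    copy_number = copy_number <= params$max_copy_number,
    energy = fold$energy <= params$max_precursor_energy,
    one_arm = geom$arm %in% c("5p", "3p"),
    pairs = !is.na(geom$n_pairs) && geom$n_pairs >= params$min_pairs,
    bulge = !is.na(geom$max_bulge) && geom$max_bulge <= params$max_bulge,
    asymmetry = !is.na(geom$asymmetry) &&
      geom$asymmetry <= params$max_asymmetry,
    star_space = !is.na(geom$space) && geom$space >= 0 &&
      geom$space <= params$max_star_space
  )
  crit$context <- context %in% params$allowed_contexts
  shuffle_p <- NA_real_
  if (fold$energy <= params$mipred_energy_cutoff) {
    crit$mipred <- TRUE
  } else {
    shuffle_p <- shuffle_test(window_seq, n_shuffles = params$n_shuffles,
                              seed = seed)$p_value
    crit$mipred <- shuffle_p <= params$mipred_p_cutoff
  }
  crit <- crit[criterion_names]
  star <- if (!is.na(geom$star_start)) {
    substr(window_seq, geom$star_start, geom$star_end)
  } else NA_character_
  tibble::tibble(
    energy = fold$energy, structure = fold$structure,
    mature_seq = substr(window_seq, mature_offset,
                        mature_offset + mature_len - 1L),
    star_seq = star, arm = geom$arm, n_pairs = geom$n_pairs,
    max_bulge = geom$max_bulge, asymmetry = geom$asymmetry,
    space = geom$space, shuffle_p = shuffle_p,
    !!!setNames(crit, paste0("crit_", criterion_names)),
    accepted = all(unlist(crit)), reason = NA_character_
  )
}

#' Call novel miRNA candidates from unannotated tags
#'
#' For every unannotated, perfectly mapped tag passing the abundance floor
#' and copy-number cap, excises candidate precursor windows, keeps the
#' lowest-energy window per locus, evaluates all discovery criteria, and
#' deduplicates overlapping accepted loci (keeping the highest-expression
#' mature, ties broken 5'-most).  Deterministic given `seed`.
#'
#' @param tags Tag table ([collapse_tags()] output).
#' @param classifications Output of [classify_tags()] for the same tags.
#' @param hits Genome hits from [map_tags()].
#' @param index A [build_genome_index()] object.
#' @param features Feature interval tibble (for genomic context).
#' @param params A [discovery_params()].
#' @param seed Integer seed for the randomization test.
#' @return A list with `candidates` (accepted one-per-locus tibble including
#'   coordinates, energy, structure, mature/star sequences and read support)
#'   and `rejections` (every evaluated locus with per-criterion verdicts).
#' @export
call_novel_candidates <- function(tags, classifications, hits, index,
                                  features, params = discovery_params(),
                                  seed = 1L) {
  unann <- classifications$sequence[classifications$category == "unannotated"]
  cand_tags <- tags %>%
    mutate(total = .data$count_peak + .data$count_late,
           seq_norm = toupper(gsub("U", "T", .data$sequence))) %>%
    filter(.data$sequence %in% unann,
           .data$total >= params$min_tag_count,
           nchar(.data$sequence) >= params$mature_len[1],
           nchar(.data$sequence) <= params$mature_len[2])
  hit_tbl <- hits %>%
    filter(.data$copy_number <= params$max_copy_number) %>%
    left_join(select(cand_tags, "seq_norm", "total"),
              by = c(sequence = "seq_norm")) %>%
    filter(!is.na(.data$total))
  if (!nrow(hit_tbl)) {
    empty <- tibble::tibble(locus_id = character(0))
    return(list(candidates = empty, rejections = empty))
  }

  # cluster overlapping hits on the same chrom/strand into loci
  hit_tbl <- arrange(hit_tbl, .data$chrom, .data$strand, .data$start)
  cluster <- integer(nrow(hit_tbl))
  cid <- 0L
  last_chrom <- ""
  last_strand <- ""
  last_end <- -1L
  for (i in seq_len(nrow(hit_tbl))) {
    if (hit_tbl$chrom[i] != last_chrom || hit_tbl$strand[i] != last_strand ||
        hit_tbl$start[i] > last_end) {
      cid <- cid + 1L
      last_end <- hit_tbl$end[i]
    } else {
      last_end <- max(last_end, hit_tbl$end[i])
    }
    last_chrom <- hit_tbl$chrom[i]
    last_strand <- hit_tbl$strand[i]
    cluster[i] <- cid
  }
  hit_tbl$cluster <- cluster

  loci <- hit_tbl %>%
    group_by(.data$cluster) %>%
    arrange(desc(.data$total), .data$start, .by_group = TRUE) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      mature_start = .data$start[1], mature_end = .data$end[1],
      mature_tag = .data$sequence[1], copy_number = .data$copy_number[1],
      total_reads = sum(.data$total),
      cut_depth = sum(.data$total[.data$start == .data$start[1]]),
      .groups = "drop"
    )

  results <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    wins <- excise_precursor_windows(index, lc$chrom, lc$mature_start,
                                     lc$mature_end, lc$strand, params)
    if (!nrow(wins)) next
    energies <- vapply(wins$sequence, function(s) {
      tryCatch(fold_sequence(s)$energy, error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE)
    if (all(is.na(energies))) next
    best <- which.min(energies)
    # context is judged at the expressed mature locus; the scanned window
    # may graze neighbouring annotation without changing where the miRNA is
    context <- locus_context(lc$chrom, lc$mature_start, lc$mature_end,
                             features)
    ev <- evaluate_candidate(
      wins$sequence[best], wins$mature_offset[best],
      lc$mature_end - lc$mature_start, lc$cut_depth, lc$copy_number,
      context, params, seed = seed + i
    )
    results[[i]] <- dplyr::bind_cols(
      tibble::tibble(locus_id = sprintf("locus_%03d", i),
                     chrom = lc$chrom, strand = lc$strand,
                     precursor_start = wins$win_start[best],
                     precursor_end = wins$win_end[best],
                     mature_start = lc$mature_start,
                     mature_end = lc$mature_end,
                     context = context, total_reads = lc$total_reads,
                     cut_depth = lc$cut_depth,
                     copy_number = lc$copy_number),
      ev
    )
  }
  evaluated <- dplyr::bind_rows(results)
  if (!nrow(evaluated)) {
    empty <- tibble::tibble(locus_id = character(0))
    return(list(candidates = empty, rejections = empty))
  }

  accepted <- filter(evaluated, .data$accepted)
  # deduplicate overlapping accepted loci
  if (nrow(accepted) > 1) {
    accepted <- arrange(accepted, .data$chrom,
                        desc(.data$total_reads), .data$precursor_start)
    keep <- rep(TRUE, nrow(accepted))
    for (i in seq_len(nrow(accepted))) {
      if (!keep[i]) next
      j <- which(keep & seq_len(nrow(accepted)) > i &
                   accepted$chrom == accepted$chrom[i] &
                   accepted$precursor_start < accepted$precursor_end[i] &
                   accepted$precursor_end > accepted$precursor_start[i])
      keep[j] <- FALSE
    }
    accepted <- accepted[keep, ]
  }
  list(
    candidates = arrange(accepted, .data$chrom, .data$precursor_start),
    rejections = filter(evaluated, !.data$accepted)
  )
}

#' Write accepted candidates as precursor FASTA and GFF3
#'
#' @param candidates Accepted candidate tibble from
#'   [call_novel_candidates()].
#' @param fasta_path,gff_path Output paths; either may be `NULL`.
#' @param index Genome index (needed for precursor sequences in FASTA).
#' @return Invisibly, the list of written paths.
#' @export
write_candidates <- function(candidates, fasta_path = NULL, gff_path = NULL,
                             index = NULL) {
  if (!is.null(fasta_path) && nrow(candidates)) {
    stopifnot(!is.null(index))
    seqs <- substring(
      as.character(index$seqs[[candidates$chrom[1]]]),
      candidates$precursor_start + 1L, candidates$precursor_end
    )
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(seqs, candidates$locus_id)),
      fasta_path
    )
  }
  if (!is.null(gff_path)) {
    gff <- sprintf(
      "%s\tlactomir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
      candidates$chrom, candidates$precursor_start + 1L,
      candidates$precursor_end, candidates$strand, candidates$locus_id
    )
    writeLines(c("##gff-version 3", gff), gff_path)
  }
  invisible(list(fasta = fasta_path, gff = gff_path))
}
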