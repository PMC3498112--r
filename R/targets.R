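#' Configuration of the miRNA target-site rules
#'
#' Positional complementarity rules evaluated over the full-length, ungapped
#' miRNA/site duplex (positions numbered 1..L from the miRNA 5' end):
#' (a) total mismatch score at most `max_mismatch_total`, with G:U wobbles
#' counting 0.5; (b) no run of more than two adjacent mismatches anywhere;
#' (c) no adjacent mismatches in positions 2-12; (d) no mismatches in
#' positions 10-11; (e) mismatch score over positions 1-12 at most
#' `max_mm_5p`; (f) duplex folding energy at least `mfe_ratio_min` of the
#' energy against the perfect complement.  In strict mode (the default) the
#' total mismatch score must additionally not exceed `strict_max_mismatch`.
#'
#' @param max_mismatch_total Rule (a) cap (default 4).
#' @param no_mm_window Positions with no mismatches allowed (default 10:11).
#' @param no_adjacent_mm_window Window for rule (c) (default 2:12).
#' @param max_mm_5p Cap on the 5' window mismatch score (default 2.5 over
#'   positions 1-12).
#' @param mm_5p_window Window for rule (e) (default 1:12).
#' @param mfe_ratio_min Minimum duplex/perfect energy ratio (default 0.75).
#' @param strict Apply the strict total-mismatch override (default TRUE).
#' @param strict_max_mismatch Strict-mode cap (default 2).
#' @param gu_adjacent Whether two adjacent G:U wobbles count as adjacent
#'   mismatches (default FALSE: a pair of adjacent non-Watson-Crick
#'   positions violates the adjacency rules only if at least one of the two
#'   is a true mismatch).
#' @return An object of class `target_rule_config`.
#' @export
target_rule_config <- function(max_mismatch_total = 4,
                               no_mm_window = 10:11,
                               no_adjacent_mm_window = 2:12,
                               max_mm_5p = 2.5,
                               mm_5p_window = 1:12,
                               mfe_ratio_min = 0.75,
                               strict = TRUE,
                               strict_max_mismatch = 2,
                               gu_adjacent = FALSE) {
  structure(as.list(environment()), class = "target_rule_config")
}

#' Score a miRNA/site duplex position by position
#'
#' The site is the target-strand sequence 5' to 3' and must have the same
#' length as the miRNA; position `i` of the miRNA (1 = 5' end) pairs with
#' site position `L - i + 1` (antiparallel).  Each position is classed
#' `"WC"` (Watson-Crick), `"GU"` (wobble, mismatch weight 0.5) or `"MM"`
#' (mismatch, weight 1).
#'
#' @param mirna,site Equal-length RNA/DNA strings, both 5' to 3'.
#' @return An object of class `duplex_score`: list with `states` (character
#'   vector over miRNA positions), `mismatch_score`, `length`.
#' @export
#' @examples
#' score_duplex("ACGUACGUACGUACGUACGUA", revcomp("ACGUACGUACGUACGUACGUA"))
score_duplex <- function(mirna, site) {
  m <- encode_rna(mirna)
  s <- encode_rna(site)
  if (length(m) != length(s)) {
    stop("site length (", length(s), ") must equal miRNA length (",
         length(m), ")")
  }
  t <- rev(s)  # antiparallel partner of each miRNA position
  wc <- (m == 0L & t == 3L) | (m == 3L & t == 0L) |
    (m == 1L & t == 2L) | (m == 2L & t == 1L)
  gu <- (m == 2L & t == 3L) | (m == 3L & t == 2L)
  states <- ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
  structure(
    list(states = states,
         mismatch_score = sum(states == "MM") + 0.5 * sum(states == "GU"),
         length = length(m)),
    class = "duplex_score"
  )
}

#' @export
print.duplex_score <- function(x, ...) {
  cat(paste(substr(x$states, 1, 1), collapse = ""),
      sprintf(" (mismatch score %.1f)", x$mismatch_score), "\n", sep = "")
  invisible(x)
}

# adjacent-mismatch predicate between consecutive positions i, i+1
adjacent_pairs <- function(states, gu_adjacent) {
  n <- length(states)
  if (n < 2) return(logical(0))
  a <- states[-n]
  b <- states[-1]
  both_non_wc <- a != "WC" & b != "WC"
  if (gu_adjacent) both_non_wc
  else both_non_wc & (a == "MM" | b == "MM")
}

#' Apply the target rules to a scored duplex
#'
#' @param score A [score_duplex()] object.
#' @param duplex_energy Energy of the miRNA/site duplex (kcal/mol).
#' @param perfect_energy Energy of the miRNA against its perfect complement.
#' @param config A [target_rule_config()].
#' @return A one-row tibble with the per-rule verdicts (`rule_a` ...
#'   `rule_f`, `rule_strict`), `mismatch_score`, `mfe_ratio`, and the
#'   conjunction `accepted`.
#' @export
apply_target_rules <- function(score, duplex_energy, perfect_energy,
                               config = target_rule_config()) {
  stopifnot(inherits(score, "duplex_score"))
  st <- score$states
  L <- score$length
  weight <- c(WC = 0, GU = 0.5, MM = 1)[st]
  adj <- adjacent_pairs(st, config$gu_adjacent)

  rule_a <- score$mismatch_score <= config$max_mismatch_total
  # (b): no more than two adjacent mismatches = no three consecutive
  # mismatch positions (two consecutive adjacent pairs)
  rule_b <- !any(adj[-length(adj)] & adj[-1])
  win_c <- intersect(config$no_adjacent_mm_window, seq_len(L))
  idx_c <- win_c[win_c < max(win_c)]  # pairs (i, i+1) fully inside window
  rule_c <- !any(adj[idx_c])
  win_d <- intersect(config$no_mm_window, seq_len(L))
  rule_d <- all(st[win_d] == "WC")
  win_e <- intersect(config$mm_5p_window, seq_len(L))
  rule_e <- sum(weight[win_e]) <= config$max_mm_5p
  mfe_ratio <- if (perfect_energy < 0) duplex_energy / perfect_energy else NA_real_
  rule_f <- !is.na(mfe_ratio) && mfe_ratio >= config$mfe_ratio_min
  rule_strict <- !config$strict ||
    score$mismatch_score <= config$strict_max_mismatch

  tibble::tibble(
    mismatch_score = score$mismatch_score,
    duplex_energy = duplex_energy,
    perfect_energy = perfect_energy,
    mfe_ratio = mfe_ratio,
    rule_a = rule_a, rule_b = rule_b, rule_c = rule_c, rule_d = rule_d,
    rule_e = rule_e, rule_f = rule_f, rule_strict = rule_strict,
    accepted = rule_a && rule_b && rule_c && rule_d && rule_e && rule_f &&
      rule_strict
  )
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every ungapped window of each transcript against each miRNA and
#' returns the sites passing all rules, ordered by miRNA, transcript and
#' position.  The default scan is exhaustive; `seed_length > 0` enables a
#' complementarity k-mer prefilter (windows must contain the exact reverse
#' complement of the miRNA 5' seed), which is faster but can miss sites
#' whose allowed mismatches fall inside the seed.
#'
#' @param mirnas Named character vector of mature miRNA sequences, or a
#'   tibble with `mirna_id` and `sequence`.
#' @param transcripts Named character vector of transcript sequences (or
#'   `DNAStringSet`).
#' @param config A [target_rule_config()].
#' @param energy_table Stacking table for duplex energies.
#' @param seed_length 0 (default) for exhaustive scanning, otherwise the
#'   length of the 5'-seed prefilter k-mer.
#' @return Tibble of accepted hits: `mirna_id`, `transcript_id`,
#'   `site_start` (0-based), `site_end` (half-open), `mismatch_score`,
#'   `duplex_energy`, `perfect_energy`, `mfe_ratio` and per-rule verdicts.
#' @export
scan_transcripts <- function(mirnas, transcripts,
                             config = target_rule_config(),
                             energy_table = default_stack_energies(),
                             seed_length = 0L) {
  if (is.data.frame(mirnas)) {
    mirnas <- setNames(mirnas$sequence, mirnas$mirna_id)
  }
  if (inherits(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  if (!length(transcripts)) stop("transcripts must be non-empty")
  if (!length(mirnas)) {
    return(empty_target_hits())
  }
  if (is.null(names(mirnas))) {
    names(mirnas) <- sprintf("mirna_%03d", seq_along(mirnas))
  }

  rows <- list()
  for (mi in seq_along(mirnas)) {
    mseq <- mirnas[[mi]]
    L <- nchar(mseq)
    perfect <- fold_duplex(mseq, revcomp(mseq), energy_table)$energy
    m_states_fun <- function(window) score_duplex(mseq, window)
    seed_rc <- if (seed_length > 0) {
      revcomp(substr(mseq, 1L, seed_length))
    } else NULL
    for (ti in seq_along(transcripts)) {
      tx <- toupper(gsub("U", "T", transcripts[[ti]]))
      if (nchar(tx) < L) next
      starts <- seq_len(nchar(tx) - L + 1L)
      if (!is.null(seed_rc)) {
        # candidate windows must contain the seed's reverse complement at
        # the 3' end of the site (pairing the miRNA 5' seed)
        hits <- stringr::str_locate_all(tx, stringr::fixed(seed_rc))[[1]][, 1]
        if (!length(hits)) next
        starts <- unique(pmax(1L, pmin(hits - (L - seed_length),
                                       nchar(tx) - L + 1L)))
        starts <- sort(unlist(lapply(hits, function(h) {
          s <- (h + seed_length - L):h
          s[s >= 1 & s <= nchar(tx) - L + 1]
        })))
        starts <- unique(starts)
        if (!length(starts)) next
      }
      # vectorised mismatch-score prefilter: exact, not heuristic -- any
      # window above the rule (a)/strict cap is rejected by those rules
      tx_enc <- encode_rna(tx)
      m_enc <- encode_rna(mseq)
      wt <- matrix(1, 4, 4)
      wt[cbind(c(1, 4, 2, 3) , c(4, 1, 3, 2))] <- 0   # WC pairs
      wt[cbind(c(3, 4), c(4, 3))] <- 0.5              # G:U wobbles
      total_w <- numeric(length(starts))
      for (i in seq_len(L)) {
        partner <- tx_enc[starts + (L - i)]
        total_w <- total_w + wt[cbind(m_enc[i] + 1L, partner + 1L)]
      }
      cap <- min(config$max_mismatch_total,
                 if (config$strict) config$strict_max_mismatch else Inf)
      keep_idx <- which(total_w <= cap)
      starts <- starts[keep_idx]
      if (!length(starts)) next
      windows <- substring(tx, starts, starts + L - 1L)
      for (k in seq_along(windows)) {
        sc <- m_states_fun(windows[k])
        denergy <- fold_duplex(mseq, windows[k], energy_table)$energy
        verdict <- apply_target_rules(sc, denergy, perfect, config)
        if (verdict$accepted) {
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(mirna_id = names(mirnas)[mi],
                           transcript_id = names(transcripts)[ti],
                           site_start = starts[k] - 1L,
                           site_end = starts[k] - 1L + L),
            verdict
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_target_hits())
  arrange(out, .data$mirna_id, .data$transcript_id, .data$site_start)
}

empty_target_hits <- function() {
  tibble::tibble(
    mirna_id = character(0), transcript_id = character(0),
    site_start = integer(0), site_end = integer(0),
    mismatch_score = numeric(0), duplex_energy = numeric(0),
    perfect_energy = numeric(0), mfe_ratio = numeric(0),
    rule_a = logical(0), rule_b = logical(0), rule_c = logical(0),
    rule_d = logical(0), rule_e = logical(0), rule_f = logical(0),
    rule_strict = logical(0), accepted = logical(0)
  )
}
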