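#' Configuration for raw read cleaning
#'
#' Parameters of the six cleaning filters, applied in a fixed order so every
#' removed read is attributed to exactly one filter: (a) low quality, (b) no
#' 3' adapter, (c) 5' adapter contaminant, (d) no inserted tag, (e) poly-A,
#' (f) length outside the retained range.
#'
#' @param adapter_3p,adapter_5p Adapter sequences (3' adapter must be
#'   non-empty).
#' @param min_len,max_len Retained insert length range in nt (default 18-30).
#' @param polya_min_fraction Minimum fraction of A in a trimmed insert for
#'   the poly-A filter (default 0.8).
#' @param quality_threshold Minimum mean Phred score (default 20).
#' @param min_adapter_overlap Minimum exact 3' adapter overlap in nt
#'   (default 6); matching is exact-prefix with no mismatches.
#' @return An object of class `clean_filter_config`.
#' @export
clean_filter_config <- function(adapter_3p,
                                adapter_5p = "",
                                min_len = 18L, max_len = 30L,
                                polya_min_fraction = 0.8,
                                quality_threshold = 20,
                                min_adapter_overlap = 6L) {
  stopifnot(nchar(adapter_3p) >= min_adapter_overlap, min_len <= max_len,
            polya_min_fraction >= 0, quality_threshold >= 0,
            min_adapter_overlap >= 1)
  structure(list(adapter_3p = toupper(adapter_3p),
                 adapter_5p = toupper(adapter_5p),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 polya_min_fraction = polya_min_fraction,
                 quality_threshold = quality_threshold,
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "clean_filter_config")
}

# mean Phred+33 quality per read, vectorised over all reads at once
mean_phred <- function(quality) {
  widths <- nchar(quality)
  if (sum(widths) == 0) return(rep(NA_real_, length(quality)))
  bytes <- as.integer(charToRaw(paste(quality, collapse = ""))) - 33L
  grp <- rep.int(seq_along(quality), widths)
  as.numeric(rowsum(bytes, grp)) / widths
}

# locate the 3' adapter: first occurrence of the seed whose extension matches
# the adapter prefix up to the read end; NA if none validates
locate_adapter <- function(sequence, adapter, min_overlap) {
  seed <- substr(adapter, 1L, min_overlap)
  hits <- stringr::str_locate_all(sequence, stringr::fixed(seed))
  alen <- nchar(adapter)
  vapply(seq_along(sequence), function(i) {
    starts <- hits[[i]][, 1]
    if (!length(starts)) return(NA_integer_)
    s <- sequence[i]
    L <- nchar(s)
    for (p in starts) {
      ov <- min(alen, L - p + 1L)
      if (substr(s, p, p + ov - 1L) == substr(adapter, 1L, ov)) {
        return(as.integer(p))
      }
    }
    NA_integer_
  }, integer(1))
}

#' Clean raw reads with the six-filter pipeline
#'
#' Applies, in order: (a) mean Phred below `quality_threshold`; (b) no 3'
#' adapter (exact seed-and-extend match of at least `min_adapter_overlap`
#' nt); (c) trimmed insert starting with the 3'-terminal bases of the 5'
#' adapter (contaminant); (d) empty insert (adapter at position 1); (e)
#' poly-A insert (fraction of A at least `polya_min_fraction`); (f) insert
#' length outside `[min_len, max_len]`.  Each read receives exactly one
#' status, so the statuses partition the input.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`; any
#'   further columns (e.g. `library`) are preserved.
#' @param config A [clean_filter_config()].
#' @return The input tibble with two added columns: `insert` (the trimmed
#'   sequence, `NA` for removed reads) and `status` (`"clean"`,
#'   `"low_quality"`, `"no_adapter3"`, `"adapter5_contaminant"`,
#'   `"no_insert"`, `"poly_a"` or `"length_out_of_range"`).
#' @export
#' @examples
#' cfg <- clean_filter_config("TCGTATGCCGTCTTCTGCTTG")
#' reads <- tibble::tibble(read_id = "r1",
#'   sequence = paste0("ACGTACGTACGTACGTACGTAC", "TCGTATGCCGTCTTCTGCTTG"),
#'   quality = strrep("I", 43))
#' clean_reads(reads, cfg)$insert
clean_reads <- function(reads, config) {
  stopifnot(inherits(config, "clean_filter_config"))
  required <- c("read_id", "sequence", "quality")
  if (!all(required %in% names(reads))) {
    stop("reads must have columns read_id, sequence, quality")
  }
  n <- nrow(reads)
  if (n == 0) {
    return(mutate(reads, insert = character(0), status = character(0)))
  }
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    stop("malformed read record at index ", bad[1],
         ": sequence and quality lengths differ")
  }
  seqs <- toupper(reads$sequence)
  status <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)

  # (a) low quality
  low <- mean_phred(reads$quality) < config$quality_threshold
  status[low] <- "low_quality"

  # (b) 3' adapter
  todo <- is.na(status)
  pos <- rep(NA_integer_, n)
  pos[todo] <- locate_adapter(seqs[todo], config$adapter_3p,
                              config$min_adapter_overlap)
  status[todo & is.na(pos)] <- "no_adapter3"

  todo <- is.na(status)
  trimmed <- substr(seqs, 1L, pmax(pos - 1L, 0L))

  # (c) 5' adapter contaminant
  if (nzchar(config$adapter_5p)) {
    sfx <- stringr::str_sub(config$adapter_5p, -config$min_adapter_overlap)
    contam <- todo & startsWith(trimmed, sfx) & nchar(trimmed) > 0
    status[contam] <- "adapter5_contaminant"
    todo <- is.na(status)
  }

  # (d) no inserted tag
  status[todo & nchar(trimmed) == 0] <- "no_insert"
  todo <- is.na(status)

  # (e) poly-A
  n_a <- stringr::str_count(trimmed, stringr::fixed("A"))
  polya <- todo & (n_a / pmax(nchar(trimmed), 1L)) >= config$polya_min_fraction
  status[polya] <- "poly_a"
  todo <- is.na(status)

  # (f) length
  len <- nchar(trimmed)
  status[todo & (len < config$min_len | len > config$max_len)] <-
    "length_out_of_range"
  todo <- is.na(status)

  status[todo] <- "clean"
  insert[status == "clean"] <- trimmed[status == "clean"]
  mutate(reads, insert = insert, status = status)
}

filter_levels <- c("low_quality", "no_adapter3", "adapter5_contaminant",
                   "no_insert", "poly_a", "length_out_of_range")

#' Per-filter removal counts from cleaned reads
#'
#' @param cleaned Output of [clean_reads()] (optionally grouped by a
#'   `library` column).
#' @return Tibble with `status` and `n`, one row per filter plus `"clean"`,
#'   zero-filled.
#' @export
filter_counts <- function(cleaned) {
  lv <- c("clean", filter_levels)
  grp <- intersect("library", names(cleaned))
  cleaned %>%
    mutate(status = factor(.data$status, levels = lv)) %>%
    count(across(all_of(grp)), .data$status, .drop = FALSE, name = "n") %>%
    mutate(status = as.character(.data$status))
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' Groups identical insert sequences and counts them per library.  The
#' output is sorted by total abundance (descending) then sequence, so the
#' table does not depend on input order.
#'
#' @param cleaned Output of [clean_reads()] with a `library` column holding
#'   values `"peak"` and `"late"`, or any tibble with `library` and `insert`.
#' @return Tibble with `sequence`, `count_peak`, `count_late` (missing
#'   libraries yield zero columns).
#' @export
collapse_tags <- function(cleaned) {
  tags <- cleaned %>%
    filter(.data$status == "clean") %>%
    count(.data$library, sequence = .data$insert, name = "n") %>%
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L, names_prefix = "count_")
  for (col in c("count_peak", "count_late")) {
    if (!col %in% names(tags)) tags[[col]] <- 0L
  }
  tags %>%
    select("sequence", "count_peak", "count_late") %>%
    arrange(desc(.data$count_peak + .data$count_late), .data$sequence)
}

#' Summarise one cleaned library
#'
#' @param cleaned Output of [clean_reads()] for a single library.
#' @return A list with `raw_reads`, `clean_reads`, `unique_tags`, `removals`
#'   (tibble status/n) and `length_histogram` (tibble length/n over clean
#'   inserts).  `raw_reads` always equals `clean_reads` plus the removals.
#' @export
library_summary <- function(cleaned) {
  clean <- filter(cleaned, .data$status == "clean")
  removals <- cleaned %>%
    filter(.data$status != "clean") %>%
    mutate(status = factor(.data$status, levels = filter_levels)) %>%
    count(.data$status, .drop = FALSE, name = "n") %>%
    mutate(status = as.character(.data$status))
  hist <- clean %>%
    count(length = nchar(.data$insert), name = "n") %>%
    arrange(.data$length)
  list(
    raw_reads = nrow(cleaned),
    clean_reads = nrow(clean),
    unique_tags = dplyr::n_distinct(clean$insert),
    removals = removals,
    length_histogram = hist
  )
}

#' Combined two-library sequencing totals
#'
#' The inclusion-exclusion arithmetic of a two-library summary table: the
#' total unique tag count is `unique_peak + unique_late - common_unique`, the
#' grand read total is the sum of the per-library clean totals, the read
#' total over shared tags is the grand total minus the library-specific read
#' totals, and mapped fractions are percentages of clean reads (two
#' decimals).
#'
#' @param unique_peak,unique_late Unique tag counts per library.
#' @param common_unique Tags present in both libraries.
#' @param reads_peak,reads_late Clean read totals per library.
#' @param specific_reads_peak,specific_reads_late Read totals over
#'   library-specific tags (optional).
#' @param mapped_peak,mapped_late Genome-mapped read counts (optional).
#' @return A one-row tibble with `total_unique`, `total_reads`,
#'   `common_reads`, `pct_mapped_peak`, `pct_mapped_late`.
#' @export
#' @examples
#' two_library_totals(466727, 259250, 66859, 19044002, 7385833)$total_unique
two_library_totals <- function(unique_peak, unique_late, common_unique,
                               reads_peak, reads_late,
                               specific_reads_peak = NA_real_,
                               specific_reads_late = NA_real_,
                               mapped_peak = NA_real_,
                               mapped_late = NA_real_) {
  tibble::tibble(
    total_unique = unique_peak + unique_late - common_unique,
    total_reads = reads_peak + reads_late,
    common_reads = .data$total_reads - specific_reads_peak - specific_reads_late,
    pct_mapped_peak = round(100 * mapped_peak / reads_peak, 2),
    pct_mapped_late = round(100 * mapped_late / reads_late, 2)
  )
}

#' Summary of a tag table across both libraries
#'
#' @param tags Tag table from [collapse_tags()].
#' @param mapped Optional tibble of genome-mapped tags (`sequence` column)
#'   used for the mapped percentages.
#' @return A one-row tibble as [two_library_totals()], plus the per-library
#'   unique and read totals.
#' @export
tag_table_summary <- function(tags, mapped = NULL) {
  in_peak <- tags$count_peak > 0
  in_late <- tags$count_late > 0
  specific_peak <- sum(tags$count_peak[in_peak & !in_late])
  specific_late <- sum(tags$count_late[in_late & !in_peak])
  mapped_peak <- NA_real_
  mapped_late <- NA_real_
  if (!is.null(mapped)) {
    hit <- tags$sequence %in% mapped$sequence
    mapped_peak <- sum(tags$count_peak[hit])
    mapped_late <- sum(tags$count_late[hit])
  }
  base <- two_library_totals(
    unique_peak = sum(in_peak), unique_late = sum(in_late),
    common_unique = sum(in_peak & in_late),
    reads_peak = sum(tags$count_peak), reads_late = sum(tags$count_late),
    specific_reads_peak = specific_peak, specific_reads_late = specific_late,
    mapped_peak = mapped_peak, mapped_late = mapped_late
  )
  mutate(base,
         unique_peak = sum(in_peak), unique_late = sum(in_late),
         common_unique = sum(in_peak & in_late),
         reads_peak = sum(tags$count_peak), reads_late = sum(tags$count_late))
}
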