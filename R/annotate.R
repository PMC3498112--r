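#' Build an exact-match genome index
#'
#' Wraps the genome for exact substring lookup on both strands.  Only
#' perfect matches are ever reported, so no gapped or mismatch-tolerant
#' alignment is involved.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a `toy_genome`.
#' @return An object of class `genome_index`.
#' @export
build_genome_index <- function(genome) {
  if (inherits(genome, "toy_genome")) {
    genome <- setNames(genome$genome, genome$chrom)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome)) || anyNA(names(genome)) ||
      any(duplicated(names(genome)))) {
    stop("genome sequences must have unique names")
  }
  if (!length(genome) || any(nchar(genome) == 0)) {
    stop("genome must be non-empty")
  }
  structure(
    list(seqs = Biostrings::DNAStringSet(genome)),
    class = "genome_index"
  )
}

#' Map tags to the genome by perfect match
#'
#' Reports every exact occurrence of each tag on either strand, with 0-based
#' half-open coordinates on the forward strand, and each tag's total genomic
#' copy number.
#'
#' @param index A [build_genome_index()] object.
#' @param tags Character vector of tag sequences (T and U equivalent).
#' @return Tibble with `sequence`, `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`, `copy_number`; tags with no perfect match are
#'   absent.
#' @export
map_tags <- function(index, tags) {
  stopifnot(inherits(index, "genome_index"))
  tags <- unique(toupper(gsub("U", "T", tags)))
  if (!length(tags)) {
    return(tibble::tibble(sequence = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), copy_number = integer(0)))
  }
  chroms <- names(index$seqs)
  rows <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    tag <- tags[i]
    pat <- Biostrings::DNAString(tag)
    rc <- Biostrings::reverseComplement(pat)
    hits <- list()
    for (ch in chroms) {
      fwd <- Biostrings::matchPattern(pat, index$seqs[[ch]])
      if (length(fwd)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          chrom = ch, start = BiocGenerics::start(fwd) - 1L,
          end = BiocGenerics::end(fwd), strand = "+")
      }
      rev <- Biostrings::matchPattern(rc, index$seqs[[ch]])
      if (length(rev)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          chrom = ch, start = BiocGenerics::start(rev) - 1L,
          end = BiocGenerics::end(rev), strand = "-")
      }
    }
    if (length(hits)) {
      h <- dplyr::bind_rows(hits)
      rows[[i]] <- mutate(h, sequence = tag, copy_number = nrow(h))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(sequence = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), copy_number = integer(0)))
  }
  out %>%
    select("sequence", "chrom", "start", "end", "strand", "copy_number") %>%
    arrange(.data$sequence, .data$chrom, .data$start)
}

#' Match tags against a catalog of known mature miRNAs
#'
#' Finds, for each tag, the best ungapped alignment of the tag within each
#' catalog mature sequence extended by `flank` nt on each side, counting
#' substitutions only.  A tag is matched to the catalog entry with the
#' fewest mismatches (ties broken by catalog order, then by the 5'-most
#' offset), provided that the best mismatch count does not exceed
#' `max_mismatch`.
#'
#' @param tags Character vector of tag sequences.
#' @param catalog Named character vector of mature miRNA sequences
#'   (18-26 nt).
#' @param max_mismatch Maximum substitutions (default 3).
#' @param flank Extension of each catalog entry, in nt (default 2); tags may
#'   overhang the mature by up to this much.
#' @return Tibble with `sequence`, `mirna_id`, `mismatches`, `offset` (0-based
#'   offset of the tag within the flank-extended mature); unmatched tags are
#'   absent.
#' @export
match_known_mirnas <- function(tags, catalog, max_mismatch = 3L, flank = 2L) {
  if (!length(tags) || !length(catalog)) {
    return(tibble::tibble(sequence = character(0), mirna_id = character(0),
                          mismatches = integer(0), offset = integer(0)))
  }
  if (is.null(names(catalog))) {
    names(catalog) <- sprintf("catalog_%03d", seq_along(catalog))
  }
  norm <- function(x) toupper(gsub("U", "T", x))
  tags_n <- norm(tags)
  cat_n <- norm(catalog)
  cat_ext <- paste0(strrep("N", flank), cat_n, strrep("N", flank))
  cat_chars <- strsplit(cat_ext, "", fixed = TRUE)

  rows <- vector("list", length(tags))
  for (i in seq_along(tags_n)) {
    tchars <- strsplit(tags_n[i], "", fixed = TRUE)[[1]]
    tl <- length(tchars)
    best <- list(mm = Inf, id = NA_character_, off = NA_integer_)
    for (ci in seq_along(cat_chars)) {
      cc <- cat_chars[[ci]]
      if (tl > length(cc)) next
      for (off in 0:(length(cc) - tl)) {
        win <- cc[(off + 1L):(off + tl)]
        mm <- sum(win != tchars)  # N flanks never match: overhang costs 1
        if (mm < best$mm) {
          best <- list(mm = mm, id = names(catalog)[ci], off = off)
        }
      }
    }
    if (is.finite(best$mm) && best$mm <= max_mismatch) {
      rows[[i]] <- tibble::tibble(sequence = tags[i], mirna_id = best$id,
                                  mismatches = as.integer(best$mm),
                                  offset = best$off)
    }
  }
  dplyr::bind_rows(rows)
}

category_levels <- c("rRNA_etc_genbank", "rRNA_etc_rfam", "known_miRNA",
                     "repeat", "exon", "intron", "unannotated")

# does the tag occur as an exact substring (either strand) of any catalog
# sequence?
matches_catalog <- function(tags, catalog) {
  if (!length(catalog)) return(rep(FALSE, length(tags)))
  subject <- Biostrings::DNAStringSet(toupper(gsub("U", "T", unname(catalog))))
  vapply(tags, function(tag) {
    pat <- Biostrings::DNAString(toupper(gsub("U", "T", tag)))
    hits <- sum(Biostrings::vcountPattern(pat, subject)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    subject))
    hits > 0
  }, logical(1), USE.NAMES = FALSE)
}

# tags whose genome hits overlap intervals of one type by >= 1 nt
overlaps_feature <- function(tags, hits, features, type) {
  fx <- filter(features, .data$type == .env$type)
  if (!nrow(fx) || !nrow(hits)) return(rep(FALSE, length(tags)))
  out <- rep(FALSE, length(tags))
  for (ch in unique(fx$chrom)) {
    f_ir <- IRanges::IRanges(start = fx$start[fx$chrom == ch] + 1L,
                             end = fx$end[fx$chrom == ch])
    h <- filter(hits, .data$chrom == ch)
    if (!nrow(h)) next
    h_ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    ov <- IRanges::countOverlaps(h_ir, f_ir, minoverlap = 1L) > 0
    out[match(h$sequence[ov], tags)] <- TRUE
  }
  out
}

#' Assign each tag one annotation category by the priority rule
#'
#' Applies the fixed priority order `rRNA etc. (GenBank > Rfam) > known
#' miRNA > repeat > exon > intron`; tags matching nothing are
#' `unannotated`.  Catalog matching (exact substring for the ncRNA catalogs,
#' up to `max_mismatch` substitutions for known mature miRNAs) precedes
#' genomic-interval overlap, and an interval category requires a perfect
#' genome hit overlapping an interval of that type by at least 1 nt on
#' either strand.
#'
#' @param tags Tag table ([collapse_tags()] output) or a character vector of
#'   sequences.
#' @param catalogs List with character-vector elements `genbank`, `rfam`,
#'   `known_mirna` (any may be empty or missing).
#' @param hits Genome hits from [map_tags()].
#' @param features Feature interval tibble (`chrom`, `start`, `end`, `type`
#'   with types including `repeat`, `exon`, `intron`).
#' @param max_mismatch Mismatch allowance for known-miRNA matching
#'   (default 3).
#' @return Tibble with `sequence` and `category` (one category per tag).
#' @export
classify_tags <- function(tags, catalogs = list(), hits = NULL,
                          features = NULL, max_mismatch = 3L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  n <- length(seqs)
  category <- rep(NA_character_, n)
  get_cat <- function(nm) {
    if (!is.null(catalogs[[nm]])) catalogs[[nm]] else character(0)
  }
  assign_cat <- function(mask, label) {
    category[is.na(category) & mask] <<- label
  }
  assign_cat(matches_catalog(seqs, get_cat("genbank")), "rRNA_etc_genbank")
  assign_cat(matches_catalog(seqs, get_cat("rfam")), "rRNA_etc_rfam")
  known <- get_cat("known_mirna")
  if (length(known)) {
    km <- match_known_mirnas(seqs, known, max_mismatch = max_mismatch)
    assign_cat(seqs %in% km$sequence, "known_miRNA")
  }
  if (!is.null(hits) && !is.null(features)) {
    hits_norm <- mutate(hits, sequence = toupper(gsub("U", "T", .data$sequence)))
    seqs_norm <- toupper(gsub("U", "T", seqs))
    for (ft in c("repeat", "exon", "intron")) {
      assign_cat(overlaps_feature(seqs_norm, hits_norm, features, ft), ft)
    }
  }
  category[is.na(category)] <- "unannotated"
  tibble::tibble(sequence = seqs,
                 category = factor(category, levels = category_levels))
}
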