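#' Specification for a toy genome with planted small-RNA features
#'
#' Describes the synthetic genomic context the generator builds: miRNA
#' hairpin precursors (a perfect stem, a short loop, and the reverse
#' complement of the stem), non-folding expressed decoy loci, ncRNA decoys
#' with an accompanying catalog, repeat elements, and exon/intron gene
#' models.  All intervals are 0-based half-open on a single toy chromosome.
#'
#' @param seed Integer seed; the seed fully determines the genome.
#' @param genome_length Genome length in nt.
#' @param n_mirna_hairpins Number of planted hairpin precursors.
#' @param n_decoy_ncrna Number of ncRNA decoy sequences (half emitted in the
#'   GenBank-style catalog, half in the Rfam-style catalog).
#' @param n_repeat_elements Number of inserted copies of one repeat unit.
#' @param n_expressed_decoys Number of expressed non-folding decoy loci
#'   (dinucleotide-shuffled hairpins, rejection-sampled until the locus folds
#'   above `decoy_max_energy`).
#' @param exon_fraction,intron_fraction Approximate fractions of the genome
#'   covered by exons and introns.
#' @param hairpin_stem,hairpin_loop Length ranges (nt) for the hairpin stem
#'   and loop.
#' @param mature_length Length range (nt) for the planted mature sequences.
#' @param decoy_max_energy Decoy loci must fold above this energy (kcal/mol).
#' @param chrom Chromosome name.
#' @return An object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(seed = 1L,
                            genome_length = 100000L,
                            n_mirna_hairpins = 20L,
                            n_decoy_ncrna = 10L,
                            n_repeat_elements = 4L,
                            n_expressed_decoys = 20L,
                            exon_fraction = 0.10,
                            intron_fraction = 0.20,
                            hairpin_stem = c(22L, 28L),
                            hairpin_loop = c(8L, 12L),
                            mature_length = c(20L, 24L),
                            decoy_max_energy = -18,
                            chrom = "toy_1") {
  stopifnot(genome_length > 0, hairpin_stem[1] <= hairpin_stem[2],
            hairpin_loop[1] <= hairpin_loop[2],
            mature_length[1] <= mature_length[2],
            exon_fraction + intron_fraction < 1)
  structure(as.list(environment()), class = "toy_genome_spec")
}

# sample n integers uniformly from [lo, hi], safe for degenerate ranges
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# place n features of the given widths into free space, uniformly at random,
# without overlap; `occupied` is a two-column matrix of 0-based [start, end)
place_features <- function(widths, genome_length, occupied,
                           max_attempts = 200L) {
  starts <- integer(0)
  occ <- occupied
  for (w in widths) {
    if (w > genome_length) {
      stop("infeasible packing: could not place a feature of width ", w,
           " in a genome of length ", genome_length)
    }
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- sample.int(genome_length - w + 1L, 1L) - 1L
      if (nrow(occ) == 0 || all(s + w <= occ[, 1] | s >= occ[, 2])) {
        occ <- rbind(occ, c(s, s + w))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible packing: could not place a feature of width ", w,
           " in a genome of length ", genome_length)
    }
  }
  list(starts = starts, occupied = occ)
}

#' Generate a toy genome with planted miRNA hairpins and decoy features
#'
#' Builds a random backbone sequence and plants, without overlap: gene models
#' (exon/intron/exon blocks), hairpin precursors constructed as
#' stem + loop + reverse-complement(stem) so that they satisfy the discovery
#' criteria by construction, expressed decoy loci that provably do not fold,
#' ncRNA decoys (returned as annotation catalogs), and tandem copies of a
#' repeat unit.  Deterministic given the spec's seed.
#'
#' @param spec A [toy_genome_spec()].
#' @return An object of class `toy_genome`: a list with `genome` (character
#'   string), `chrom`, `features` (tibble: chrom, start, end, strand, type,
#'   id; 0-based half-open), `mirnas` (per-hairpin truth: precursor/mature/
#'   star coordinates and sequences), `decoy_loci`, `catalogs` (named DNA
#'   character vectors `genbank` and `rfam`), and `mature_catalog` (the
#'   planted mature sequences, named).
#' @export
generate_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  withr::with_seed(as.integer(spec$seed), generate_toy_genome_impl(spec))
}

generate_toy_genome_impl <- function(spec) {
  L <- as.integer(spec$genome_length)
  genome <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
  occupied <- matrix(integer(0), ncol = 2)
  feats <- list()

  # gene models: exon - intron - exon blocks until coverage targets are met
  exon_len <- 400L
  target_exon <- spec$exon_fraction * L
  target_intron <- spec$intron_fraction * L
  n_genes <- max(0L, ceiling(target_exon / (2 * exon_len)))
  intron_len <- if (n_genes > 0) as.integer(round(target_intron / n_genes)) else 0L
  if (n_genes > 0) {
    gene_w <- 2L * exon_len + intron_len
    pl <- place_features(rep(gene_w, n_genes), L, occupied)
    occupied <- pl$occupied
    for (g in seq_len(n_genes)) {
      s <- pl$starts[g]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        start = c(s, s + exon_len, s + exon_len + intron_len),
        end = c(s + exon_len, s + exon_len + intron_len, s + gene_w),
        type = c("exon", "intron", "exon"),
        id = paste0("gene_", g, c("_exon1", "_intron1", "_exon2"))
      )
    }
  }

  # hairpin precursors
  mirnas <- NULL
  if (spec$n_mirna_hairpins > 0) {
    stems <- sample_range(spec$hairpin_stem[1], spec$hairpin_stem[2],
                          spec$n_mirna_hairpins)
    loops <- sample_range(spec$hairpin_loop[1], spec$hairpin_loop[2],
                          spec$n_mirna_hairpins)
    mlens <- sample_range(spec$mature_length[1], spec$mature_length[2],
                          spec$n_mirna_hairpins)
    widths <- 2L * stems + loops
    pl <- place_features(widths, L, occupied)
    occupied <- pl$occupied
    rows <- vector("list", spec$n_mirna_hairpins)
    for (i in seq_len(spec$n_mirna_hairpins)) {
      stem <- random_dna(stems[i])
      loop <- random_dna(loops[i])
      prec <- paste0(stem, loop, revcomp(stem))
      s <- pl$starts[i]
      w <- widths[i]
      genome[(s + 1L):(s + w)] <- strsplit(prec, "", fixed = TRUE)[[1]]
      mature <- substr(stem, 1L, mlens[i])
      fold <- fold_sequence(prec)
      geom <- hairpin_geometry(fold, 1L, mlens[i])
      rows[[i]] <- tibble::tibble(
        mirna_id = sprintf("mir_%02d", i),
        precursor_start = s, precursor_end = s + w,
        mature_start = s, mature_end = s + mlens[i],
        star_start = s + geom$star_start - 1L, star_end = s + geom$star_end,
        stem_len = stems[i], loop_len = loops[i],
        precursor_seq = prec, mature_seq = mature,
        star_seq = substr(prec, geom$star_start, geom$star_end),
        precursor_energy = fold$energy
      )
      feats[[length(feats) + 1L]] <- tibble::tibble(
        start = s, end = s + w, type = "hairpin",
        id = sprintf("mir_%02d", i)
      )
    }
    mirnas <- dplyr::bind_rows(rows)
  } else {
    mirnas <- tibble::tibble(
      mirna_id = character(0), precursor_start = integer(0),
      precursor_end = integer(0), mature_start = integer(0),
      mature_end = integer(0), star_start = integer(0), star_end = integer(0),
      stem_len = integer(0), loop_len = integer(0),
      precursor_seq = character(0), mature_seq = character(0),
      star_seq = character(0), precursor_energy = numeric(0)
    )
  }

  # expressed decoy loci: shuffled hairpins that provably do not fold
  decoys <- tibble::tibble(decoy_id = character(0), start = integer(0),
                           end = integer(0), tag_seq = character(0))
  if (spec$n_expressed_decoys > 0) {
    wdec <- 2L * spec$hairpin_stem[2] + spec$hairpin_loop[2]
    pl <- place_features(rep(wdec, spec$n_expressed_decoys), L, occupied)
    occupied <- pl$occupied
    rows <- vector("list", spec$n_expressed_decoys)
    for (i in seq_len(spec$n_expressed_decoys)) {
      # shuffle a hairpin until the result does not fold; a GC-rich source
      # hairpin may have no such shuffle, so redraw the source as needed
      seq <- NULL
      for (redraw in 1:100) {
        stem <- random_dna(spec$hairpin_stem[2])
        hp <- paste0(stem, random_dna(spec$hairpin_loop[2]), revcomp(stem))
        for (try in 1:40) {
          cand <- decode_dna(dinucleotide_shuffle(encode_rna(hp)))
          if (fold_sequence(cand)$energy > spec$decoy_max_energy) {
            seq <- cand
            break
          }
        }
        if (!is.null(seq)) break
      }
      if (is.null(seq)) stop("could not generate a non-folding decoy locus")
      s <- pl$starts[i]
      genome[(s + 1L):(s + wdec)] <- strsplit(seq, "", fixed = TRUE)[[1]]
      tag_start <- as.integer(floor((wdec - 22L) / 2))
      rows[[i]] <- tibble::tibble(
        decoy_id = sprintf("decoy_%02d", i),
        start = s, end = s + wdec,
        tag_seq = substr(seq, tag_start + 1L, tag_start + 22L)
      )
      feats[[length(feats) + 1L]] <- tibble::tibble(
        start = s, end = s + wdec, type = "decoy_locus",
        id = sprintf("decoy_%02d", i)
      )
    }
    decoys <- dplyr::bind_rows(rows)
  }

  # ncRNA decoys: catalogs only partially planted in the genome
  catalogs <- list(genbank = character(0), rfam = character(0))
  if (spec$n_decoy_ncrna > 0) {
    lens <- sample_range(80L, 150L, spec$n_decoy_ncrna)
    pl <- place_features(lens, L, occupied)
    occupied <- pl$occupied
    seqs <- character(spec$n_decoy_ncrna)
    for (i in seq_len(spec$n_decoy_ncrna)) {
      seqs[i] <- random_dna(lens[i])
      s <- pl$starts[i]
      genome[(s + 1L):(s + lens[i])] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        start = s, end = s + lens[i], type = "ncRNA",
        id = sprintf("ncrna_%02d", i)
      )
    }
    half <- ceiling(spec$n_decoy_ncrna / 2)
    catalogs$genbank <- setNames(seqs[seq_len(half)],
                                 sprintf("ncrna_%02d", seq_len(half)))
    if (half < spec$n_decoy_ncrna) {
      idx <- (half + 1L):spec$n_decoy_ncrna
      catalogs$rfam <- setNames(seqs[idx], sprintf("ncrna_%02d", idx))
    }
  }

  # repeat elements: multiple genomic copies of one unit
  if (spec$n_repeat_elements > 0) {
    unit <- random_dna(300L)
    pl <- place_features(rep(300L, spec$n_repeat_elements), L, occupied)
    occupied <- pl$occupied
    for (i in seq_len(spec$n_repeat_elements)) {
      s <- pl$starts[i]
      genome[(s + 1L):(s + 300L)] <- strsplit(unit, "", fixed = TRUE)[[1]]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        start = s, end = s + 300L, type = "repeat",
        id = sprintf("repeat_%02d", i)
      )
    }
  }

  features <- dplyr::bind_rows(feats)
  if (nrow(features) == 0) {
    features <- tibble::tibble(start = integer(0), end = integer(0),
                               type = character(0), id = character(0))
  }
  features <- features %>%
    mutate(chrom = spec$chrom, strand = "+") %>%
    select("chrom", "start", "end", "strand", "type", "id") %>%
    arrange(.data$start)

  structure(
    list(
      spec = spec,
      chrom = spec$chrom,
      genome = paste(genome, collapse = ""),
      features = features,
      mirnas = mirnas,
      decoy_loci = decoys,
      catalogs = catalogs,
      mature_catalog = setNames(mirnas$mature_seq, mirnas$mirna_id)
    ),
    class = "toy_genome"
  )
}

decode_dna <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy genome:", nchar(x$genome), "nt on", x$chrom, "\n")
  cat("  planted hairpins:", nrow(x$mirnas),
      " expressed decoys:", nrow(x$decoy_loci),
      " features:", nrow(x$features), "\n")
  invisible(x)
}

#' Specification for simulating two small-RNA libraries
#'
#' Controls read synthesis for the `peak` and `late` libraries: per-miRNA
#' read counts, adapter sequences, the fixed sequencing read length, noise
#' class fractions and the per-base mutation rate.  Noise classes mirror the
#' read-cleaning filters: `poly_a` inserts, `short` (< 18 nt) inserts,
#' `low_quality` reads, `adapterless` reads, and `degradation` fragments of
#' exons.  The per-library totals are
#' `sum(expression) + sum(decoy counts) + noise`, where noise counts are the
#' configured fractions of `n_reads`; an error is raised if the requested
#' signal exceeds the `n_reads` budget.
#'
#' @param seed Integer seed.
#' @param n_reads Named vector `c(peak = ..., late = ...)`: per-library read
#'   budget used to size the noise classes and bound the signal.
#' @param read_length Fixed raw read length in nt.
#' @param adapter_3p,adapter_5p Adapter sequences.
#' @param noise Named numeric vector of fractions for `poly_a`, `short`,
#'   `low_quality`, `adapterless`, `degradation`.
#' @param mutation_rate Per-base substitution probability on miRNA inserts.
#' @param expression Tibble with `mirna_id`, `count_peak`, `count_late`
#'   (`NULL` = use [default_expression_profile()]).
#' @param decoy_expression Tibble with `decoy_id`, `count_peak`,
#'   `count_late` (`NULL` = a small flat count per decoy locus).
#' @return An object of class `library_sim_spec`.
#' @export
library_sim_spec <- function(seed = 1L,
                             n_reads = c(peak = 100000L, late = 100000L),
                             read_length = 36L,
                             adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                             adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                             noise = c(poly_a = 0, short = 0, low_quality = 0,
                                       adapterless = 0, degradation = 0),
                             mutation_rate = 0,
                             expression = NULL,
                             decoy_expression = NULL) {
  noise_full <- c(poly_a = 0, short = 0, low_quality = 0, adapterless = 0,
                  degradation = 0)
  noise_full[names(noise)] <- noise
  stopifnot(all(noise_full >= 0), sum(noise_full) < 1, mutation_rate >= 0,
            mutation_rate <= 1, nchar(adapter_3p) > 0)
  spec <- list(seed = as.integer(seed), n_reads = n_reads,
               read_length = as.integer(read_length),
               adapter_3p = adapter_3p, adapter_5p = adapter_5p,
               noise = noise_full, mutation_rate = mutation_rate,
               expression = expression, decoy_expression = decoy_expression)
  structure(spec, class = "library_sim_spec")
}

#' Default per-miRNA expression profile with planted fold changes
#'
#' Splits the planted miRNAs in half: the first half is up-regulated in the
#' late library by `fold_change`, the second half down-regulated by the same
#' factor, with per-library totals equal to `reads_per_library`.  This is the
#' planted ground truth the differential-expression stage is expected to
#' recover (flag each difference as significant with the correct sign).
#'
#' @param toy_genome A `toy_genome`.
#' @param reads_per_library Total signal reads per library.
#' @param fold_change Planted expression ratio between libraries.
#' @return Tibble with `mirna_id`, `count_peak`, `count_late`.
#' @export
default_expression_profile <- function(toy_genome, reads_per_library = 100000L,
                                       fold_change = 10) {
  n <- nrow(toy_genome$mirnas)
  stopifnot(n > 0)
  n_up <- ceiling(n / 2)
  n_down <- n - n_up
  # up miRNAs count lo in peak / hi in late, down miRNAs the reverse, with
  # hi/lo = fold_change and both library totals bounded by reads_per_library
  lo <- floor(reads_per_library /
                max(n_up * fold_change + n_down,
                    n_down * fold_change + n_up))
  hi <- floor(fold_change * lo)
  up <- rep(c(TRUE, FALSE), c(n_up, n_down))
  tibble::tibble(
    mirna_id = toy_genome$mirnas$mirna_id,
    count_peak = ifelse(up, lo, hi),
    count_late = ifelse(up, hi, lo),
    planted_log2_fc = ifelse(up, log2(fold_change), -log2(fold_change))
  )
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate two raw small-RNA libraries from a toy genome
#'
#' Synthesises adapter-ligated reads for the `peak` and `late` libraries:
#' each signal read is a planted mature (or decoy tag) insert followed by the
#' 3' adapter and random filler, truncated to the fixed read length, with
#' high base qualities; noise reads exercise the individual cleaning filters.
#' Every read's origin is recorded in the truth manifest.  Deterministic
#' given the sim spec's seed.
#'
#' @param toy_genome A `toy_genome` from [generate_toy_genome()].
#' @param sim A [library_sim_spec()].
#' @return An object of class `sim_libraries`: a list with `reads` (tibble:
#'   `library`, `read_id`, `sequence`, `quality`, `category`, `origin_id`)
#'   and `manifest` (list with per-miRNA and per-decoy true counts, and noise
#'   class counts per library).
#' @export
simulate_libraries <- function(toy_genome, sim) {
  stopifnot(inherits(toy_genome, "toy_genome"),
            inherits(sim, "library_sim_spec"))
  withr::with_seed(sim$seed, simulate_libraries_impl(toy_genome, sim))
}

simulate_libraries_impl <- function(tg, sim) {
  expr <- sim$expression
  if (is.null(expr)) {
    expr <- default_expression_profile(tg, reads_per_library =
                                         round(min(sim$n_reads) * 0.9))
  }
  if (!all(expr$mirna_id %in% tg$mirnas$mirna_id)) {
    stop("expression profile references miRNAs not planted in the genome")
  }
  dexpr <- sim$decoy_expression
  if (is.null(dexpr) && nrow(tg$decoy_loci) > 0) {
    dexpr <- tibble::tibble(decoy_id = tg$decoy_loci$decoy_id,
                            count_peak = 20L, count_late = 20L)
  }

  hi_q <- "I"  # Phred 40
  lo_q <- "#"  # Phred 2
  exons <- filter(tg$features, .data$type == "exon")

  build_library <- function(lib) {
    n_budget <- sim$n_reads[[lib]]
    noise_n <- round(sim$noise * n_budget)
    cnt_col <- paste0("count_", lib)
    sig_mirna <- setNames(expr[[cnt_col]], expr$mirna_id)
    sig_decoy <- if (!is.null(dexpr)) setNames(dexpr[[cnt_col]], dexpr$decoy_id)
                 else integer(0)
    if (sum(sig_mirna) + sum(sig_decoy) + sum(noise_n) > n_budget) {
      stop("requested read counts exceed n_reads for library '", lib, "'")
    }

    inserts <- c(
      rep(setNames(tg$mirnas$mature_seq, tg$mirnas$mirna_id)[names(sig_mirna)],
          sig_mirna),
      rep(setNames(tg$decoy_loci$tag_seq, tg$decoy_loci$decoy_id)[names(sig_decoy)],
          sig_decoy)
    )
    origin <- c(rep(names(sig_mirna), sig_mirna),
                rep(names(sig_decoy), sig_decoy))
    category <- c(rep("mirna", sum(sig_mirna)),
                  rep("decoy_locus", sum(sig_decoy)))
    inserts <- mutate_bases(unname(inserts), sim$mutation_rate)
    qual <- rep(hi_q, length(inserts))

    add <- function(ins, cat, q) {
      inserts <<- c(inserts, ins)
      origin <<- c(origin, rep(NA_character_, length(ins)))
      category <<- c(category, rep(cat, length(ins)))
      qual <<- c(qual, rep(q, length(ins)))
    }
    if (noise_n[["poly_a"]] > 0) {
      add(vapply(sample(20:26, noise_n[["poly_a"]], TRUE),
                 function(k) strrep("A", k), character(1)), "poly_a", hi_q)
    }
    if (noise_n[["short"]] > 0) {
      lens <- sample(10:17, noise_n[["short"]], TRUE)
      starts <- sample.int(nchar(tg$genome) - 20L, noise_n[["short"]])
      add(substring(tg$genome, starts, starts + lens - 1L), "short", hi_q)
    }
    if (noise_n[["low_quality"]] > 0) {
      picks <- sample(tg$mirnas$mature_seq, noise_n[["low_quality"]], TRUE)
      add(picks, "low_quality", lo_q)
    }
    if (noise_n[["degradation"]] > 0 && nrow(exons) > 0) {
      ei <- sample.int(nrow(exons), noise_n[["degradation"]], TRUE)
      lens <- sample(18:28, noise_n[["degradation"]], TRUE)
      offs <- vapply(seq_along(ei), function(k) {
        sample.int(exons$end[ei[k]] - exons$start[ei[k]] - lens[k], 1L)
      }, integer(1))
      starts <- exons$start[ei] + offs
      add(substring(tg$genome, starts + 1L, starts + lens), "degradation", hi_q)
    }

    rl <- sim$read_length
    filler <- vapply(seq_along(inserts), function(i) random_dna(rl),
                     character(1))
    seqs <- substr(paste0(inserts, sim$adapter_3p, filler), 1L, rl)
    quals <- strrep(qual, rl)
    if (noise_n[["adapterless"]] > 0) {
      seqs <- c(seqs, vapply(seq_len(noise_n[["adapterless"]]),
                             function(i) random_dna(rl), character(1)))
      quals <- c(quals, rep(strrep(hi_q, rl), noise_n[["adapterless"]]))
      origin <- c(origin, rep(NA_character_, noise_n[["adapterless"]]))
      category <- c(category, rep("adapterless", noise_n[["adapterless"]]))
    }
    ord <- sample.int(length(seqs))
    tibble::tibble(
      library = lib,
      read_id = sprintf("%s_%06d", lib, seq_along(seqs)),
      sequence = seqs[ord],
      quality = quals[ord],
      category = category[ord],
      origin_id = origin[ord]
    )
  }

  reads <- dplyr::bind_rows(build_library("peak"), build_library("late"))

  counts_of <- function(lib) {
    r <- filter(reads, .data$library == lib, .data$category == "mirna")
    tab <- table(factor(r$origin_id, levels = expr$mirna_id))
    as.integer(tab)
  }
  mirna_counts <- tibble::tibble(
    mirna_id = expr$mirna_id,
    count_peak = counts_of("peak"),
    count_late = counts_of("late")
  )
  noise_counts <- reads %>%
    filter(!.data$category %in% c("mirna", "decoy_locus")) %>%
    count(.data$library, .data$category, name = "n")

  structure(
    list(
      spec = sim,
      reads = reads,
      manifest = list(
        mirna_counts = mirna_counts,
        decoy_expression = dexpr,
        noise_counts = noise_counts,
        read_origins = select(reads, "library", "read_id", "category",
                              "origin_id")
      )
    ),
    class = "sim_libraries"
  )
}

#' @export
print.sim_libraries <- function(x, ...) {
  tab <- count(x$reads, .data$library)
  cat("simulated libraries:",
      paste(sprintf("%s = %d reads", tab$library, tab$n), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write simulated reads to FASTQ (Sanger Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (one library).
#' @param path Output path (uncompressed FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed Sanger FASTQ file.
#' @return Tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: number of lines not a multiple of 4 in ", path)
  }
  ids <- lines[seq(1, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at index ", bad[1], " in ", path)
  }
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", ids)),
    sequence = lines[seq(2, length(lines), 4)],
    quality = lines[seq(4, length(lines), 4)]
  )
}

#' Write a toy genome to FASTA and its features to a BED-like TSV
#'
#' @param toy_genome A `toy_genome`.
#' @param fasta_path,bed_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_toy_genome <- function(toy_genome, fasta_path = NULL, bed_path = NULL) {
  if (!is.null(fasta_path)) {
    dna <- Biostrings::DNAStringSet(setNames(toy_genome$genome,
                                             toy_genome$chrom))
    Biostrings::writeXStringSet(dna, fasta_path)
  }
  if (!is.null(bed_path)) {
    write_bed(toy_genome$features, bed_path)
  }
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Read/write feature intervals as BED-like TSV (0-based, half-open)
#'
#' Columns: chrom, start, end, id, score (unused, 0), strand, type.
#'
#' @param features Tibble with `chrom`, `start`, `end`, `strand`, `type`, `id`.
#' @param path File path.
#' @return `read_bed()` returns the features tibble; `write_bed()` returns
#'   `path` invisibly.
#' @export
write_bed <- function(features, path) {
  out <- tibble::tibble(
    chrom = features$chrom, start = features$start, end = features$end,
    name = features$id, score = 0L, strand = features$strand,
    type = features$type
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand", "type"),
                        col_types = "ciicicc", progress = FALSE)
  tibble::tibble(chrom = df$chrom, start = df$start, end = df$end,
                 strand = df$strand, type = df$type, id = df$name)
}

#' Synthetic transcripts with planted miRNA target sites
#'
#' Builds random transcript sequences and embeds, in the first
#' `n_with_sites` transcripts, the exact reverse complement of one planted
#' mature miRNA at a recorded offset — a perfect target site that the target
#' scan must find.
#'
#' @param toy_genome A `toy_genome`.
#' @param n_transcripts Number of transcripts.
#' @param n_with_sites How many carry one planted perfect site.
#' @param length Transcript length in nt.
#' @param seed Integer seed.
#' @return A list with `transcripts` (named character vector) and
#'   `planted_sites` (tibble: transcript_id, mirna_id, site_start 0-based).
#' @export
make_synthetic_transcripts <- function(toy_genome, n_transcripts = 20L,
                                       n_with_sites = 10L, length = 500L,
                                       seed = 1L) {
  stopifnot(n_with_sites <= n_transcripts, nrow(toy_genome$mirnas) > 0)
  withr::with_seed(as.integer(seed), {
    tx <- vapply(seq_len(n_transcripts), function(i) random_dna(length),
                 character(1))
    names(tx) <- sprintf("tx_%03d", seq_len(n_transcripts))
    mids <- sample(toy_genome$mirnas$mirna_id, n_with_sites, replace = TRUE)
    sites <- vector("list", n_with_sites)
    for (i in seq_len(n_with_sites)) {
      mat <- toy_genome$mirnas$mature_seq[toy_genome$mirnas$mirna_id == mids[i]]
      site <- revcomp(mat)
      pos <- sample.int(length - nchar(site) + 1L, 1L) - 1L
      substr(tx[i], pos + 1L, pos + nchar(site)) <- site
      sites[[i]] <- tibble::tibble(transcript_id = names(tx)[i],
                                   mirna_id = mids[i], site_start = pos)
    }
    list(transcripts = tx, planted_sites = dplyr::bind_rows(sites))
  })
}

#' Synthetic gene-to-term annotation map with one enriched term
#'
#' Builds a background of `n_genes` genes annotated to `n_terms` terms at
#' random, plus one planted term (`TERM_ENRICHED`) carried by every gene in
#' `enriched_genes` and a small random fraction of the background — an
#' extreme enrichment signal that must rank first.
#'
#' @param n_genes Background size.
#' @param n_terms Number of random terms.
#' @param enriched_genes Character vector of genes carrying the planted term.
#' @param namespace Annotation namespace label (e.g. `"GO"` or `"KEGG"`).
#' @param seed Integer seed.
#' @return A tibble with `gene_id`, `term_id`, `namespace`.
#' @export
make_synthetic_term_map <- function(n_genes = 200L, n_terms = 20L,
                                    enriched_genes = character(0),
                                    namespace = "GO", seed = 1L) {
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    rows <- lapply(seq_len(n_terms), function(t) {
      members <- sample(genes, max(3L, rbinom(1, n_genes, 0.08)))
      tibble::tibble(gene_id = members,
                     term_id = sprintf("TERM_%03d", t))
    })
    map <- dplyr::bind_rows(rows)
    if (length(enriched_genes)) {
      extra <- sample(setdiff(genes, enriched_genes),
                      max(1L, round(0.02 * n_genes)))
      map <- dplyr::bind_rows(
        map,
        tibble::tibble(gene_id = c(enriched_genes, extra),
                       term_id = "TERM_ENRICHED")
      )
    }
    mutate(map, namespace = namespace)
  })
}
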