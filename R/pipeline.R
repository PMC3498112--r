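#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()].  By default every
#' input is synthetic (generated from the seeded specs); external inputs can
#' be supplied instead via `genome_fasta` and `fastq_peak`/`fastq_late`, and
#' are checked for existence at validation time, before any stage runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed, propagated to every stochastic stage.
#' @param genome Named list of [toy_genome_spec()] arguments.
#' @param libraries Named list of [library_sim_spec()] arguments.
#' @param discovery Named list of [discovery_params()] arguments.
#' @param diffexpr List with `p_cut`, `fc_cut`.
#' @param targets List with `n_transcripts`, `n_with_sites`,
#'   `transcript_length`, `max_mirnas` (cap on the number of significant
#'   miRNAs scanned).
#' @param enrichment List with `method`, `alpha`.
#' @param genome_fasta,fastq_peak,fastq_late Optional external input paths.
#' @param verbose Emit progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            genome = list(),
                            libraries = list(),
                            discovery = list(),
                            diffexpr = list(p_cut = 0.01, fc_cut = 1),
                            targets = list(n_transcripts = 20L,
                                           n_with_sites = 10L,
                                           transcript_length = 300L,
                                           max_mirnas = 5L),
                            enrichment = list(method = "bonferroni",
                                              alpha = 0.5),
                            genome_fasta = NULL,
                            fastq_peak = NULL, fastq_late = NULL,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Validate a pipeline configuration
#'
#' Checks argument consistency and that every referenced external input
#' exists; called by [run_pipeline()] before any stage runs.
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly; errors on the first problem found.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir) || !nzchar(config$out_dir)) {
    stop("pipeline config: out_dir must be set")
  }
  for (field in c("genome_fasta", "fastq_peak", "fastq_late")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline config: ", field, " path does not exist: ", p)
    }
  }
  invisible(config)
}

stage_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[lactomir] ", ...)
}

run_stage <- function(name, config, expr) {
  stage_msg(config, "stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Orchestrates the stages end to end: synthetic genome and library
#' simulation (or external inputs), read cleaning and tag collapsing,
#' genome mapping and priority annotation, novel hairpin discovery,
#' differential expression over the known-miRNA catalog, target prediction
#' on (synthetic) transcripts, and term enrichment of the predicted target
#' genes.  Every output table is written under `out_dir` together with a
#' versioned JSON run report containing per-stage counts and file
#' checksums.  Outputs are a pure function of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with each stage's in-memory result and the run
#'   `report`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- as.integer(config$seed)

  # --- simulate ------------------------------------------------------------
  sim_stage <- run_stage("simulate", config, {
    tg <- generate_toy_genome(
      do.call(toy_genome_spec, c(list(seed = seed), config$genome))
    )
    sim <- simulate_libraries(
      tg, do.call(library_sim_spec, c(list(seed = seed + 1L),
                                      config$libraries))
    )
    write_toy_genome(tg, out("genome.fa"), out("features.bed"))
    for (lib in c("peak", "late")) {
      write_fastq(filter(sim$reads, .data$library == lib),
                  out(paste0(lib, ".fastq")))
    }
    readr::write_tsv(sim$manifest$mirna_counts, out("truth_mirna_counts.tsv"))
    list(tg = tg, sim = sim)
  })
  tg <- sim_stage$tg
  sim <- sim_stage$sim

  # --- preprocess ----------------------------------------------------------
  prep <- run_stage("preprocess", config, {
    cfg <- clean_filter_config(adapter_3p = sim$spec$adapter_3p,
                               adapter_5p = sim$spec$adapter_5p)
    reads <- if (!is.null(config$fastq_peak)) {
      dplyr::bind_rows(
        mutate(read_fastq(config$fastq_peak), library = "peak"),
        mutate(read_fastq(config$fastq_late), library = "late")
      )
    } else {
      sim$reads
    }
    cleaned <- clean_reads(reads, cfg)
    tags <- collapse_tags(cleaned)
    readr::write_tsv(tags, out("tags.tsv"))
    readr::write_tsv(filter_counts(cleaned), out("filter_counts.tsv"))
    list(cleaned = cleaned, tags = tags,
         totals = cleaned %>% filter(.data$status == "clean") %>%
           count(.data$library, name = "n"))
  })

  # --- annotate ------------------------------------------------------------
  ann <- run_stage("annotate", config, {
    index <- if (!is.null(config$genome_fasta)) {
      build_genome_index(Biostrings::readDNAStringSet(config$genome_fasta))
    } else {
      build_genome_index(tg)
    }
    hits <- map_tags(index, prep$tags$sequence)
    # the planted matures are treated as unknown here: the point of the
    # synthetic run is that discovery must find them as novel candidates;
    # the mature catalog is used downstream only to quantify per-miRNA counts
    catalogs <- list(genbank = tg$catalogs$genbank,
                     rfam = tg$catalogs$rfam)
    cls <- classify_tags(prep$tags, catalogs, hits, tg$features)
    readr::write_tsv(cls, out("tag_categories.tsv"))
    list(index = index, hits = hits, classifications = cls,
         catalogs = catalogs)
  })

  # --- discover ------------------------------------------------------------
  disc <- run_stage("discover", config, {
    params <- do.call(discovery_params, config$discovery)
    res <- call_novel_candidates(prep$tags, ann$classifications, ann$hits,
                                 ann$index, tg$features, params,
                                 seed = seed + 2L)
    if (nrow(res$candidates)) {
      readr::write_tsv(res$candidates, out("novel_candidates.tsv"))
      write_candidates(res$candidates, out("novel_precursors.fa"),
                       out("novel_candidates.gff3"), ann$index)
    }
    res
  })

  # --- diffexpr ------------------------------------------------------------
  de <- run_stage("diffexpr", config, {
    km <- match_known_mirnas(prep$tags$sequence, tg$mature_catalog)
    counts <- prep$tags %>%
      left_join(km, by = "sequence") %>%
      filter(!is.na(.data$mirna_id)) %>%
      group_by(mirna_id = .data$mirna_id) %>%
      summarise(count_peak = sum(.data$count_peak),
                count_late = sum(.data$count_late), .groups = "drop")
    totals <- setNames(prep$totals$n, prep$totals$library)
    det <- differential_table(counts, totals[["peak"]], totals[["late"]],
                              p_cut = config$diffexpr$p_cut,
                              fc_cut = config$diffexpr$fc_cut)
    write_de_table(det, out("differential_expression.tsv"))
    det
  })

  # --- targets -------------------------------------------------------------
  tg_stage <- run_stage("targets", config, {
    sig <- filter(tidy(de), .data$sig_level %in% c("*", "**"))
    sig_ids <- head(sig$mirna_id, config$targets$max_mirnas)
    tx <- make_synthetic_transcripts(
      tg, n_transcripts = config$targets$n_transcripts,
      n_with_sites = config$targets$n_with_sites,
      length = config$targets$transcript_length, seed = seed + 3L
    )
    mir_seqs <- tg$mature_catalog[intersect(sig_ids,
                                            names(tg$mature_catalog))]
    hits <- if (length(mir_seqs)) {
      scan_transcripts(mir_seqs, tx$transcripts)
    } else {
      empty_target_hits()
    }
    readr::write_tsv(hits, out("target_hits.tsv"))
    list(transcripts = tx, hits = hits)
  })

  # --- enrich --------------------------------------------------------------
  enr <- run_stage("enrich", config, {
    genes <- names(tg_stage$transcripts$transcripts)
    targets <- unique(tg_stage$hits$transcript_id)
    term_map <- make_synthetic_term_map(
      n_genes = length(genes), n_terms = 10L,
      enriched_genes = targets, seed = seed + 4L
    )
    term_map$gene_id <- genes[match(term_map$gene_id,
                                    sprintf("gene_%04d",
                                            seq_along(genes)))]
    res <- if (length(targets)) {
      enrich_terms(targets, genes, term_map,
                   method = config$enrichment$method,
                   alpha = config$enrichment$alpha)
    } else NULL
    if (!is.null(res)) readr::write_tsv(tidy(res), out("enrichment.tsv"))
    res
  })

  # --- report --------------------------------------------------------------
  report <- run_stage("report", config, {
    files <- list.files(config$out_dir, full.names = TRUE)
    files <- files[!grepl("run_report[.]json$", files)]
    rep <- list(
      schema_version = "1.0",
      seed = seed,
      stage_counts = list(
        raw_reads = nrow(sim$reads),
        clean_reads = sum(prep$cleaned$status == "clean"),
        unique_tags = nrow(prep$tags),
        category_counts = as.list(table(ann$classifications$category)),
        novel_candidates = nrow(disc$candidates),
        de_significant = sum(!is.na(de$sig_level) &
                               de$sig_level %in% c("*", "**")),
        target_hits = nrow(tg_stage$hits),
        enriched_terms = if (!is.null(enr)) sum(enr$significant) else 0L
      ),
      checksums = as.list(tools::md5sum(files))
    )
    jsonlite::write_json(rep, out("run_report.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    rep
  })

  invisible(list(toy_genome = tg, sim = sim, preprocess = prep,
                 annotate = ann, discover = disc, diffexpr = de,
                 targets = tg_stage, enrichment = enr, report = report))
}
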