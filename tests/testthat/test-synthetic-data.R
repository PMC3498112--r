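test_that("toy genome generation is deterministic and honours the empty case", {
  spec <- toy_genome_spec(seed = 401, genome_length = 30000,
                          n_mirna_hairpins = 4, n_expressed_decoys = 2,
                          n_decoy_ncrna = 2, n_repeat_elements = 2)
  a <- generate_toy_genome(spec)
  b <- generate_toy_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)
  expect_identical(a$mirnas, b$mirnas)

  none <- generate_toy_genome(toy_genome_spec(
    seed = 402, genome_length = 20000, n_mirna_hairpins = 0,
    n_expressed_decoys = 0, n_decoy_ncrna = 0, n_repeat_elements = 0
  ))
  expect_identical(nrow(none$mirnas), 0L)
  expect_false("hairpin" %in% none$features$type)
})

test_that("planted features do not overlap and sequences match the genome", {
  run <- small_run()
  tg <- run$tg
  fx <- dplyr::filter(tg$features,
                      .data$type %in% c("hairpin", "ncRNA", "repeat",
                                        "decoy_locus"))
  fx <- fx[order(fx$start), ]
  expect_true(all(fx$start[-1] >= fx$end[-nrow(fx)]))
  for (i in seq_len(nrow(tg$mirnas))) {
    expect_identical(
      substr(tg$genome, tg$mirnas$precursor_start[i] + 1,
             tg$mirnas$precursor_end[i]),
      tg$mirnas$precursor_seq[i]
    )
  }
})

test_that("all planted stem-25 precursors fold below the discovery threshold", {
  tg <- generate_toy_genome(toy_genome_spec(
    seed = 403, genome_length = 80000, n_mirna_hairpins = 20,
    hairpin_stem = c(25L, 25L), hairpin_loop = c(8L, 8L),
    n_expressed_decoys = 0, n_decoy_ncrna = 0, n_repeat_elements = 0
  ))
  energies <- vapply(tg$mirnas$precursor_seq,
                     function(s) fold_sequence(s)$energy, numeric(1))
  expect_true(all(energies < -18))
})

test_that("infeasible feature packing raises an explicit error", {
  expect_error(
    generate_toy_genome(toy_genome_spec(
      seed = 404, genome_length = 800, n_mirna_hairpins = 30,
      n_expressed_decoys = 0, n_decoy_ncrna = 0, n_repeat_elements = 0,
      exon_fraction = 0.01, intron_fraction = 0.01
    )),
    "infeasible packing"
  )
})

test_that("zero-noise reads trim back to exact genome substrings", {
  run <- small_run()
  clean <- dplyr::filter(run$cleaned, .data$status == "clean")
  inserts <- unique(clean$insert)
  found <- vapply(inserts, function(s) {
    grepl(s, run$tg$genome, fixed = TRUE) ||
      grepl(revcomp(s), run$tg$genome, fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
})

test_that("the truth manifest records exactly the requested counts", {
  run <- small_run()
  tg <- run$tg
  expr <- tibble::tibble(mirna_id = tg$mirnas$mirna_id[1:2],
                         count_peak = c(1000L, 50L),
                         count_late = c(10L, 500L))
  sim <- simulate_libraries(tg, library_sim_spec(
    seed = 405, n_reads = c(peak = 2000, late = 2000), expression = expr,
    decoy_expression = tibble::tibble(decoy_id = character(0),
                                      count_peak = integer(0),
                                      count_late = integer(0))
  ))
  expect_identical(sim$manifest$mirna_counts$count_peak, expr$count_peak)
  expect_identical(sim$manifest$mirna_counts$count_late, expr$count_late)

  expect_error(
    simulate_libraries(tg, library_sim_spec(
      seed = 406, n_reads = c(peak = 100, late = 100), expression = expr
    )),
    "exceed n_reads"
  )
})

test_that("per-library read totals decompose exactly by origin category", {
  run <- small_run()
  reads <- run$sim$reads
  totals <- dplyr::count(reads, .data$library)
  by_cat <- dplyr::count(reads, .data$library, .data$category)
  recomposed <- dplyr::count(by_cat, .data$library, wt = .data$n)
  expect_identical(dplyr::arrange(recomposed, .data$library),
                   dplyr::arrange(totals, .data$library))
  mc <- run$sim$manifest$mirna_counts
  expect_identical(sum(mc$count_peak),
                   sum(reads$library == "peak" & reads$category == "mirna"))
})

test_that("simulation is deterministic given the seed", {
  run <- small_run()
  sim2 <- simulate_libraries(run$tg, run$sim$spec)
  expect_identical(run$sim$reads, sim2$reads)
})

test_that("noise classes appear at the configured rates and round-trip FASTQ", {
  run <- small_run()
  sim <- simulate_libraries(run$tg, library_sim_spec(
    seed = 407, n_reads = c(peak = 1000, late = 1000),
    expression = tibble::tibble(mirna_id = run$tg$mirnas$mirna_id[1],
                                count_peak = 300L, count_late = 300L),
    decoy_expression = tibble::tibble(decoy_id = character(0),
                                      count_peak = integer(0),
                                      count_late = integer(0)),
    noise = c(poly_a = 0.1, short = 0.05, low_quality = 0.05,
              adapterless = 0.05, degradation = 0.1)
  ))
  peak <- dplyr::filter(sim$reads, .data$library == "peak")
  expect_identical(sum(peak$category == "poly_a"), 100L)
  expect_identical(sum(peak$category == "short"), 50L)
  expect_identical(sum(peak$category == "adapterless"), 50L)

  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(peak, path)
  back <- read_fastq(path)
  expect_identical(back$sequence, peak$sequence)
  expect_identical(back$quality, peak$quality)
})

test_that("synthetic transcripts carry their planted sites where recorded", {
  run <- small_run()
  tx <- make_synthetic_transcripts(run$tg, n_transcripts = 6,
                                   n_with_sites = 3, length = 200, seed = 408)
  for (i in seq_len(nrow(tx$planted_sites))) {
    ps <- tx$planted_sites[i, ]
    mat <- run$tg$mirnas$mature_seq[run$tg$mirnas$mirna_id == ps$mirna_id]
    site <- substr(tx$transcripts[[ps$transcript_id]], ps$site_start + 1,
                   ps$site_start + nchar(mat))
    expect_identical(site, revcomp(mat))
  }
})
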