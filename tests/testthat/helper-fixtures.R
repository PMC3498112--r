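# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

# a small seeded toy genome + zero-noise simulation reused across files
small_run <- function() {
  if (is.null(.fixtures$small_run)) {
    tg <- generate_toy_genome(toy_genome_spec(
      seed = 101, genome_length = 60000, n_mirna_hairpins = 8,
      n_expressed_decoys = 8, n_decoy_ncrna = 6, n_repeat_elements = 3
    ))
    prof <- default_expression_profile(tg, reads_per_library = 4000,
                                       fold_change = 10)
    sim <- simulate_libraries(tg, library_sim_spec(
      seed = 102, n_reads = c(peak = 5000, late = 5000), expression = prof
    ))
    cfg <- clean_filter_config(adapter_3p = sim$spec$adapter_3p,
                               adapter_5p = sim$spec$adapter_5p)
    cleaned <- clean_reads(sim$reads, cfg)
    tags <- collapse_tags(cleaned)
    index <- build_genome_index(tg)
    hits <- map_tags(index, tags$sequence)
    .fixtures$small_run <- list(tg = tg, prof = prof, sim = sim, cfg = cfg,
                                cleaned = cleaned, tags = tags,
                                index = index, hits = hits)
  }
  .fixtures$small_run
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a perfect hairpin: stem + loop + reverse complement of the stem
make_hairpin <- function(stem_len, loop_len, rna = TRUE) {
  stem <- random_rna(stem_len)
  loop <- random_rna(loop_len)
  paste0(stem, loop, revcomp(stem, rna = rna))
}

# independent scorer for a returned fold: stacks between adjacently nested
# pairs plus one initiation charge per helix head (used to validate that the
# reported energy matches the reported structure)
score_fold_from_partner <- function(sequence, partner, helix_init = 4.1,
                                    energy_table = default_stack_energies()) {
  chars <- strsplit(gsub("T", "U", toupper(sequence)), "")[[1]]
  pt <- function(i, j) {
    key <- paste0(chars[i], chars[j])
    c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)[key]
  }
  e <- 0
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > i) {
      head_pair <- !(i > 1 && j < length(partner) && partner[i - 1] == j + 1)
      if (head_pair) e <- e + helix_init
      if (partner[i + 1] == j - 1 && j - 1 > i + 1) {
        e <- e + energy_table[pt(i, j), pt(i + 1, j - 1)]
      }
    }
  }
  unname(e)
}
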