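test_that("genome index reports exact hits only, with brute-force copy numbers", {
  set.seed(601)
  tag <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
  spacers <- replicate(26, paste(sample(c("A", "C", "G", "T"), 40,
                                        replace = TRUE), collapse = ""))
  genome <- paste0(spacers[1],
                   paste0(tag, spacers[2:26], collapse = ""))
  idx <- build_genome_index(c(chr1 = genome))
  hits <- map_tags(idx, tag)
  # oracle: brute-force scan of both strands
  n_fwd <- length(gregexpr(tag, genome, fixed = TRUE)[[1]])
  n_rev <- sum(gregexpr(revcomp(tag), genome, fixed = TRUE)[[1]] > 0)
  expect_identical(n_fwd, 25L)
  expect_identical(unique(hits$copy_number), n_fwd + n_rev)
  expect_identical(nrow(hits), n_fwd + n_rev)
  # the genome substring at each reported hit equals the tag
  for (i in seq_len(nrow(hits))) {
    sub <- substr(genome, hits$start[i] + 1, hits$end[i])
    expect_identical(if (hits$strand[i] == "+") sub else revcomp(sub), tag)
  }
  # one mismatch: no hits
  mut <- tag
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(tag, 5, 5))[1]
  expect_identical(nrow(map_tags(idx, mut)), 0L)
})

test_that("genome index input validation", {
  expect_error(build_genome_index(c("ACGT", "GGGG")), "unique names")
  expect_error(build_genome_index(setNames(character(0), character(0))),
               "non-empty")
})

test_that("known-miRNA matching honours the mismatch threshold and recovers mutated tags", {
  set.seed(602)
  catalog <- setNames(
    replicate(20, paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                        collapse = "")),
    sprintf("known_%02d", 1:20)
  )
  exact <- match_known_mirnas(catalog[[3]], catalog)
  expect_identical(exact$mirna_id, "known_03")
  expect_identical(exact$mismatches, 0L)

  # 100 tags mutated with up to 3 substitutions return to their source
  mutate_tag <- function(seq, k) {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(chars), k)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "U"),
                                              chars[p]), 1)
    paste(chars, collapse = "")
  }
  truth <- sample(names(catalog), 100, replace = TRUE)
  tags <- vapply(truth, function(id) mutate_tag(catalog[[id]],
                                                sample(0:3, 1)),
                 character(1), USE.NAMES = FALSE)
  m <- match_known_mirnas(tags, catalog)
  expect_identical(nrow(m), 100L)
  expect_identical(m$mirna_id, truth)

  # 4 substitutions versus every entry leaves the tag unmatched
  far <- mutate_tag(catalog[[1]], 8)
  stopifnot(min(vapply(catalog, function(cs) {
    sum(strsplit(cs, "")[[1]] != strsplit(far, "")[[1]])
  }, numeric(1))) > 3)
  expect_identical(nrow(match_known_mirnas(far, catalog)), 0L)
})

test_that("priority rule assigns one category per tag, top class first", {
  mirna <- "ACGUACGUACGUACGUACGUAC"
  catalogs <- list(
    genbank = c(rrna1 = paste0("GGGG", gsub("U", "T", mirna), "CCCC")),
    known_mirna = c(known1 = mirna)
  )
  cls <- classify_tags(mirna, catalogs)
  expect_identical(as.character(cls$category), "rRNA_etc_genbank")

  # without the higher-priority catalog the tag falls to known miRNA
  cls2 <- classify_tags(mirna, catalogs[-1])
  expect_identical(as.character(cls2$category), "known_miRNA")
})

test_that("interval categories require an overlapping perfect genome hit", {
  run <- small_run()
  tg <- run$tg
  intron <- dplyr::filter(tg$features, .data$type == "intron")[1, ]
  tag <- substr(tg$genome, intron$start + 101, intron$start + 122)
  hits <- map_tags(run$index, tag)
  cls <- classify_tags(tag, list(), hits, tg$features)
  expect_identical(as.character(cls$category), "intron")

  exon <- dplyr::filter(tg$features, .data$type == "exon")[1, ]
  tag_e <- substr(tg$genome, exon$start + 51, exon$start + 72)
  cls_e <- classify_tags(tag_e, list(), map_tags(run$index, tag_e),
                         tg$features)
  expect_identical(as.character(cls_e$category), "exon")
})

test_that("classification partitions synthetic tags as the manifest dictates", {
  run <- small_run()
  tg <- run$tg
  catalogs <- list(genbank = tg$catalogs$genbank, rfam = tg$catalogs$rfam,
                   known_mirna = tg$mature_catalog)
  cls <- classify_tags(run$tags, catalogs, run$hits, tg$features)
  # partition: every tag gets exactly one category
  expect_identical(nrow(cls), nrow(run$tags))
  expect_false(anyNA(cls$category))

  merged <- dplyr::left_join(run$tags, cls, by = "sequence")
  mature_set <- toupper(tg$mirnas$mature_seq)
  decoy_set <- toupper(tg$decoy_loci$tag_seq)
  expect_true(all(merged$category[merged$sequence %in% mature_set] ==
                    "known_miRNA"))
  expect_true(all(merged$category[merged$sequence %in% decoy_set] ==
                    "unannotated"))
})

test_that("dropping a high-priority catalog only demotes tags", {
  run <- small_run()
  tg <- run$tg
  full <- list(genbank = tg$catalogs$genbank, rfam = tg$catalogs$rfam,
               known_mirna = tg$mature_catalog)
  cls_full <- classify_tags(run$tags, full, run$hits, tg$features)
  cls_nok <- classify_tags(run$tags, full[c("genbank", "rfam")], run$hits,
                           tg$features)
  rank <- function(cat) match(as.character(cat), levels(cls_full$category))
  expect_true(all(rank(cls_nok$category) >= rank(cls_full$category)))
})
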