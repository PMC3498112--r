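test_that("duplex scoring classifies WC, wobble and mismatch positions", {
  m <- "ACGUACGUACGUACGUACGUA"
  sc <- score_duplex(m, revcomp(m, rna = TRUE))
  expect_true(all(sc$states == "WC"))
  expect_identical(sc$mismatch_score, 0)

  # replace the site base paired with miRNA position 3 (a G) by U -> G:U
  site <- revcomp(m, rna = TRUE)
  pos <- nchar(m) - 3 + 1
  stopifnot(substr(m, 3, 3) == "G", substr(site, pos, pos) == "C")
  substr(site, pos, pos) <- "U"
  sc_gu <- score_duplex(m, site)
  expect_identical(sc_gu$states[3], "GU")
  expect_identical(sc_gu$mismatch_score, 0.5)

  expect_error(score_duplex(m, "ACGU"), "must equal")
})

test_that("positional rules fire where designed", {
  set.seed(801)
  m <- random_rna(21)
  perfect <- revcomp(m, rna = TRUE)
  pe <- fold_duplex(m, perfect)$energy

  ok <- apply_target_rules(score_duplex(m, perfect), pe, pe)
  expect_true(ok$accepted)
  expect_identical(ok$mfe_ratio, 1)

  # force MM at miRNA positions 10 and 11
  site_d <- perfect
  for (p in c(10, 11)) {
    sp <- nchar(m) - p + 1
    mb <- substr(m, p, p)
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(revcomp(mb, rna = TRUE), if (mb == "G") "U",
                     if (mb == "U") "G"))
    substr(site_d, sp, sp) <- bad[1]
  }
  v <- apply_target_rules(score_duplex(m, site_d),
                          fold_duplex(m, site_d)$energy, pe)
  expect_false(v$rule_d)
  expect_false(v$accepted)
})

test_that("three spread mismatches pass the positional rules but fail strict mode", {
  set.seed(802)
  m <- random_rna(22)
  site <- revcomp(m, rna = TRUE)
  # mismatches at miRNA positions 3, 7, 20: spread, outside 10-11
  for (p in c(3, 7, 20)) {
    sp <- nchar(m) - p + 1
    mb <- substr(m, p, p)
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(revcomp(mb, rna = TRUE), if (mb == "G") "U",
                     if (mb == "U") "G"))
    substr(site, sp, sp) <- bad[1]
  }
  de <- fold_duplex(m, site)$energy
  pe <- fold_duplex(m, revcomp(m, rna = TRUE))$energy
  sc <- score_duplex(m, site)
  expect_identical(sc$mismatch_score, 3)
  lenient <- apply_target_rules(sc, de, pe, target_rule_config(strict = FALSE))
  expect_true(all(c(lenient$rule_a, lenient$rule_b, lenient$rule_c,
                    lenient$rule_d, lenient$rule_e)))
  strict <- apply_target_rules(sc, de, pe, target_rule_config())
  expect_false(strict$rule_strict)
  expect_false(strict$accepted)
})

test_that("verdicts equal the literal rule transcription on randomized duplexes", {
  set.seed(803)
  n_match <- 0
  for (i in 1:2000) {
    m <- random_rna(sample(19:24, 1))
    site <- mutate_site(revcomp(m, rna = TRUE), sample(0:5, 1))
    de <- fold_duplex(m, site)$energy
    pe <- fold_duplex(m, revcomp(m, rna = TRUE))$energy
    got <- apply_target_rules(score_duplex(m, site), de, pe)$accepted
    expect_identical(got, rule_oracle(m, site, de, pe), info = paste(m, site))
    n_match <- n_match + got
  }
  expect_gt(n_match, 0)  # the case mix exercises both verdicts
})

test_that("reversing both strands yields mirrored states and the same score", {
  set.seed(804)
  for (i in 1:25) {
    m <- random_rna(21)
    site <- mutate_site(revcomp(m, rna = TRUE), sample(0:4, 1))
    a <- score_duplex(m, site)
    b <- score_duplex(stringi_rev(m), stringi_rev(site))
    expect_identical(a$states, rev(b$states))
    expect_identical(a$mismatch_score, b$mismatch_score)
  }
})

test_that("transcript scanning finds planted sites and matches brute force", {
  set.seed(805)
  m <- random_rna(21)
  tx <- random_rna(400)
  pos <- 150
  substr(tx, pos + 1, pos + 21) <- revcomp(m)
  hits <- scan_transcripts(c(mir1 = m), c(tx1 = tx))
  planted <- dplyr::filter(hits, .data$site_start == pos)
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$mismatch_score, 0)

  # brute force: evaluate every window independently
  brute <- 0L
  pe <- fold_duplex(m, revcomp(m, rna = TRUE))$energy
  for (s in 0:(nchar(tx) - 21)) {
    w <- substr(tx, s + 1, s + 21)
    de <- fold_duplex(m, w)$energy
    if (rule_oracle(m, w, de, pe)) brute <- brute + 1L
  }
  expect_identical(nrow(hits), brute)

  expect_identical(nrow(scan_transcripts(character(0), c(tx1 = tx))), 0L)
  expect_error(scan_transcripts(c(mir1 = m), character(0)), "non-empty")
})

test_that("tightening the mismatch budget never adds hits", {
  set.seed(806)
  mirnas <- setNames(replicate(3, random_rna(21)), paste0("m", 1:3))
  tx <- vapply(1:4, function(i) {
    t <- random_rna(300)
    mm <- mutate_site(revcomp(sample(mirnas, 1), rna = TRUE), 2)
    substr(t, 51, 50 + nchar(mm)) <- gsub("U", "T", mm)
    t
  }, character(1))
  names(tx) <- paste0("t", 1:4)
  loose <- scan_transcripts(mirnas, tx,
                            target_rule_config(strict = FALSE))
  mid <- scan_transcripts(mirnas, tx,
                          target_rule_config(strict = TRUE,
                                             strict_max_mismatch = 2))
  tight <- scan_transcripts(mirnas, tx,
                            target_rule_config(strict = TRUE,
                                               strict_max_mismatch = 0))
  key <- function(h) paste(h$mirna_id, h$transcript_id, h$site_start)
  expect_true(all(key(mid) %in% key(loose)))
  expect_true(all(key(tight) %in% key(mid)))
  # mfe ratio is 1 exactly when the site is the perfect complement
  if (nrow(loose)) {
    expect_true(all(loose$mfe_ratio <= 1 + 1e-12))
    expect_identical(loose$mfe_ratio == 1, loose$mismatch_score == 0)
  }
})

test_that("the optional seed prefilter agrees with exhaustive scanning on seed-perfect sites", {
  set.seed(807)
  m <- random_rna(21)
  tx <- random_rna(300)
  substr(tx, 101, 121) <- revcomp(m)
  exhaustive <- scan_transcripts(c(a = m), c(t = tx))
  seeded <- scan_transcripts(c(a = m), c(t = tx), seed_length = 8L)
  expect_identical(
    dplyr::filter(seeded, .data$site_start == 100L),
    dplyr::filter(exhaustive, .data$site_start == 100L)
  )
})

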