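test_that("engine energy equals exhaustive structure enumeration on short sequences", {
  set.seed(301)
  for (i in 1:200) {
    s <- random_rna(sample(10:30, 1))
    eng <- fold_sequence(s)
    oracle <- lactomir:::enumerate_min_energy(s)
    expect_equal(eng$energy, oracle$energy, tolerance = 1e-9, info = s)
  }
})

test_that("returned structures are valid and consistent with their energy", {
  set.seed(302)
  for (i in 1:50) {
    s <- random_rna(sample(15:40, 1))
    f <- fold_sequence(s)
    partner <- f$partner
    paired <- which(partner > 0)
    # symmetric pairing map
    expect_true(all(partner[partner[paired]] == paired))
    # balanced dot-bracket
    db <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    # pairs are WC or G:U with min loop 3
    chars <- strsplit(f$sequence, "")[[1]]
    for (i2 in paired[partner[paired] > paired]) {
      j <- partner[i2]
      expect_gte(j - i2 - 1, 3)
      expect_true(paste0(chars[i2], chars[j]) %in%
                    c("AU", "UA", "CG", "GC", "GU", "UG"))
    }
    # energy non-positive; zero iff no pairs
    expect_lte(f$energy, 0)
    expect_identical(f$energy == 0, length(paired) == 0L)
    # reported energy matches an independent scoring of the reported fold
    expect_equal(f$energy, score_fold_from_partner(s, partner),
                 tolerance = 1e-9)
  }
})

test_that("hairpin energy decreases strictly with stem length", {
  set.seed(303)
  stem_full <- random_rna(25)
  loop <- random_rna(8)
  energies <- vapply(10:25, function(k) {
    stem <- substr(stem_full, 1, k)
    fold_sequence(paste0(stem, loop, revcomp(stem, rna = TRUE)))$energy
  }, numeric(1))
  expect_true(all(diff(energies) < 0))
  expect_lt(energies[length(energies)], -18)
})

test_that("degenerate and invalid folding inputs are handled", {
  f <- fold_sequence(strrep("A", 20))
  expect_identical(f$energy, 0)
  expect_identical(f$structure, strrep(".", 20))
  expect_error(fold_sequence("ACGUACGXAC GU"), "invalid characters")
  expect_error(fold_sequence("ACGUA"), "at least 10 nt")
})

test_that("duplex energies match exhaustive offset enumeration", {
  # independent oracle: score every antiparallel ungapped offset directly
  duplex_oracle <- function(a, b, init = 4.1,
                            tab = default_stack_energies()) {
    pt_of <- function(x, y) {
      key <- paste0(x, y)
      unname(c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)[key])
    }
    ac <- strsplit(gsub("T", "U", toupper(a)), "")[[1]]
    bc <- rev(strsplit(gsub("T", "U", toupper(b)), "")[[1]])
    best <- 0
    for (off in (-(length(ac) - 1)):(length(bc) - 1)) {
      e <- 0
      run_len <- 0
      run_e <- 0
      prev_pt <- NA
      for (i in seq_along(ac)) {
        j <- i + off
        p <- if (j >= 1 && j <= length(bc)) pt_of(ac[i], bc[j]) else NA
        if (!is.na(p)) {
          run_len <- run_len + 1
          if (run_len > 1) run_e <- run_e + tab[prev_pt, p]
          prev_pt <- p
        } else {
          if (run_len >= 2) e <- e + init + run_e
          run_len <- 0; run_e <- 0; prev_pt <- NA
        }
      }
      if (run_len >= 2) e <- e + init + run_e
      best <- min(best, e)
    }
    best
  }
  set.seed(304)
  for (i in 1:100) {
    a <- random_rna(sample(6:15, 1))
    b <- random_rna(sample(6:15, 1))
    expect_equal(fold_duplex(a, b)$energy, duplex_oracle(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("perfect-complement duplexes pair fully and beat mismatched sites", {
  set.seed(305)
  for (i in 1:20) {
    m <- random_rna(22)
    d <- fold_duplex(m, revcomp(m, rna = TRUE))
    expect_identical(nrow(d$pairs), 22L)
    # one internal true mismatch (neither WC nor wobble) destabilises the
    # duplex
    site <- revcomp(m, rna = TRUE)
    pos <- 11
    mb <- substr(m, nchar(m) - pos + 1, nchar(m) - pos + 1)
    wobble <- c(G = "U", U = "G")[mb]
    choices <- setdiff(c("A", "C", "G", "U"),
                       c(revcomp(mb, rna = TRUE), wobble))
    substr(site, pos, pos) <- choices[sample.int(length(choices), 1)]
    expect_gt(fold_duplex(m, site)$energy, d$energy)
  }
  expect_error(fold_duplex("", "ACGU"), "non-empty")
})

test_that("dinucleotide shuffles preserve exact dinucleotide counts", {
  dinuc_counts <- function(codes) {
    table(paste0(codes[-length(codes)], codes[-1]))
  }
  set.seed(306)
  for (i in 1:50) {
    codes <- lactomir:::encode_rna(random_rna(sample(10:60, 1)))
    shuf <- lactomir:::dinucleotide_shuffle(codes)
    expect_identical(dinuc_counts(shuf), dinuc_counts(codes))
    expect_identical(shuf[1], codes[1])
    expect_identical(shuf[length(shuf)], codes[length(codes)])
  }
})

test_that("shuffle test gives extreme P for a perfect stem and 1 for homopolymers", {
  set.seed(307)
  hp <- make_hairpin(30, 8)
  st <- shuffle_test(hp, n_shuffles = 99, seed = 7)
  expect_equal(st$p_value, 1 / 100)
  expect_true(all(st$shuffled_energies > st$observed))

  st_a <- shuffle_test(strrep("A", 30), n_shuffles = 19, seed = 1)
  expect_identical(st_a$p_value, 1)

  st2 <- shuffle_test(hp, n_shuffles = 99, seed = 7)
  expect_identical(st, st2)
  expect_error(shuffle_test(hp, n_shuffles = 5), "at least 19")
  expect_error(shuffle_test("ACG", n_shuffles = 19), "too short")
})

test_that("shuffle-test P always lies in [1/(n+1), 1]", {
  set.seed(308)
  for (i in 1:10) {
    st <- shuffle_test(random_rna(40), n_shuffles = 19, seed = i)
    expect_gte(st$p_value, 1 / 20)
    expect_lte(st$p_value, 1)
  }
})

test_that("hairpin geometry reads arm, pairing and spacing off the fold", {
  set.seed(309)
  stem <- random_rna(22)
  loop <- random_rna(8)
  hp <- paste0(stem, loop, revcomp(stem, rna = TRUE))
  f <- fold_sequence(hp)
  g <- hairpin_geometry(f, 1, 22)
  expect_identical(g$arm, "5p")
  expect_identical(g$n_pairs, 22L)
  expect_identical(g$max_bulge, 0L)
  expect_identical(g$asymmetry, 0L)
  expect_identical(g$space, 8L)

  # the 3' arm mature mirrors the geometry
  g3 <- hairpin_geometry(f, 31, 52)
  expect_identical(g3$arm, "3p")
  expect_identical(g3$n_pairs, 22L)

  # an interval across the loop is disqualifying
  gl <- hairpin_geometry(f, 15, 40)
  expect_identical(gl$arm, "loop_spanning")

  expect_error(hairpin_geometry(f, 0, 10), "out of range")
  expect_error(hairpin_geometry(f, 40, 200), "out of range")
})

test_that("planted precursor geometry matches its construction", {
  run <- small_run()
  mir <- run$tg$mirnas
  for (i in seq_len(nrow(mir))) {
    f <- fold_sequence(mir$precursor_seq[i])
    mlen <- nchar(mir$mature_seq[i])
    g <- hairpin_geometry(f, 1, mlen)
    expect_identical(g$arm, "5p")
    expect_identical(g$n_pairs, as.integer(mlen))
    expect_identical(g$max_bulge, 0L)
    expect_identical(g$asymmetry, 0L)
    # mature occupies the arm from its 5' end, so the mature/star spacing is
    # the loop plus the unused remainder of both stem arms
    expect_identical(g$space,
                     2L * (mir$stem_len[i] - mlen) + mir$loop_len[i])
  }
})
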