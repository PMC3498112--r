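# the published two-library worked rows used throughout: counts are inputs,
# everything else is recomputed
N1 <- 19044002
N2 <- 7385833

# miR-378e peak NE is 34,391.56: truncation gives 34,391 (the one cell where
# published renderings round instead; truncation is this package's convention)
table2_rows <- tibble::tribble(
  ~mirna_id,      ~count_peak, ~count_late, ~ne_peak, ~ne_late, ~fc,    ~sig,
  "miR-143",      3663628L,    2501394L,    192377,   338674,   0.82,   "#",
  "miR-148a-3p",  1948637L,    193553L,     102322,   26205,    -1.97,  "*",
  "miR-378e",     654953L,     511109L,     34391,    69201,    1.01,   "*"
)

table3_rows <- tibble::tribble(
  ~mirna_id,   ~count_peak, ~count_late, ~ne_peak, ~ne_late, ~fc,     ~sig,
  "miR-17a*",  0L,          54914L,      0.01,     7435,     19.50,   "**",
  "miR-5425",  0L,          6766L,       0.01,     916,      16.48,   "**",
  "miR-881",   29370L,      0L,          1542,     0.01,     -17.23,  "**"
)

test_that("normalization truncates reported NE toward zero as published", {
  expect_identical(floor(normalize_expression(3663628, N1)), 192377)
  expect_identical(floor(normalize_expression(1948637, N1)), 102322)
  expect_identical(floor(normalize_expression(6766, N2)), 916)
  expect_identical(floor(normalize_expression(54914, N2)), 7435)
  expect_identical(normalize_expression(0, N1), 0)
  expect_error(normalize_expression(5, 0), "positive")
  expect_error(normalize_expression(-1, 10), "non-negative")
})

test_that("full-precision NE sums to one million when counts exhaust the library", {
  set.seed(701)
  counts <- as.vector(stats::rmultinom(1, size = 50000, prob = runif(40)))
  expect_equal(sum(normalize_expression(counts, sum(counts))), 1e6)
})

test_that("zero-substitution and removal rules behave as specified", {
  r <- apply_zero_and_removal_rules(0, 7435)
  expect_identical(r$ne_peak, 0.01)
  expect_identical(r$ne_late, 7435)
  expect_false(r$removed)
  expect_true(apply_zero_and_removal_rules(0.5, 0.8)$removed)
  r00 <- apply_zero_and_removal_rules(0, 0)
  expect_identical(c(r00$ne_peak, r00$ne_late), c(0.01, 0.01))
  expect_true(r00$removed)
})

test_that("fold change reproduces the published worked values", {
  expect_identical(round(fold_change(192377, 338674), 2), 0.82)
  expect_identical(round(fold_change(0.01, 7435), 2), 19.50)
  expect_identical(round(fold_change(1542, 0.01), 2), -17.23)
  expect_error(fold_change(0, 10), "positive")
})

test_that("the differential table reproduces every published example cell", {
  rows <- dplyr::bind_rows(table2_rows, table3_rows)
  de <- differential_table(rows[, 1:3], N1, N2)
  got <- dplyr::left_join(rows, tidy(de), by = "mirna_id",
                          suffix = c("_exp", "_got"))
  expect_equal(got$ne_peak_got, got$ne_peak_exp)
  expect_equal(got$ne_late_got, got$ne_late_exp)
  expect_equal(got$fold_change, got$fc)
  expect_identical(got$sig_level, got$sig)
  expect_true(all(got$p_value < 0.01))
})

test_that("Audic-Claverie P matches the arbitrary-precision oracle", {
  # oracle: the conditional law is negative binomial with size x+1 and
  # success probability N1/(N1+N2) -- an independent closed-form route
  set.seed(702)
  for (i in 1:100) {
    x <- rpois(1, sample(c(2, 20, 200, 2000), 1))
    y <- rpois(1, sample(c(2, 20, 200, 2000), 1))
    n1 <- sample(1e5:2e6, 1)
    n2 <- sample(1e5:2e6, 1)
    # same canonical orientation as the statistic: condition on the larger
    # count (ties: larger library)
    if (y > x || (y == x && n2 > n1)) {
      tmp <- x; x <- y; y <- tmp
      tmp <- n1; n1 <- n2; n2 <- tmp
    }
    p_lo <- stats::pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
    p_hi <- if (y > 0) {
      stats::pnbinom(y - 1, size = x + 1, prob = n1 / (n1 + n2),
                     lower.tail = FALSE)
    } else 1
    oracle <- min(1, 2 * min(p_lo, p_hi))
    got <- count_pvalue(x, y, n1, n2)
    expect_equal(got, oracle, tolerance = 1e-10, info = paste(x, y, n1, n2))
  }
})

test_that("Audic-Claverie P is symmetric, bounded and tail-monotone", {
  set.seed(703)
  for (i in 1:25) {
    x <- sample(0:500, 1); y <- sample(0:500, 1)
    n1 <- sample(1e4:1e6, 1); n2 <- sample(1e4:1e6, 1)
    p1 <- count_pvalue(x, y, n1, n2)
    p2 <- count_pvalue(y, x, n2, n1)
    expect_equal(p1, p2, tolerance = 1e-9)
    expect_gte(p1, 0); expect_lte(p1, 1)
  }
  # moving y away from its conditional expectation shrinks P
  x <- 100; n1 <- n2 <- 1e6
  ys <- c(100, 150, 250, 500, 1000)
  ps <- count_pvalue(x, ys, n1, n2)
  expect_true(all(diff(ps) < 0))
  # extreme tail
  expect_lt(count_pvalue(1000, 10, 1e6, 1e6), 0.01)
  # closed form for equal libraries: P(Y <= 0 | x = 5) = (1/2)^6
  expect_equal(count_pvalue(5, 0, 1e6, 1e6), 2 * 0.5^6, tolerance = 1e-12)
})

test_that("swapping the libraries negates every fold change", {
  set.seed(704)
  counts <- tibble::tibble(mirna_id = sprintf("m%02d", 1:30),
                           count_peak = rpois(30, 300),
                           count_late = rpois(30, 300))
  fwd <- differential_table(counts, 1e6, 2e6)
  rev <- differential_table(
    dplyr::rename(counts, count_peak = "count_late",
                  count_late = "count_peak"),
    2e6, 1e6
  )
  m <- dplyr::left_join(tidy(fwd), tidy(rev), by = "mirna_id")
  expect_equal(m$fold_change.x, -m$fold_change.y)
})

test_that("removal and significance flags interact correctly", {
  counts <- tibble::tibble(
    mirna_id = c("kept_weak", "removed", "one_lib"),
    count_peak = c(40L, 3L, 0L),
    count_late = c(50L, 2L, 4000L)
  )
  de <- differential_table(counts, 1e7, 1e7)
  td <- tidy(de)
  expect_true(td$removed[td$mirna_id == "removed"])
  expect_identical(td$sig_level[td$mirna_id == "removed"], NA_character_)
  expect_identical(td$sig_level[td$mirna_id == "one_lib"], "**")
  expect_identical(td$sig_level[td$mirna_id == "kept_weak"], "#")
  g <- glance(de)
  expect_identical(g$n, 3L)
  expect_identical(g$n_removed, 1L)
  expect_identical(g$n_significant, 1L)
})
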