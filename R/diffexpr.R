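#' Normalized expression in transcripts per million
#'
#' `NE = count / total * 1e6`.  The full-precision value is returned;
#' reported tables use truncation toward zero (see [differential_table()]),
#' which is the convention that reproduces published two-library summary
#' tables.
#'
#' @param count Read count(s) for the entity.
#' @param total Total clean reads of the library (> 0).
#' @return Numeric NE value(s), full precision.
#' @export
#' @examples
#' floor(normalize_expression(3663628, 19044002))  # 192377
normalize_expression <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total * 1e6
}

#' Zero-substitution and removal rules for a pair of NE values
#'
#' An NE of zero is replaced by 0.01; an entity whose NE is below 1 in both
#' libraries is flagged for removal from the differential analysis.
#'
#' @param ne_peak,ne_late Normalized expression values (vectors allowed).
#' @return Tibble with `ne_peak`, `ne_late` (substituted) and `removed`.
#' @export
#' @examples
#' apply_zero_and_removal_rules(0, 7435)
apply_zero_and_removal_rules <- function(ne_peak, ne_late) {
  stopifnot(all(ne_peak >= 0), all(ne_late >= 0))
  removed <- ne_peak < 1 & ne_late < 1
  tibble::tibble(
    ne_peak = ifelse(ne_peak == 0, 0.01, ne_peak),
    ne_late = ifelse(ne_late == 0, 0.01, ne_late),
    removed = removed
  )
}

#' Log2 fold change between late and peak expression
#'
#' `log2(ne_late / ne_peak)`, on substituted values (both inputs must be
#' positive); negative values mean down-regulation in the late library.
#'
#' @param ne_peak,ne_late Substituted NE values (> 0).
#' @return Numeric log2 ratio(s), full precision.
#' @export
#' @examples
#' round(fold_change(0.01, 7435), 2)  # 19.50
fold_change <- function(ne_peak, ne_late) {
  if (any(ne_peak <= 0) || any(ne_late <= 0)) {
    stop("fold_change() requires positive (substituted) NE values")
  }
  log2(ne_late / ne_peak)
}

# log P(Y = k | x) under the Audic-Claverie conditional law
# p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))
ac_log_pmf <- function(k, x, log_p1, log_p2) {
  lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) +
    (x + 1) * log_p1 + k * log_p2
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Audic-Claverie two-library count P-value
#'
#' Exact conditional test for a difference in counts between two sequencing
#' libraries of sizes `N1` and `N2`: given `x` reads in the first library,
#' the count in the second follows
#' `p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`.  The
#' two-sided P-value is `min(1, 2 min(P(Y <= y | x), P(Y >= y | x)))`.  The
#' conditioning direction is canonicalised (condition on the larger count,
#' ties broken by the larger library), which makes the statistic exactly
#' symmetric under swapping the libraries.  All summation is done in log
#' space, so extreme counts (millions of reads) do not overflow or lose the
#' small tail.
#'
#' @param x,y Read counts in the peak and late libraries (non-negative
#'   integers; vectors allowed).
#' @param n1,n2 Total clean reads in the peak and late libraries.
#' @return Two-sided P-value(s) in `[0, 1]`.
#' @export
#' @examples
#' count_pvalue(1000, 10, 1e6, 1e6) < 0.01
count_pvalue <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  args <- vctrs_recycle(x, y, n1, n2)
  mapply(count_pvalue_one, args$x, args$y, args$n1, args$n2)
}

vctrs_recycle <- function(x, y, n1, n2) {
  n <- max(length(x), length(y), length(n1), length(n2))
  list(x = rep_len(x, n), y = rep_len(y, n),
       n1 = rep_len(n1, n), n2 = rep_len(n2, n))
}

count_pvalue_one <- function(x, y, n1, n2) {
  # canonical orientation: condition on the larger count (ties broken by the
  # larger library), making the two-sided statistic exactly symmetric in
  # (x, N1) <-> (y, N2)
  if (y > x || (y == x && n2 > n1)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  log_p1 <- log(n1) - log(n1 + n2)  # log(1/(1+r))
  log_p2 <- log(n2) - log(n1 + n2)  # log(r/(1+r))
  mean_y <- (x + 1) * r
  sd_y <- sqrt((x + 1) * r * (1 + r))

  lower <- function(yy) {       # log P(Y <= yy)
    if (yy < 0) return(-Inf)
    log_sum_exp(ac_log_pmf(0:yy, x, log_p1, log_p2))
  }
  upper <- function(yy) {       # log P(Y >= yy), summed upward to convergence
    hi <- max(yy, ceiling(mean_y + 20 * sd_y)) + 50
    log_sum_exp(ac_log_pmf(yy:hi, x, log_p1, log_p2))
  }
  # evaluate the cheaper tail exactly; derive the other from it when it is
  # the numerically safe direction
  if (y <= mean_y) {
    p_lo <- exp(lower(y))
    p_hi <- min(1, exp(upper(y)))
  } else {
    p_hi <- exp(upper(y))
    p_lo <- min(1, exp(lower(y)))
  }
  min(1, 2 * min(p_lo, p_hi))
}

#' Two-library differential expression table
#'
#' Applies the full rule set to per-miRNA counts: reads-per-million
#' normalization against the library clean totals, truncation of reported
#' NE toward zero, zero-substitution with 0.01, removal of entities below 1
#' in both libraries, `log2(late/peak)` fold change on the substituted
#' reported values, the Audic-Claverie count P-value, and significance
#' flags: `#` when `P >= p_cut` or `|log2 FC| < fc_cut`, `*` when
#' `P < p_cut` and `|log2 FC| >= fc_cut`, upgraded to `**` when the entity
#' is detected in only one library (library-specific expression).
#'
#' @param counts Tibble with `mirna_id` (or `id`), `count_peak`,
#'   `count_late`.
#' @param total_peak,total_late Library clean-read totals (`N1`, `N2`).
#' @param p_cut,fc_cut Significance thresholds (defaults 0.01 and 1).
#' @param fc_basis `"reported"` (default) computes fold change on the
#'   truncated reported NE (falling back to full precision when truncation
#'   would reach zero for a non-zero count); `"full"` uses full-precision NE.
#' @return A tibble of class `mirna_de` with columns `mirna_id`,
#'   `count_peak`, `count_late`, `ne_peak`, `ne_late` (reported, substituted),
#'   `fold_change` (2 decimals), `p_value`, `sig_level`, `removed`; rows
#'   sorted by total reads.  Attributes `total_peak`/`total_late` record the
#'   library sizes.
#' @export
differential_table <- function(counts, total_peak, total_late,
                               p_cut = 0.01, fc_cut = 1,
                               fc_basis = c("reported", "full")) {
  fc_basis <- match.arg(fc_basis)
  if ("id" %in% names(counts) && !"mirna_id" %in% names(counts)) {
    counts <- rename(counts, mirna_id = "id")
  }
  stopifnot(all(c("mirna_id", "count_peak", "count_late") %in% names(counts)))

  ne_full_peak <- normalize_expression(counts$count_peak, total_peak)
  ne_full_late <- normalize_expression(counts$count_late, total_late)
  rep_peak <- floor(ne_full_peak)
  rep_late <- floor(ne_full_late)

  basis_peak <- if (fc_basis == "reported") {
    ifelse(rep_peak == 0 & counts$count_peak > 0, ne_full_peak, rep_peak)
  } else ne_full_peak
  basis_late <- if (fc_basis == "reported") {
    ifelse(rep_late == 0 & counts$count_late > 0, ne_full_late, rep_late)
  } else ne_full_late

  adj <- apply_zero_and_removal_rules(basis_peak, basis_late)
  fc <- round(fold_change(adj$ne_peak, adj$ne_late), 2)
  p <- count_pvalue(counts$count_peak, counts$count_late,
                    total_peak, total_late)
  sig <- dplyr::case_when(
    adj$removed ~ NA_character_,
    p >= p_cut | abs(fc) < fc_cut ~ "#",
    counts$count_peak == 0 | counts$count_late == 0 ~ "**",
    TRUE ~ "*"
  )
  out <- tibble::tibble(
    mirna_id = counts$mirna_id,
    count_peak = counts$count_peak,
    count_late = counts$count_late,
    ne_peak = ifelse(counts$count_peak == 0, 0.01, rep_peak),
    ne_late = ifelse(counts$count_late == 0, 0.01, rep_late),
    fold_change = fc,
    p_value = p,
    sig_level = sig,
    removed = adj$removed
  ) %>%
    arrange(desc(.data$count_peak + .data$count_late), .data$mirna_id)
  attr(out, "total_peak") <- total_peak
  attr(out, "total_late") <- total_late
  attr(out, "p_cut") <- p_cut
  attr(out, "fc_cut") <- fc_cut
  class(out) <- c("mirna_de", class(out))
  out
}

#' @export
#' @method tidy mirna_de
#' @rdname mirna_de_methods
tidy.mirna_de <- function(x, ...) {
  class(x) <- setdiff(class(x), "mirna_de")
  tibble::as_tibble(x)
}

#' Broom-style accessors for differential expression tables
#'
#' `tidy()` returns the per-miRNA table as a plain tibble; `glance()`
#' returns a one-row summary with the library totals and the numbers of
#' tested, removed, significant, up- and down-regulated entities.
#'
#' @param x A `mirna_de` table from [differential_table()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method glance mirna_de
#' @rdname mirna_de_methods
glance.mirna_de <- function(x, ...) {
  sig <- !is.na(x$sig_level) & x$sig_level %in% c("*", "**")
  tibble::tibble(
    n = nrow(x),
    n_removed = sum(x$removed),
    n_tested = sum(!x$removed),
    n_significant = sum(sig),
    n_up_late = sum(sig & x$fold_change > 0),
    n_down_late = sum(sig & x$fold_change < 0),
    total_peak = attr(x, "total_peak"),
    total_late = attr(x, "total_late")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a differential expression table as TSV
#'
#' Columns mirror the published layout: reads, normalized reads, fold
#' change, P-value and significance level per library pair.
#'
#' @param de A `mirna_de` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(tidy(de), path)
  invisible(path)
}
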