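#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `m` annotated genes among `n` target
#' candidates drawn from a background of `N` genes of which `M` carry the
#' term: `P(X >= m) = sum_{i=m}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n)`.
#' Computed by direct log-space summation of binomial coefficients.
#'
#' @param N Background size (all annotated genes).
#' @param n Target-gene candidates within the background.
#' @param M Background genes carrying the term.
#' @param m Target genes carrying the term.
#' @return The upper-tail probability in `[0, 1]` (`m = 0` gives 1).
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 3)
hypergeom_upper_tail <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || n > N || M > N || m > min(n, M)) {
    stop("invalid hypergeometric configuration: require m <= min(n, M), ",
         "n <= N, M <= N")
  }
  if (m == 0) return(1)
  i <- m:min(n, M)
  i <- i[n - i <= N - M]  # terms with impossible complements vanish
  if (!length(i)) return(0)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Multiple-testing correction of raw P-values
#'
#' Bonferroni (`min(1, P * k)`) or Benjamini-Hochberg step-up FDR, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Corrected P-values, same order as the input.
#' @export
correct_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Term enrichment of target genes against a background
#'
#' Computes, for every term in the map, the hypergeometric upper-tail
#' probability of the observed target-gene overlap, applies the requested
#' multiple-testing correction, and flags significant terms at `alpha`.
#' The published convention for this pipeline family uses Bonferroni with
#' `alpha = 0.5` for GO and BH-FDR with `alpha = 0.5` for KEGG; both
#' thresholds are permissive and a conventional 0.05 is available via
#' `alpha`.
#'
#' @param target_genes Character vector of target-gene candidates.
#' @param background_genes Character vector of all annotated genes (targets
#'   outside the background are dropped with a warning).
#' @param term_map Tibble with `gene_id`, `term_id` (and optionally
#'   `namespace`).
#' @param method Correction method: `"bonferroni"` (GO convention) or
#'   `"bh"` (KEGG convention).
#' @param alpha Significance threshold on the corrected value (default 0.5).
#' @return A tibble of class `term_enrichment`, sorted by corrected P:
#'   `term_id`, `N`, `n`, `M`, `m`, `p_value`, `p_corrected`, `significant`.
#' @export
enrich_terms <- function(target_genes, background_genes, term_map,
                         method = c("bonferroni", "bh"), alpha = 0.5) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)),
            nrow(term_map) > 0)
  background_genes <- unique(background_genes)
  target_genes <- unique(target_genes)
  missing <- setdiff(target_genes, background_genes)
  if (length(missing)) {
    warning(length(missing),
            " target gene(s) absent from the background were excluded")
    target_genes <- intersect(target_genes, background_genes)
  }
  term_map <- filter(term_map, .data$gene_id %in% background_genes)
  N <- length(background_genes)
  n <- length(target_genes)

  per_term <- term_map %>%
    distinct(.data$gene_id, .data$term_id) %>%
    group_by(.data$term_id) %>%
    summarise(M = dplyr::n(),
              m = sum(.data$gene_id %in% target_genes), .groups = "drop")
  p <- vapply(seq_len(nrow(per_term)), function(i) {
    hypergeom_upper_tail(N, n, per_term$M[i], per_term$m[i])
  }, numeric(1))
  out <- per_term %>%
    mutate(N = N, n = n, p_value = p,
           p_corrected = correct_pvalues(p, method),
           significant = .data$p_corrected <= alpha) %>%
    select("term_id", "N", "n", "M", "m", "p_value", "p_corrected",
           "significant") %>%
    arrange(.data$p_corrected, .data$p_value, .data$term_id)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  class(out) <- c("term_enrichment", class(out))
  out
}

#' @export
#' @method tidy term_enrichment
#' @rdname term_enrichment_methods
tidy.term_enrichment <- function(x, ...) {
  class(x) <- setdiff(class(x), "term_enrichment")
  tibble::as_tibble(x)
}

#' Broom-style accessors for enrichment results
#'
#' @param x A `term_enrichment` table from [enrich_terms()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method glance term_enrichment
#' @rdname term_enrichment_methods
glance.term_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    method = attr(x, "method"),
    alpha = attr(x, "alpha"),
    background = x$N[1],
    targets = x$n[1]
  )
}

#' Read a gene-to-term map from TSV
#'
#' Expects columns `gene_id`, `term_id` and optionally `namespace`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_term_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
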