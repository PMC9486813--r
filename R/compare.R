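# Reference-cohort comparison: from-scratch two-tailed Fisher exact test
# (point-probability definition, computed in log space) and
# Benjamini-Hochberg step-up FDR adjustment. Base fisher.test and p.adjust
# serve as independent cross-checks in the test suite, not as the
# implementation.

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Point-probability (conventional) two-sided definition: p is the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table,
#' within relative tolerance 1e-7. Probabilities are computed in log space
#' via `lchoose`, so large counts do not overflow. A table with a zero
#' variable margin (an empty row or column) is degenerate and returns 1.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("Fisher table cells must be non-negative")
  }
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  log_obs <- logp[match(a, support)]
  min(1, sum(exp(logp[logp <= log_obs + log1p(1e-7)])))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' p_adj(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j), clipped at
#' 1, returned in input order. Monotone (raising any raw p never lowers any
#' adjusted p) and permutation-equivariant.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Read a reference-cohort allele-count table
#'
#' @param path TSV with columns `contig`, `pos`, `ref`, `alt`,
#'   `alt_allele_count`, `total_alleles`.
#' @return Tibble with a `key` column.
#' @export
read_reference_counts <- function(path) {
  stopifnot_file(path, "Reference cohort counts")
  readr::read_tsv(path, col_types = readr::cols(
    contig = "c", pos = "i", ref = "c", alt = "c", alt_allele_count = "i",
    total_alleles = "i"
  ), progress = FALSE) |>
    mutate(key = variant_key(.data$contig, .data$pos, .data$ref, .data$alt))
}

#' Compare study allele counts against a reference cohort
#'
#' For each variant present in both cohorts, builds the 2x2 table of alt
#' versus non-alt alleles by cohort, computes the two-tailed Fisher exact
#' p-value, adjusts across the compared set with Benjamini-Hochberg (the FDR
#' family is the intersection), and flags significance at `alpha`. Variants
#' with zero total alleles on either side are skipped with a log entry.
#'
#' @param study Tibble: `key`, `allele_count`, `n_genotyped` (study alleles
#'   = 2 x n_genotyped).
#' @param reference Tibble from [read_reference_counts()].
#' @param alpha Significance level after adjustment (default 0.05).
#' @return List: `comparisons` (tibble with counts, `p_value`, `p_adjusted`,
#'   `significant`), `skipped` (tibble of zero-margin keys).
#' @export
compare_allele_counts <- function(study, reference, alpha = 0.05) {
  shared <- study |>
    mutate(study_alt = .data$allele_count,
           study_total = 2L * .data$n_genotyped) |>
    inner_join(reference |>
                 select("key", ref_alt = "alt_allele_count",
                        ref_total = "total_alleles"),
               by = "key")
  skipped <- shared |> filter(.data$study_total == 0 | .data$ref_total == 0)
  ok <- shared |> filter(.data$study_total > 0 & .data$ref_total > 0)
  if (nrow(ok) == 0) {
    return(list(comparisons = ok, skipped = skipped))
  }
  p <- purrr::pmap_dbl(
    list(ok$study_alt, ok$study_total, ok$ref_alt, ok$ref_total),
    function(sa, st, ra, rt) fisher_exact_2x2(sa, st - sa, ra, rt - ra)
  )
  ok$p_value <- p
  ok$p_adjusted <- adjust_bh(p)
  ok$significant <- ok$p_adjusted < alpha
  list(
    comparisons = ok |>
      select("key", "study_alt", "study_total", "ref_alt", "ref_total",
             "p_value", "p_adjusted", "significant"),
    skipped = skipped |> select("key")
  )
}
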