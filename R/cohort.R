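# Cohort definition and carrier statistics: sample QC, phenotype-based
# exclusion, genotype counting, allele frequencies, per-gene combined
# summaries across molecular mechanisms, and carrier categorization by
# inheritance implication.

# Printed comparator per metric: direction and strictness follow the QC
# protocol exactly (mapped reads > 98 strict; coverage >= 20 inclusive; ...).
SAMPLE_QC_RULES <- tibble::tribble(
  ~metric,                    ~op,  ~threshold,
  "mapped_read_pct",          ">",  98,
  "autosome_median_coverage", ">=", 20,
  "uniformity_pct",           ">=", 80,
  "contamination_pct",        "<",  2,
  "callability_pct",          ">=", 95,
  "q30_pct",                  ">=", 90,
  "chimeric_pct",             "<",  5,
  "duplicate_pct",            "<",  10
)

#' Apply sample-level sequencing QC
#'
#' An individual passes only if all eight metrics satisfy their printed
#' comparators: mapped reads > 98% (strict), autosome median coverage >= 20X,
#' uniformity >= 80%, contamination < 2% (strict), autosome callability
#' >= 95%, Q30 >= 90%, chimeric reads < 5% (strict), duplicates < 10%
#' (strict). Boundary values follow the comparator (exactly 20X coverage
#' passes; exactly 98% mapped reads fails).
#'
#' @param qc Tibble with `sample_id` and the eight metric columns.
#' @return List: `passing`, `failing` (with a `failed_metrics` column).
#' @export
apply_sample_qc <- function(qc) {
  missing_cols <- setdiff(c("sample_id", SAMPLE_QC_RULES$metric), names(qc))
  if (length(missing_cols) > 0) {
    abort(sprintf("Sample QC table missing metric(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(qc[SAMPLE_QC_RULES$metric])) {
    abort("Missing sample QC metric value")
  }
  fail_mat <- vapply(seq_len(nrow(SAMPLE_QC_RULES)), function(i) {
    v <- qc[[SAMPLE_QC_RULES$metric[i]]]
    t <- SAMPLE_QC_RULES$threshold[i]
    !switch(SAMPLE_QC_RULES$op[i],
            ">" = v > t, ">=" = v >= t, "<" = v < t, "<=" = v <= t)
  }, logical(nrow(qc)))
  fail_mat <- matrix(fail_mat, nrow = nrow(qc))
  any_fail <- rowSums(fail_mat) > 0
  failing <- qc[any_fail, , drop = FALSE]
  failing$failed_metrics <- apply(
    fail_mat[any_fail, , drop = FALSE], 1,
    function(r) paste(SAMPLE_QC_RULES$metric[r], collapse = ",")
  )
  list(passing = qc[!any_fail, , drop = FALSE], failing = failing)
}

#' Split a cohort by hearing-loss phenotype terms
#'
#' An individual is affected iff its HPO term set intersects the
#' hearing-loss term list; the unaffected cohort is the complement and is
#' the basis for all population statistics.
#'
#' @param individuals Tibble with `sample_id` and `hpo_terms` (list-column
#'   or `;`-separated string of HPO ids).
#' @param hl_terms Character vector of hearing-loss HPO ids (non-empty).
#' @return List: `unaffected`, `affected` tibbles.
#' @export
split_by_phenotype <- function(individuals, hl_terms) {
  if (length(hl_terms) == 0) abort("hl_terms must be non-empty")
  terms <- individuals$hpo_terms
  if (!is.list(terms)) {
    terms <- stringr::str_split(dplyr::coalesce(terms, ""), ";")
  }
  affected <- purrr::map_lgl(terms, ~ any(.x %in% hl_terms))
  list(unaffected = individuals[!affected, , drop = FALSE],
       affected = individuals[affected, , drop = FALSE])
}

#' Count genotypes for retained variants
#'
#' Tallies heterozygotes, homozygotes and hemizygotes per variant among
#' non-missing genotype calls of the screened cohort. Hemizygous calls
#' (male X) are book-kept separately and contribute one allele each.
#'
#' @param calls QC-retained long call tibble restricted to the cohort.
#' @param keys Variant keys to count (default: all keys present).
#' @param n_cohort Number of individuals in the screened cohort (genotype
#'   denominators; samples with a missing call at a variant are subtracted
#'   per variant).
#' @return Tibble: `key`, `het_count`, `hom_count`, `hemi_count`,
#'   `n_genotyped`, `allele_count`.
#' @export
count_genotypes <- function(calls, keys = NULL, n_cohort) {
  if (is.null(keys)) keys <- unique(calls$key)
  counts <- calls |>
    filter(.data$key %in% keys) |>
    group_by(.data$key) |>
    summarise(
      het_count = sum(.data$genotype == "het"),
      hom_count = sum(.data$genotype == "hom_alt"),
      hemi_count = sum(.data$genotype == "hemi_alt"),
      n_missing = sum(.data$genotype == "missing"),
      n_seen = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      n_genotyped = n_cohort - .data$n_missing,
      allele_count = .data$het_count + 2L * .data$hom_count +
        .data$hemi_count
    ) |>
    select(-"n_missing", -"n_seen")
  # Variants with no call rows at all: fully reference-typed.
  absent <- setdiff(keys, counts$key)
  if (length(absent) > 0) {
    counts <- bind_rows(counts, tibble(
      key = absent, het_count = 0L, hom_count = 0L, hemi_count = 0L,
      n_genotyped = n_cohort, allele_count = 0L
    ))
  }
  counts
}

#' Allele frequency from genotype counts
#'
#' AF = (het + 2 x hom + hemi) / (2 x n_genotyped). Internal values are kept
#' at full precision; report display rounds half-up to two decimals in
#' percent (28 het + 1 hom among 2,097 -> 30/4,194 = 0.7153% -> "0.72%").
#'
#' @param het_count,hom_count Genotype counts.
#' @param n_genotyped Individuals genotyped for the variant (> 0).
#' @param hemi_count Hemizygote count (default 0).
#' @return Allele frequency as a fraction.
#' @export
allele_frequency <- function(het_count, hom_count, n_genotyped,
                             hemi_count = 0L) {
  if (any(n_genotyped <= 0)) abort("n_genotyped must be positive")
  (het_count + 2 * hom_count + hemi_count) / (2 * n_genotyped)
}

#' Per-gene combined carrier summary across molecular mechanisms
#'
#' Sums pathogenic allele counts over each gene's P/LP variants separately
#' for sequence variants, CNVs, and both combined. The combined allele
#' frequency divides total alleles by 2 x `n_cohort`; allele-count
#' aggregation (not AF summing) is authoritative, so shared carriers of two
#' variants in one gene are never double-counted at the allele level.
#'
#' @param variant_counts Tibble: `gene_symbol`, `key`, `mechanism`
#'   ("sequence" or "cnv"), `het_count`, `hom_count`, `allele_count`.
#' @param n_cohort Cohort size (AF denominator is 2 x n_cohort).
#' @return Tibble: per gene x mechanism (sequence, cnv, combined) rows with
#'   `n_variants`, `het_count`, `hom_count`, `allele_count`, `combined_af`.
#' @export
summarize_gene_burden <- function(variant_counts, n_cohort) {
  per_mech <- variant_counts |>
    group_by(.data$gene_symbol, .data$mechanism) |>
    summarise(
      n_variants = dplyr::n_distinct(.data$key),
      het_count = sum(.data$het_count),
      hom_count = sum(.data$hom_count),
      allele_count = sum(.data$allele_count),
      .groups = "drop"
    )
  combined <- variant_counts |>
    group_by(.data$gene_symbol) |>
    summarise(
      mechanism = "combined",
      n_variants = dplyr::n_distinct(.data$key),
      het_count = sum(.data$het_count),
      hom_count = sum(.data$hom_count),
      allele_count = sum(.data$allele_count),
      .groups = "drop"
    )
  bind_rows(per_mech, combined) |>
    mutate(combined_af = .data$allele_count / (2 * n_cohort)) |>
    arrange(.data$gene_symbol, .data$mechanism)
}

#' Categorize carrier individuals by inheritance implication
#'
#' Assigns each heterozygous carrier one category with the precedence
#' AD_only > AD_AR_gene > AR_only: `AD_only` if any carried variant's gene is
#' associated exclusively with dominant inheritance, else `AD_AR_gene` if any
#' gene carries both dominant and recessive modes, else `AR_only`. The
#' AD-implicated set (carriers who may themselves develop hearing impairment)
#' is AD_only plus AD_AR_gene carriers; the recessive-implicated set is
#' carriers of any variant in a gene with a recessive mode.
#'
#' @param carriers Tibble: `sample_id`, `gene_symbol`, `mechanism` — one row
#'   per carried heterozygous variant (homozygotes are tallied separately and
#'   must not be included).
#' @param retained_panel Retained panel tibble (for gene mode sets).
#' @return List: `per_individual` (sample_id, category), `tallies`
#'   (category, n), `n_ad_implicated`, `n_recessive_implicated`.
#' @export
classify_carriers <- function(carriers, retained_panel) {
  classes <- gene_inheritance_class(retained_panel)
  joined <- carriers |>
    left_join(classes, by = "gene_symbol")
  if (anyNA(joined$class)) {
    abort(sprintf("Carrier variant in gene absent from retained panel: %s",
                  joined$gene_symbol[is.na(joined$class)][1]))
  }
  per_ind <- joined |>
    group_by(.data$sample_id) |>
    summarise(
      category = if (any(.data$class == "AD")) "AD_only"
      else if (any(.data$class == "AD/AR")) "AD_AR_gene"
      else if (any(.data$class == "AR")) "AR_only"
      else "none",
      .groups = "drop"
    )
  tallies <- per_ind |>
    count(.data$category, name = "n")
  ad_set <- joined |>
    filter(.data$class %in% c("AD", "AD/AR")) |>
    pull(.data$sample_id)
  ar_set <- joined |>
    filter(.data$class %in% c("AR", "AD/AR")) |>
    pull(.data$sample_id)
  list(
    per_individual = per_ind,
    tallies = tallies,
    n_ad_implicated = dplyr::n_distinct(ad_set),
    n_recessive_implicated = dplyr::n_distinct(ar_set)
  )
}
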