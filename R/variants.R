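# Sequence-variant screening: catalogue preselection on pathogenicity class,
# per-call depth QC, per-variant call-rate QC, curation decisions, and the
# mitochondrial lookup screen.

AGGREGATE_CLASSES <- c("P", "LP", "conflicting", "VUS", "LB", "B")
FINAL_CLASSES <- c("P", "LP", "VUS", "LB", "B")
GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")

#' Read a ClinVar-style variant catalogue
#'
#' @param path TSV with columns `contig`, `pos` (1-based, VCF convention),
#'   `ref`, `alt`, `gene_symbol`, `hgvs_c`, `hgvs_p`, `aggregate_class`
#'   (P/LP/conflicting/VUS/LB/B) and `any_plp_submitter` (0/1: at least one
#'   submitter classified the variant P or LP).
#' @return Tibble with a `key` column (`contig:pos:ref:alt`).
#' @export
read_variant_catalogue <- function(path) {
  stopifnot_file(path, "Variant catalogue")
  cat <- readr::read_tsv(path, col_types = readr::cols(
    contig = "c", pos = "i", ref = "c", alt = "c", gene_symbol = "c",
    hgvs_c = "c", hgvs_p = "c", aggregate_class = "c",
    any_plp_submitter = "i"
  ), progress = FALSE)
  bad <- setdiff(unique(cat$aggregate_class), AGGREGATE_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown aggregate_class label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(cat$ref == cat$alt)) abort("Catalogue record with ref == alt")
  if (any(cat$pos < 1L)) abort("Catalogue record with pos < 1")
  cat |>
    mutate(key = variant_key(.data$contig, .data$pos, .data$ref, .data$alt),
           any_plp_submitter = .data$any_plp_submitter == 1L)
}

#' Read analyst curation decisions
#'
#' @param path TSV with columns `contig`, `pos`, `ref`, `alt`, `final_class`
#'   (P/LP/VUS/LB/B) and `acmg_criteria` (free text). One decision per
#'   variant key.
#' @return Tibble with a `key` column.
#' @export
read_curation_decisions <- function(path) {
  stopifnot_file(path, "Curation decisions")
  dec <- readr::read_tsv(path, col_types = readr::cols(
    contig = "c", pos = "i", ref = "c", alt = "c", final_class = "c",
    acmg_criteria = "c"
  ), progress = FALSE)
  bad <- setdiff(unique(dec$final_class), FINAL_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown final_class label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dec <- dec |>
    mutate(key = variant_key(.data$contig, .data$pos, .data$ref, .data$alt))
  if (anyDuplicated(dec$key)) {
    abort(sprintf("Multiple curation decisions for variant %s",
                  dec$key[duplicated(dec$key)][1]))
  }
  dec
}

#' Read a multi-sample VCF into long genotype calls
#'
#' Parses FORMAT fields GT and DP into one row per sample per site. Phased
#' (`|`) and unphased (`/`) separators are accepted; `./.` (or a one-sided
#' missing allele) is a missing genotype; a single-allele genotype on a sex
#' or mitochondrial contig is hemizygous. Multi-allelic sites must have been
#' decomposed upstream (an error is raised otherwise): matching downstream is
#' on the biallelic (contig, pos, ref, alt) key.
#'
#' @param path VCF 4.2+ file, plain text.
#' @param samples Optional character vector restricting parsed samples.
#' @return Tibble: `sample_id`, `key`, `contig`, `pos`, `genotype`
#'   (hom_ref/het/hom_alt/hemi_alt/missing), `depth` (integer reads, NA when
#'   absent).
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  stopifnot_file(path, "VCF")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("Multi-allelic VCF site found; decompose to biallelic records first")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  )
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (!is.null(samples)) {
    keep <- colnames(gt) %in% samples
    gt <- gt[, keep, drop = FALSE]
    dp <- dp[, keep, drop = FALSE]
  }
  keys <- variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
  n_var <- nrow(gt)
  n_smp <- ncol(gt)
  calls <- tibble(
    sample_id = rep(colnames(gt), each = n_var),
    key = rep(keys, times = n_smp),
    contig = rep(fix$CHROM, times = n_smp),
    pos = rep(as.integer(fix$POS), times = n_smp),
    genotype = classify_gt(as.vector(gt)),
    depth = as.integer(as.vector(dp))
  )
  calls
}

# Map VCF GT strings to genotype categories.
classify_gt <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  out <- rep("missing", length(g))
  out[g %in% c("0/0")] <- "hom_ref"
  out[g %in% c("0/1", "1/0")] <- "het"
  out[g %in% c("1/1")] <- "hom_alt"
  out[g %in% c("1")] <- "hemi_alt"
  out[g %in% c("0")] <- "hom_ref"
  out
}

#' Preselect candidate variants from a catalogue
#'
#' Keeps catalogue records whose gene is in the retained panel and whose
#' aggregate classification is pathogenic, likely pathogenic, or conflicting
#' with at least one P/LP submission. Benign, likely benign, VUS-only and
#' uncatalogued records are dropped. Records mapped to genes absent from the
#' panel are skipped and reported in the log.
#'
#' @param catalogue Tibble from [read_variant_catalogue()].
#' @param panel Retained panel tibble from [filter_gene_panel()].
#' @return List: `preselected` (tibble), `skipped_off_panel` (tibble of
#'   records whose gene is not on the panel).
#' @export
preselect_variants <- function(catalogue, panel) {
  panel_genes <- unique(panel$gene_symbol)
  on_panel <- catalogue$gene_symbol %in% panel_genes
  qualifies <- catalogue$aggregate_class %in% c("P", "LP") |
    (catalogue$aggregate_class == "conflicting" & catalogue$any_plp_submitter)
  list(
    preselected = catalogue[on_panel & qualifies, , drop = FALSE],
    skipped_off_panel = catalogue[!on_panel, , drop = FALSE]
  )
}

#' Apply per-call depth and per-variant call-rate quality control
#'
#' Calls with read depth below `min_depth` are set to missing (the printed
#' comparator is strict: "less than 20X" fails, exactly 20X passes). A
#' variant whose non-missing genotype fraction across `n_samples` falls below
#' `min_call_rate` is dropped entirely; the boundary is inclusive (a call
#' rate of exactly 0.95 is retained). Samples absent from `calls` for a
#' variant are counted as genotyped reference calls only if `calls` is
#' complete; pass the full call set for exact call rates.
#'
#' @param calls Long call tibble (from [read_vcf_genotypes()]), already
#'   restricted to the cohort being screened.
#' @param min_depth Minimum read depth per call (default 20).
#' @param min_call_rate Minimum per-variant genotyped fraction (default 0.95).
#' @param n_samples Call-rate denominator: number of individuals in the
#'   screened cohort.
#' @return List: `retained_calls` (tibble; depth-failed calls set to missing,
#'   low-call-rate variants removed), `dropped_variants` (tibble: key,
#'   call_rate).
#' @export
apply_call_qc <- function(calls, min_depth = 20, min_call_rate = 0.95,
                          n_samples) {
  if (missing(n_samples) || length(n_samples) != 1 || n_samples <= 0) {
    abort("n_samples must be a single positive integer")
  }
  calls <- calls |>
    mutate(genotype = if_else(
      !is.na(.data$depth) & .data$depth < min_depth,
      "missing", .data$genotype
    ))
  rate <- calls |>
    group_by(.data$key) |>
    summarise(
      n_called = sum(.data$genotype != "missing"),
      n_seen = dplyr::n(),
      .groups = "drop"
    ) |>
    # Samples without an explicit row are untyped only if the matrix is
    # sparse by construction; the VCF reader emits every sample, so n_seen
    # == n_samples there. For sparse inputs, absent rows count as called
    # reference genotypes.
    mutate(call_rate = (.data$n_called + (n_samples - .data$n_seen)) /
             n_samples)
  dropped <- rate |> filter(.data$call_rate < min_call_rate)
  list(
    retained_calls = calls |> anti_join(dropped, by = "key"),
    dropped_variants = dropped |> select("key", "call_rate")
  )
}

#' Apply curation decisions to preselected variants
#'
#' Every preselected variant must have an explicit final ACMG class; only
#' variants curated P or LP survive. A missing decision is an error naming
#' the variant, forcing explicit curation of every candidate.
#'
#' @param preselected Tibble of preselected variant records (with `key`).
#' @param decisions Tibble from [read_curation_decisions()].
#' @return Tibble of retained records with a `final_class` column (P or LP).
#' @export
apply_curation <- function(preselected, decisions) {
  missing_keys <- setdiff(preselected$key, decisions$key)
  if (length(missing_keys) > 0) {
    abort(sprintf("No curation decision for variant(s): %s",
                  paste(utils::head(missing_keys, 5), collapse = ", ")))
  }
  preselected |>
    inner_join(decisions |> select("key", "final_class"), by = "key") |>
    filter(.data$final_class %in% c("P", "LP"))
}

#' Screen calls against a mitochondrial lookup list
#'
#' Mitochondrial variants are not discovered; only a fixed list of variants
#' already associated with hearing loss is looked up. Matching is exact on
#' (contig, pos, ref, alt).
#'
#' @param calls Long call tibble.
#' @param mito_list Tibble of lookup records with a `key` column (contig
#'   `chrM`).
#' @return Calls (non-reference, non-missing) matching the lookup list.
#' @export
screen_mito <- function(calls, mito_list) {
  calls |>
    filter(.data$key %in% mito_list$key,
           .data$genotype %in% c("het", "hom_alt", "hemi_alt"))
}
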