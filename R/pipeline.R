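# Pipeline orchestration: one reproducible run from a single configuration,
# executing panel filtering -> sample QC -> phenotype exclusion -> sequence
# variant screen -> CNV screen -> carrier statistics -> Hardy-Weinberg
# projection -> ROH classification -> reference-cohort comparison, with
# every exclusion logged and a monotone entity funnel.

#' Validate a screen run configuration
#'
#' Checks input paths and threshold ranges without side effects and returns
#' every detectable problem.
#'
#' @param config List (or YAML path) with `paths` (panel, vcf, catalogue,
#'   decisions, cnv_calls, cnv_decisions, exons_bed, syndromic_bed, roh_bed,
#'   phenotype, sample_qc, reference_counts, mito_list) and `thresholds`
#'   (min_depth, min_call_rate, max_cnv_size_bp, alpha, autosome_length_mb,
#'   min_roh_len_bp).
#' @return Character vector of problems (empty when valid).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  needed <- c("panel", "vcf", "catalogue", "decisions", "cnv_calls",
              "cnv_decisions", "exons_bed", "syndromic_bed", "roh_bed",
              "phenotype", "sample_qc", "reference_counts", "mito_list")
  for (nm in needed) {
    path <- config$paths[[nm]]
    if (is.null(path)) {
      problems <- c(problems, sprintf("missing path entry: %s", nm))
    } else if (!file.exists(path)) {
      problems <- c(problems, sprintf("missing file (%s): %s", nm, path))
    }
  }
  th <- config$thresholds
  in_range <- function(name, lo, hi) {
    v <- th[[name]]
    if (is.null(v) || !is.numeric(v) || v < lo || v > hi) {
      problems <<- c(problems,
                     sprintf("threshold %s out of range [%g, %g]",
                             name, lo, hi))
    }
  }
  in_range("min_depth", 0, 1000)
  in_range("min_call_rate", 0, 1)
  in_range("max_cnv_size_bp", 1, 1e9)
  in_range("alpha", 0, 1)
  in_range("autosome_length_mb", 1, 10000)
  in_range("min_roh_len_bp", 0, 1e9)
  problems
}

#' Run the full carrier screen
#'
#' Executes every stage on the configured inputs and returns an
#' `nshl_screen` object whose components are the per-stage tibbles. When
#' `out_dir` is given, per-variant, per-gene, Hardy-Weinberg, ROH and
#' comparison tables are written as TSV alongside a machine-readable JSON
#' summary and a run log echoing every threshold.
#'
#' @param config List from [generate_cohort()]'s `run_config`, or a YAML
#'   path written by it.
#' @param out_dir Optional report directory.
#' @return An `nshl_screen` object; see [tidy.nshl_screen()],
#'   [glance.nshl_screen()] and [autoplot.nshl_screen()].
#' @export
run_screen <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_run_config(config)
  if (length(problems) > 0) {
    abort(paste(c("Invalid run configuration:", problems),
                collapse = "\n  "))
  }
  th <- config$thresholds
  hl_terms <- config$hl_terms %||% hl_hpo_terms()

  ## panel
  panel_raw <- read_gene_panel(config$paths$panel)
  pf <- filter_gene_panel(panel_raw)
  panel <- pf$retained
  panel_summary <- summarize_gene_panel(panel)

  ## samples
  qc_tab <- readr::read_tsv(config$paths$sample_qc,
                            col_types = readr::cols(sample_id = "c"),
                            progress = FALSE)
  sq <- apply_sample_qc(qc_tab)
  pheno <- readr::read_tsv(config$paths$phenotype,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE) |>
    semi_join(sq$passing, by = "sample_id")
  ph <- split_by_phenotype(pheno, hl_terms)
  unaffected_ids <- ph$unaffected$sample_id
  n_unaffected <- length(unaffected_ids)

  ## sequence variants
  catalogue <- read_variant_catalogue(config$paths$catalogue)
  decisions <- read_curation_decisions(config$paths$decisions)
  calls <- read_vcf_genotypes(config$paths$vcf, samples = unaffected_ids)
  candidate_keys <- catalogue$key[
    !catalogue$aggregate_class %in% c("B", "LB") &
      catalogue$gene_symbol %in% panel$gene_symbol
  ]
  cand_calls <- calls |> filter(.data$key %in% candidate_keys)
  call_qc <- apply_call_qc(cand_calls, min_depth = th$min_depth,
                           min_call_rate = th$min_call_rate,
                           n_samples = n_unaffected)
  detected_keys <- call_qc$retained_calls |>
    filter(.data$genotype %in% c("het", "hom_alt", "hemi_alt")) |>
    distinct(.data$key) |>
    pull()
  pres <- preselect_variants(catalogue, panel)$preselected |>
    filter(.data$key %in% detected_keys)
  retained_variants <- apply_curation(pres, decisions)

  seq_counts <- count_genotypes(
    call_qc$retained_calls |> filter(.data$key %in% retained_variants$key),
    keys = retained_variants$key, n_cohort = n_unaffected
  ) |>
    left_join(retained_variants |>
                select("key", "gene_symbol", "hgvs_c", "hgvs_p",
                       "final_class"),
              by = "key") |>
    mutate(allele_frequency = allele_frequency(
      .data$het_count, .data$hom_count, .data$n_genotyped,
      .data$hemi_count
    )) |>
    arrange(dplyr::desc(.data$allele_frequency), .data$key)

  mito_list <- readr::read_tsv(config$paths$mito_list,
                               col_types = readr::cols(
                                 contig = "c", pos = "i", ref = "c",
                                 alt = "c", .default = "c"
                               ), progress = FALSE) |>
    mutate(key = variant_key(.data$contig, .data$pos, .data$ref, .data$alt))
  mito_hits <- screen_mito(calls, mito_list)

  ## CNVs
  exon_map <- read_region_bed(config$paths$exons_bed)
  syndromic <- read_region_bed(config$paths$syndromic_bed)
  cnv_all <- read_cnv_calls(config$paths$cnv_calls)
  cnv_cohort <- cnv_all |> filter(.data$sample_id %in% unaffected_ids)
  cnv_coding <- filter_coding_overlap(cnv_cohort, exon_map)
  cnv_sz <- filter_cnv_size_syndromic(cnv_coding, syndromic,
                                      max_size_bp = th$max_cnv_size_bp)
  cnv_filtered <- cnv_sz$retained
  cnv_distinct_pre <- aggregate_recurrent_cnvs(cnv_filtered)
  cnv_decisions <- read_cnv_decisions(config$paths$cnv_decisions)
  cnv_relevant <- apply_cnv_curation(cnv_filtered, cnv_decisions)
  cnv_summary <- aggregate_recurrent_cnvs(cnv_relevant) |>
    left_join(cnv_relevant |> distinct(.data$key, .data$final_class),
              by = "key")
  cnv_annot <- tibble(key = character(), gene_symbol = character(),
                      exon_min = integer(), exon_max = integer())
  if (nrow(cnv_summary) > 0) cnv_annot <- purrr::map_dfr(
    seq_len(nrow(cnv_summary)), function(i) {
    ann <- annotate_cnv_genes(cnv_summary[i, ], panel, exon_map)
    tibble(
      key = cnv_summary$key[i],
      gene_symbol = if (length(ann$panel_genes_hit) > 0)
        ann$panel_genes_hit else NA_character_,
      exon_min = if (nrow(ann$exon_spans) > 0)
        ann$exon_spans$exon_min[match(ann$panel_genes_hit,
                                      ann$exon_spans$gene_symbol)]
      else NA_integer_,
      exon_max = if (nrow(ann$exon_spans) > 0)
        ann$exon_spans$exon_max[match(ann$panel_genes_hit,
                                      ann$exon_spans$gene_symbol)]
      else NA_integer_
    )
  })
  cnv_summary <- cnv_summary |>
    left_join(cnv_annot |>
                group_by(.data$key) |>
                summarise(panel_genes = paste(stats::na.omit(
                  .data$gene_symbol), collapse = ","), .groups = "drop"),
              by = "key") |>
    mutate(allele_frequency = .data$n_carriers / (2 * n_unaffected))

  ## per-gene combined burden
  variant_counts <- bind_rows(
    seq_counts |>
      select("gene_symbol", "key", "het_count", "hom_count",
             "allele_count") |>
      mutate(mechanism = "sequence"),
    cnv_annot |>
      filter(!is.na(.data$gene_symbol)) |>
      left_join(cnv_summary |> select("key", "n_carriers"), by = "key") |>
      mutate(het_count = .data$n_carriers, hom_count = 0L,
             allele_count = .data$n_carriers, mechanism = "cnv") |>
      select("gene_symbol", "key", "het_count", "hom_count",
             "allele_count", "mechanism")
  )
  gene_summary <- summarize_gene_burden(variant_counts, n_unaffected)

  ## carrier categories
  seq_carriers <- call_qc$retained_calls |>
    filter(.data$key %in% retained_variants$key,
           .data$genotype %in% c("het", "hemi_alt")) |>
    left_join(retained_variants |> select("key", "gene_symbol"),
              by = "key") |>
    select("sample_id", "gene_symbol") |>
    mutate(mechanism = "sequence")
  cnv_carriers <- cnv_relevant |>
    inner_join(cnv_annot |> filter(!is.na(.data$gene_symbol)),
               by = "key", relationship = "many-to-many") |>
    select("sample_id", "gene_symbol") |>
    mutate(mechanism = "cnv")
  all_carriers <- bind_rows(seq_carriers, cnv_carriers)
  seq_class <- classify_carriers(seq_carriers, panel)
  comb_class <- classify_carriers(all_carriers, panel)
  hom_samples <- call_qc$retained_calls |>
    filter(.data$key %in% retained_variants$key,
           .data$genotype == "hom_alt") |>
    distinct(.data$sample_id)
  carrier_stats <- list(
    n_cohort = n_unaffected,
    n_seq_het = dplyr::n_distinct(seq_carriers$sample_id),
    n_cnv_het = dplyr::n_distinct(cnv_carriers$sample_id),
    n_any_het = dplyr::n_distinct(all_carriers$sample_id),
    n_hom = nrow(hom_samples),
    seq_categories = seq_class$tallies,
    n_ad_implicated = comb_class$n_ad_implicated,
    n_recessive_implicated = comb_class$n_recessive_implicated
  )

  ## Hardy-Weinberg projection over recessive-capable genes
  classes <- gene_inheritance_class(panel)
  ar_genes <- classes$gene_symbol[classes$class %in% c("AR", "AD/AR")]
  hw_input <- gene_summary |>
    filter(.data$mechanism == "combined",
           .data$gene_symbol %in% ar_genes,
           .data$allele_count > 0)
  hw_estimates <- hw_affected_frequency(hw_input$combined_af,
                                        hw_input$gene_symbol) |>
    arrange(dplyr::desc(.data$q_squared))
  hw_top5 <- combined_recessive_burden(utils::head(hw_estimates, 5), panel)
  hw_all <- combined_recessive_burden(hw_estimates, panel)

  ## ROH and consanguinity
  roh_segments <- read_roh_segments(config$paths$roh_bed) |>
    filter(.data$sample_id %in% unaffected_ids)
  roh_metrics <- roh_sample_metrics(
    roh_segments, min_len_bp = th$min_roh_len_bp,
    autosome_length_mb = th$autosome_length_mb
  )
  roh_recon <- reconcile_consanguinity(roh_metrics, ph$unaffected)
  roh_summary <- list(
    n_with_data = nrow(roh_metrics),
    mean_nroh = mean(roh_metrics$nroh),
    mean_sroh_mb = mean(roh_metrics$sroh_mb),
    mean_froh = mean(roh_metrics$froh),
    class_counts = roh_metrics |> count(.data$consanguinity_class,
                                        name = "n"),
    mismatch_rate = roh_recon$mismatch_rate
  )

  ## reference-cohort comparison
  reference <- read_reference_counts(config$paths$reference_counts)
  comparison <- compare_allele_counts(
    seq_counts |> select("key", "allele_count", "n_genotyped"),
    reference, alpha = th$alpha
  )

  funnel <- tibble::tribble(
    ~entity,    ~stage,                        ~n,
    "samples",  "preselected",                 nrow(qc_tab),
    "samples",  "sample_qc_pass",              nrow(sq$passing),
    "samples",  "unaffected",                  n_unaffected,
    "variants", "detected",                    length(detected_keys),
    "variants", "plp_preselected",             nrow(pres),
    "variants", "curated_relevant",            nrow(retained_variants),
    "cnvs",     "events_called",               nrow(cnv_all),
    "cnvs",     "distinct_filtered",           nrow(cnv_distinct_pre),
    "cnvs",     "distinct_relevant",           nrow(cnv_summary)
  )

  result <- structure(list(
    config = config,
    funnel = funnel,
    panel = list(retained = panel, exclusion_log = pf$exclusion_log,
                 summary = panel_summary),
    samples = list(qc_failing = sq$failing, affected = ph$affected,
                   unaffected = ph$unaffected),
    variants = list(per_variant = seq_counts,
                    dropped_call_rate = call_qc$dropped_variants,
                    mito_hits = mito_hits),
    cnvs = list(summary = cnv_summary, excluded_log = cnv_sz$excluded_log,
                annotations = cnv_annot),
    gene_summary = gene_summary,
    carrier_stats = carrier_stats,
    hw = list(estimates = hw_estimates, top5 = hw_top5, all = hw_all),
    roh = list(metrics = roh_metrics, summary = roh_summary,
               reconciliation = roh_recon$table),
    comparison = comparison
  ), class = "nshl_screen")

  if (!is.null(out_dir)) write_screen_reports(result, out_dir)
  result
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# TSV + JSON report bundle under out_dir, with a log of thresholds.
write_screen_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(name) file.path(out_dir, name)
  per_variant <- result$variants$per_variant |>
    mutate(af_pct = round_half_up(100 * .data$allele_frequency, 2)) |>
    select("gene_symbol", "hgvs_c", "hgvs_p", "key", "final_class",
           "het_count", "hom_count", "n_genotyped", "af_pct")
  readr::write_tsv(per_variant, p("per_variant.tsv"))
  readr::write_tsv(result$gene_summary, p("per_gene.tsv"))
  readr::write_tsv(result$hw$estimates, p("hw_estimates.tsv"))
  readr::write_tsv(result$roh$metrics, p("roh_metrics.tsv"))
  if (nrow(result$comparison$comparisons) > 0) {
    readr::write_tsv(result$comparison$comparisons, p("comparison.tsv"))
  }
  readr::write_tsv(result$funnel, p("funnel.tsv"))
  jsonlite::write_json(as.list(glance(result)), p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("nshlcarrier screen run: %s", format(Sys.time(), "%Y-%m-%d")),
    sprintf("seed: %s", result$config$seed %||% "NA"),
    vapply(names(result$config$thresholds), function(nm) {
      sprintf("threshold %s = %g", nm, result$config$thresholds[[nm]])
    }, character(1))
  ), p("run_log.txt"))
  invisible(out_dir)
}
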