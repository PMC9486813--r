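# Synthetic cohort generator: complete, seeded input bundles (multi-sample
# VCF, CNV calls, ROH segments, phenotype and sample-QC tables, variant
# catalogue, curation decisions, gene panel, exon and syndromic maps,
# reference-cohort counts, mitochondrial lookup list, run config) so every
# pipeline stage is testable without patient data. Planted carrier counts
# among QC-passing unaffected individuals are exact; every decoy is
# constructed to be removed by exactly one named filter.

#' Build a synthetic-cohort configuration
#'
#' @param n_individuals Cohort size before sample QC.
#' @param seed Integer seed; the only source of randomness.
#' @param variants Tibble of planted catalogued variants: `gene_symbol`,
#'   `hgvs_c`, `hgvs_p`, `aggregate_class`, `any_plp_submitter`,
#'   `final_class` (curation outcome; VUS/LB rows are detected but curated
#'   out), `n_het`, `n_hom`.
#' @param cnvs Tibble of planted clinically relevant CNVs: `contig`,
#'   `start_1based`, `end_1based`, `svtype`, `source`, `final_class`,
#'   `n_carriers`.
#' @param decoys List of sequence-variant decoy counts:
#'   `n_conflicting` (catalogued conflicting without a P/LP submitter,
#'   detected, dropped at preselection), `n_benign` (B/LB catalogue records,
#'   detected), `n_absent` (detected but uncatalogued), `n_low_depth`
#'   (variants whose every call is under the depth threshold),
#'   `n_low_callrate` (variants genotyped in under 95% of the cohort),
#'   `n_callrate_missing` (samples set missing for each low-call-rate
#'   variant), `n_catalogue_filler` (catalogued but undetected rows).
#' @param cnv_decoys List: `n_vus` (events surviving all filters but curated
#'   VUS), `n_vus_sv_caller` (how many of those come from the SV caller),
#'   `n_noncoding`, `n_oversize`, `n_syndromic`, `n_hl_sample` (events in
#'   affected individuals, removed by cohort restriction).
#' @param n_hl_affected QC-passing individuals carrying a hearing-loss HPO
#'   term.
#' @param n_qc_fail Individuals failing sample QC.
#' @param roh_profile Tibble: `class`, `n`, `sroh_min`, `sroh_max` (Mb),
#'   `nroh_min`, `nroh_max`; applied to unaffected individuals.
#' @param n_no_roh_data Unaffected individuals without ROH segments.
#' @param self_report List of counts: `yes_high`, `yes_low`, `no_high`,
#'   `no_low` (high = ROH class probable/evidence); the remainder report
#'   unknown.
#' @param reference Tibble of reference-cohort rows: `gene_symbol`,
#'   `hgvs_c`, `ref_alt`, `ref_total` (matched to planted variants by gene
#'   and HGVS).
#' @param panel Panel tibble (default [builtin_panel()]).
#' @return A `nshl_cohort_config` list.
#' @export
cohort_config <- function(n_individuals,
                          seed = 1L,
                          variants = NULL,
                          cnvs = NULL,
                          decoys = list(),
                          cnv_decoys = list(),
                          n_hl_affected = 0L,
                          n_qc_fail = 0L,
                          roh_profile = NULL,
                          n_no_roh_data = 0L,
                          self_report = NULL,
                          reference = NULL,
                          panel = builtin_panel()) {
  decoy_defaults <- list(n_conflicting = 0L, n_benign = 0L, n_absent = 0L,
                         n_low_depth = 0L, n_low_callrate = 0L,
                         n_callrate_missing = 0L, n_catalogue_filler = 0L)
  cnv_decoy_defaults <- list(n_vus = 0L, n_vus_sv_caller = 0L,
                             n_noncoding = 0L, n_oversize = 0L,
                             n_syndromic = 0L, n_hl_sample = 0L)
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    seed = as.integer(seed),
    variants = variants,
    cnvs = cnvs,
    decoys = utils::modifyList(decoy_defaults, decoys),
    cnv_decoys = utils::modifyList(cnv_decoy_defaults, cnv_decoys),
    n_hl_affected = as.integer(n_hl_affected),
    n_qc_fail = as.integer(n_qc_fail),
    roh_profile = roh_profile,
    n_no_roh_data = as.integer(n_no_roh_data),
    self_report = self_report,
    reference = reference,
    panel = panel
  ), class = "nshl_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  n_unaffected <- cfg$n_individuals - cfg$n_qc_fail - cfg$n_hl_affected
  if (n_unaffected < 0) abort("More QC failures and affected than individuals")
  n_carrier_slots <- 0L
  if (!is.null(cfg$variants)) {
    if (any(cfg$variants$n_het < 0 | cfg$variants$n_hom < 0)) {
      abort("Negative planted carrier count")
    }
    bad_gene <- setdiff(cfg$variants$gene_symbol, cfg$panel$gene_symbol)
    if (length(bad_gene) > 0) {
      abort(sprintf("Planted variant in gene absent from panel: %s",
                    paste(bad_gene, collapse = ", ")))
    }
    n_carrier_slots <- sum(cfg$variants$n_het[
      cfg$variants$final_class %in% c("P", "LP")]) +
      sum(cfg$variants$n_hom)
  }
  if (!is.null(cfg$cnvs)) {
    n_carrier_slots <- n_carrier_slots + sum(cfg$cnvs$n_carriers)
  }
  if (n_carrier_slots > n_unaffected) {
    abort(sprintf(
      "Infeasible config: %d carrier slots exceed %d unaffected individuals",
      n_carrier_slots, n_unaffected
    ))
  }
  if (!is.null(cfg$roh_profile) && sum(cfg$roh_profile$n) >
        n_unaffected - cfg$n_no_roh_data) {
    abort("ROH profile counts exceed unaffected individuals with ROH data")
  }
  invisible(cfg)
}

# Assign variant coordinates within their genes' intervals. Deletion-style
# HGVS rows become two-base indel keys; other rows cycle SNV ref/alt pairs.
# Offset blocks keep planted, conflicting-decoy and filler positions
# disjoint inside each gene.
assign_variant_coords <- function(variants, panel, offset = 5000L,
                                  step = 20L) {
  gene_iv <- panel |>
    distinct(.data$gene_symbol, .keep_all = TRUE) |>
    select("gene_symbol", "contig", "start_1based")
  refs <- c("A", "C", "G", "T")
  alts <- c(A = "G", C = "T", G = "A", T = "C")
  variants |>
    left_join(gene_iv, by = "gene_symbol") |>
    group_by(.data$gene_symbol) |>
    mutate(pos = .data$start_1based + offset + (row_number() - 1L) * step) |>
    ungroup() |>
    mutate(
      ref = if_else(grepl("del", .data$hgvs_c, fixed = TRUE),
                    paste0(refs[(.data$pos %% 4) + 1],
                           refs[((.data$pos + 1) %% 4) + 1]),
                    refs[(.data$pos %% 4) + 1]),
      alt = if_else(grepl("del", .data$hgvs_c, fixed = TRUE),
                    substr(.data$ref, 1, 1),
                    unname(alts[refs[(.data$pos %% 4) + 1]])),
      key = variant_key(.data$contig, .data$pos, .data$ref, .data$alt)
    ) |>
    select(-"start_1based")
}

# Partition a Mb total into n segments each at least 1 Mb (returned in bp).
split_sroh <- function(sroh_mb, n) {
  if (n == 0) return(numeric(0))
  spare <- max(sroh_mb - n, 0)
  w <- stats::runif(n)
  round((1 + spare * w / sum(w)) * 1e6)
}

#' Generate a synthetic cohort input bundle
#'
#' Writes every pipeline input to `out_dir` and returns the file paths plus
#' a ready-to-run screen configuration. Deterministic given `config$seed`:
#' two runs with the same config are byte-identical, while different seeds
#' permute carrier assignments without changing planted counts. Carriers are
#' planted only among QC-passing unaffected individuals, so the pipeline
#' recovers every planted count exactly; each decoy is removed by exactly
#' one named filter.
#'
#' @param config A `nshl_cohort_config` from [cohort_config()] or
#'   [study_fixture_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `run_config` (list accepted by [run_screen()]).
#' @export
generate_cohort <- function(config, out_dir) {
  validate_cohort_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_individuals
  sample_ids <- sprintf("S%05d", seq_len(n))
  shuffled <- sample(sample_ids)
  qc_fail_ids <- shuffled[seq_len(config$n_qc_fail)]
  affected_ids <- shuffled[config$n_qc_fail + seq_len(config$n_hl_affected)]
  unaffected_ids <- setdiff(shuffled, c(qc_fail_ids, affected_ids))
  n_unaffected <- length(unaffected_ids)

  paths <- list()
  p <- function(name) file.path(out_dir, name)

  ## ---- panel ----------------------------------------------------------
  panel_out <- config$panel |>
    mutate(no_valid_transcript = as.integer(.data$no_valid_transcript),
           non_mendelian = as.integer(.data$non_mendelian))
  readr::write_tsv(panel_out, p("panel.tsv"))
  paths$panel <- p("panel.tsv")
  retained_panel <- filter_gene_panel(config$panel)$retained

  ## ---- exon and syndromic maps ----------------------------------------
  exons <- builtin_exon_map(config$panel)
  exon_bed <- exons |>
    mutate(start0 = .data$start_1based - 1L, end0 = .data$end_1based,
           name = paste(.data$gene_symbol, .data$exon_number, sep = "|")) |>
    select("contig", "start0", "end0", "name")
  readr::write_tsv(exon_bed, p("exons.bed"), col_names = FALSE)
  paths$exons_bed <- p("exons.bed")
  syn <- syndromic_regions() |>
    mutate(start0 = .data$start_1based - 1L, end0 = .data$end_1based) |>
    select("contig", "start0", "end0", "label")
  readr::write_tsv(syn, p("syndromic.bed"), col_names = FALSE)
  paths$syndromic_bed <- p("syndromic.bed")

  ## ---- sample QC table ------------------------------------------------
  qc <- tibble(
    sample_id = sample_ids,
    mapped_read_pct = round(stats::runif(n, 98.3, 99.9), 2),
    autosome_median_coverage = round(stats::runif(n, 28, 45), 1),
    uniformity_pct = round(stats::runif(n, 88, 97), 1),
    contamination_pct = round(stats::runif(n, 0, 1), 2),
    callability_pct = round(stats::runif(n, 96, 99.5), 1),
    q30_pct = round(stats::runif(n, 91, 96), 1),
    chimeric_pct = round(stats::runif(n, 0.5, 3), 2),
    duplicate_pct = round(stats::runif(n, 2, 8), 1)
  )
  if (config$n_qc_fail > 0) {
    fi <- match(qc_fail_ids, qc$sample_id)
    # mostly low autosome coverage, a few failing other metrics
    n_cov <- max(config$n_qc_fail - 4L, 1L)
    qc$autosome_median_coverage[fi[seq_len(n_cov)]] <-
      round(stats::runif(n_cov, 12, 19.5), 1)
    extra <- fi[-seq_len(n_cov)]
    others <- c("mapped_read_pct", "contamination_pct", "callability_pct",
                "uniformity_pct")
    bad_val <- c(97.2, 2.8, 93.5, 76.0)
    for (j in seq_along(extra)) {
      qc[[others[(j - 1L) %% 4L + 1L]]][extra[j]] <- bad_val[(j - 1L) %% 4L + 1L]
    }
  }
  readr::write_tsv(qc, p("sample_qc.tsv"))
  paths$sample_qc <- p("sample_qc.tsv")

  ## ---- variants, catalogue, decisions, VCF ----------------------------
  variants <- config$variants
  if (is.null(variants)) {
    variants <- tibble(gene_symbol = character(), hgvs_c = character(),
                       hgvs_p = character(), aggregate_class = character(),
                       any_plp_submitter = logical(),
                       final_class = character(), n_het = integer(),
                       n_hom = integer())
  }
  planted <- assign_variant_coords(variants, config$panel, offset = 5000L)

  dk <- config$decoys
  conflict_genes <- retained_panel |>
    filter(.data$inheritance_mode != "XL") |>
    distinct(.data$gene_symbol) |>
    pull()
  xl_genes <- retained_panel |>
    filter(.data$inheritance_mode == "XL") |>
    distinct(.data$gene_symbol) |>
    pull()
  n_conf_x <- min(3L, dk$n_conflicting, length(xl_genes))
  conflict <- tibble(
    gene_symbol = c(
      rep(conflict_genes,
          length.out = max(dk$n_conflicting - n_conf_x, 0L)),
      rep(xl_genes, length.out = n_conf_x)
    ),
    hgvs_c = sprintf("c.%d>conf", seq_len(dk$n_conflicting)),
    hgvs_p = "p.?",
    aggregate_class = "conflicting",
    any_plp_submitter = FALSE,
    final_class = NA_character_,
    n_het = 1L, n_hom = 0L
  )
  conflict <- assign_variant_coords(conflict, config$panel, offset = 12000L,
                                    step = 10L)
  benign <- tibble(
    gene_symbol = rep(conflict_genes, length.out = dk$n_benign),
    hgvs_c = sprintf("c.%d>ben", seq_len(dk$n_benign)),
    hgvs_p = "p.?",
    aggregate_class = rep(c("B", "LB"), length.out = dk$n_benign),
    any_plp_submitter = FALSE, final_class = NA_character_,
    n_het = 1L, n_hom = 0L
  )
  benign <- assign_variant_coords(benign, config$panel, offset = 14000L,
                                  step = 10L)
  absent <- tibble(
    gene_symbol = rep(conflict_genes, length.out = dk$n_absent),
    hgvs_c = sprintf("c.%d>abs", seq_len(dk$n_absent)),
    hgvs_p = "p.?",
    aggregate_class = NA_character_, any_plp_submitter = FALSE,
    final_class = NA_character_, n_het = 1L, n_hom = 0L
  )
  absent <- assign_variant_coords(absent, config$panel, offset = 16000L,
                                  step = 10L)
  low_depth <- tibble(
    gene_symbol = rep(conflict_genes, length.out = dk$n_low_depth),
    hgvs_c = sprintf("c.%d>lowdp", seq_len(dk$n_low_depth)),
    hgvs_p = "p.?",
    aggregate_class = "P", any_plp_submitter = TRUE,
    final_class = "P", n_het = 3L, n_hom = 0L
  )
  low_depth <- assign_variant_coords(low_depth, config$panel,
                                     offset = 17000L, step = 10L)
  low_cr <- tibble(
    gene_symbol = rep(rev(conflict_genes), length.out = dk$n_low_callrate),
    hgvs_c = sprintf("c.%d>lowcr", seq_len(dk$n_low_callrate)),
    hgvs_p = "p.?",
    aggregate_class = "P", any_plp_submitter = TRUE,
    final_class = "P", n_het = 2L, n_hom = 0L
  )
  low_cr <- assign_variant_coords(low_cr, config$panel, offset = 18000L,
                                  step = 10L)
  filler <- tibble(
    gene_symbol = rep(c(conflict_genes, xl_genes),
                      length.out = dk$n_catalogue_filler),
    hgvs_c = sprintf("c.%d>und", seq_len(dk$n_catalogue_filler)),
    hgvs_p = "p.?",
    aggregate_class = rep(c("VUS", "conflicting", "P", "LB", "LP", "B"),
                          length.out = dk$n_catalogue_filler),
    any_plp_submitter = FALSE, final_class = NA_character_,
    n_het = 0L, n_hom = 0L
  )
  filler <- assign_variant_coords(filler, config$panel, offset = 20000L,
                                  step = 3L)

  catalogue <- bind_rows(planted, conflict, benign, low_depth, low_cr,
                         filler) |>
    filter(!is.na(.data$aggregate_class)) |>
    mutate(any_plp_submitter = as.integer(.data$any_plp_submitter)) |>
    select("contig", "pos", "ref", "alt", "gene_symbol", "hgvs_c",
           "hgvs_p", "aggregate_class", "any_plp_submitter")
  readr::write_tsv(catalogue, p("catalogue.tsv"))
  paths$catalogue <- p("catalogue.tsv")

  decisions <- bind_rows(planted, low_depth, low_cr) |>
    filter(!is.na(.data$final_class)) |>
    mutate(acmg_criteria = if_else(
      .data$final_class %in% c("P", "LP"), "PVS1;PM2", "PM2"
    )) |>
    select("contig", "pos", "ref", "alt", "final_class", "acmg_criteria")
  readr::write_tsv(decisions, p("decisions.tsv"))
  paths$decisions <- p("decisions.tsv")

  # mitochondrial lookup list (searched, none planted by default)
  mito <- tibble(
    contig = "chrM",
    pos = seq(750L, by = 120L, length.out = 112L),
    ref = rep(c("A", "G", "T", "C"), length.out = 112L),
    alt = rep(c("G", "A", "C", "T"), length.out = 112L),
    gene_symbol = rep(c("MT-RNR1", "MT-TS1", "MT-TL1", "MT-CO1"),
                      length.out = 112L),
    hgvs_c = sprintf("m.%d%s>%s", seq(750L, by = 120L, length.out = 112L),
                     rep(c("A", "G", "T", "C"), length.out = 112L),
                     rep(c("G", "A", "C", "T"), length.out = 112L))
  )
  readr::write_tsv(mito, p("mito_list.tsv"))
  paths$mito_list <- p("mito_list.tsv")

  ## ---- carrier assignment ---------------------------------------------
  pool <- sample(unaffected_ids)
  take <- function(k) {
    if (k == 0) return(character(0))
    if (k > length(pool)) abort("Carrier pool exhausted")
    out <- pool[seq_len(k)]
    pool <<- pool[seq_len(length(pool))[-seq_len(k)]]
    out
  }
  retained_rows <- planted |>
    filter(.data$final_class %in% c("P", "LP"))
  het_assign <- tibble(
    key = rep(retained_rows$key, times = retained_rows$n_het),
    sample_id = take(sum(retained_rows$n_het)),
    gt = "het"
  )
  hom_rows <- planted |> filter(.data$n_hom > 0)
  hom_assign <- tibble(
    key = rep(hom_rows$key, times = hom_rows$n_hom),
    sample_id = take(sum(hom_rows$n_hom)),
    gt = "hom"
  )
  # detected decoys: one (or a few) carriers each, drawn anywhere unaffected
  decoy_rows <- bind_rows(
    planted |> filter(!.data$final_class %in% c("P", "LP")),
    conflict, benign, absent, low_depth, low_cr
  )
  decoy_assign <- tibble(
    key = rep(decoy_rows$key, times = decoy_rows$n_het),
    sample_id = sample(unaffected_ids, sum(decoy_rows$n_het),
                       replace = TRUE),
    gt = "het"
  ) |>
    distinct(.data$key, .data$sample_id, .keep_all = TRUE)

  ## ---- VCF -------------------------------------------------------------
  vcf_rows <- bind_rows(planted, conflict, benign, absent, low_depth,
                        low_cr)
  if (nrow(vcf_rows) > 0) {
    gt_mat <- matrix("0/0:30", nrow = nrow(vcf_rows), ncol = n,
                     dimnames = list(vcf_rows$key, sample_ids))
    if (dk$n_low_depth > 0) {
      gt_mat[low_depth$key, ] <- "0/0:8"
    }
    set_cells <- function(assign, value) {
      if (nrow(assign) == 0) return()
      gt_mat[cbind(match(assign$key, vcf_rows$key),
                   match(assign$sample_id, sample_ids))] <<- value
    }
    set_cells(het_assign, "0/1:35")
    set_cells(hom_assign, "1/1:34")
    low_depth_carriers <- decoy_assign |>
      filter(.data$key %in% low_depth$key)
    normal_decoys <- decoy_assign |>
      filter(!.data$key %in% low_depth$key)
    set_cells(normal_decoys, "0/1:33")
    set_cells(low_depth_carriers, "0/1:8")
    if (dk$n_low_callrate > 0 && dk$n_callrate_missing > 0) {
      for (k in low_cr$key) {
        miss <- sample(unaffected_ids, dk$n_callrate_missing)
        gt_mat[k, miss] <- "./.:0"
      }
    }
    ord <- order(vcf_rows$contig, vcf_rows$pos)
    contigs <- unique(c(paste0("chr", 1:22), "chrX", "chrM",
                        vcf_rows$contig))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=nshlcarrier_synthetic_cohort",
      sprintf("##contig=<ID=%s,length=250000000>", contigs),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sample_ids), collapse = "\t")
    )
    fix <- paste(vcf_rows$contig[ord], vcf_rows$pos[ord], ".",
                 vcf_rows$ref[ord], vcf_rows$alt[ord], ".", "PASS", ".",
                 "GT:DP", sep = "\t")
    body <- vapply(ord, function(i) {
      paste(gt_mat[i, ], collapse = "\t")
    }, character(1))
    writeLines(c(header, paste(fix, body, sep = "\t")), p("cohort.vcf"))
  } else {
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sample_ids), collapse = "\t")
    ), p("cohort.vcf"))
  }
  paths$vcf <- p("cohort.vcf")

  ## ---- CNVs ------------------------------------------------------------
  cnvs <- config$cnvs
  if (is.null(cnvs)) {
    cnvs <- tibble(contig = character(), start_1based = integer(),
                   end_1based = integer(), svtype = character(),
                   source = character(), final_class = character(),
                   n_carriers = integer())
  }
  cnv_carrier_ids <- take(sum(cnvs$n_carriers))
  relevant_events <- tibble(
    sample_id = cnv_carrier_ids,
    contig = rep(cnvs$contig, times = cnvs$n_carriers),
    start_1based = rep(cnvs$start_1based, times = cnvs$n_carriers),
    end_1based = rep(cnvs$end_1based, times = cnvs$n_carriers),
    svtype = rep(cnvs$svtype, times = cnvs$n_carriers),
    source = rep(cnvs$source, times = cnvs$n_carriers)
  )

  ck <- config$cnv_decoys
  sched_genes <- retained_panel |>
    filter(.data$start_1based >= 150000000L) |>
    distinct(.data$gene_symbol, .data$contig, .data$start_1based)
  mk_decoy <- function(n_ev, start_off, len, tag) {
    if (n_ev == 0 || nrow(sched_genes) == 0) {
      return(tibble(sample_id = character(), contig = character(),
                    start_1based = integer(), end_1based = integer(),
                    svtype = character(), source = character()))
    }
    gi <- rep(seq_len(nrow(sched_genes)), length.out = n_ev)
    jitter <- (seq_len(n_ev) - 1L) %/% nrow(sched_genes)
    tibble(
      sample_id = sample(unaffected_ids, n_ev, replace = TRUE),
      contig = sched_genes$contig[gi],
      start_1based = sched_genes$start_1based[gi] + start_off + jitter * 7L,
      end_1based = sched_genes$start_1based[gi] + start_off + len +
        jitter * 7L,
      svtype = rep(c("DEL", "DUP"), length.out = n_ev),
      source = "cnv_caller"
    )
  }
  vus_events <- mk_decoy(ck$n_vus, 9000L, 2500L, "vus")
  if (ck$n_vus_sv_caller > 0 && nrow(vus_events) > 0) {
    vus_events$source[seq_len(min(ck$n_vus_sv_caller, nrow(vus_events)))] <-
      "sv_caller"
  }
  noncoding_events <- if (ck$n_noncoding > 0) tibble(
    sample_id = sample(unaffected_ids, ck$n_noncoding, replace = TRUE),
    contig = paste0("chr", (seq_len(ck$n_noncoding) - 1L) %% 22L + 1L),
    start_1based = 140000001L + (seq_len(ck$n_noncoding) - 1L) * 500L,
    end_1based = 140005000L + (seq_len(ck$n_noncoding) - 1L) * 500L,
    svtype = rep(c("DEL", "DUP"), length.out = ck$n_noncoding),
    source = "cnv_caller"
  ) else NULL
  oversize_events <- mk_decoy(ck$n_oversize, -200000L, 1500000L, "big")
  syn_iv <- syndromic_region_exons()
  syndromic_events <- if (ck$n_syndromic > 0) {
    si <- rep(seq_len(nrow(syn_iv)), length.out = ck$n_syndromic)
    jit <- (seq_len(ck$n_syndromic) - 1L) %/% nrow(syn_iv)
    tibble(
      sample_id = sample(unaffected_ids, ck$n_syndromic, replace = TRUE),
      contig = syn_iv$contig[si],
      start_1based = syn_iv$exon_start[si] - 100000L + jit * 11L,
      end_1based = syn_iv$exon_start[si] + 100000L + jit * 11L,
      svtype = rep(c("DEL", "DUP"), length.out = ck$n_syndromic),
      source = "cnv_caller"
    )
  } else NULL
  hl_events <- if (ck$n_hl_sample > 0 && length(affected_ids) > 0) {
    gi <- rep(seq_len(nrow(sched_genes)), length.out = ck$n_hl_sample)
    jit <- (seq_len(ck$n_hl_sample) - 1L) %/% nrow(sched_genes)
    tibble(
      sample_id = rep(affected_ids, length.out = ck$n_hl_sample),
      contig = sched_genes$contig[gi],
      start_1based = sched_genes$start_1based[gi] + 8500L + jit * 13L,
      end_1based = sched_genes$start_1based[gi] + 12000L + jit * 13L,
      svtype = "DEL",
      source = "cnv_caller"
    )
  } else NULL
  cnv_calls <- bind_rows(relevant_events, vus_events, noncoding_events,
                         oversize_events, syndromic_events, hl_events)
  readr::write_tsv(cnv_calls, p("cnv_calls.tsv"))
  paths$cnv_calls <- p("cnv_calls.tsv")

  cnv_dec <- bind_rows(
    cnvs |>
      select("contig", "start_1based", "end_1based", "svtype",
             "final_class"),
    vus_events |>
      distinct(.data$contig, .data$start_1based, .data$end_1based,
               .data$svtype) |>
      mutate(final_class = "VUS")
  ) |>
    mutate(acmg_criteria = if_else(.data$final_class %in% c("P", "LP"),
                                   "5A;2C", "2F"))
  readr::write_tsv(cnv_dec, p("cnv_decisions.tsv"))
  paths$cnv_decisions <- p("cnv_decisions.tsv")

  ## ---- ROH -------------------------------------------------------------
  roh_rows <- NULL
  roh_class <- setNames(rep(NA_character_, n_unaffected), unaffected_ids)
  if (!is.null(config$roh_profile)) {
    profile <- config$roh_profile
    # the lone OTOF truncating-variant carrier is the worked consanguinity
    # counter-example: fixed 3 + 4 Mb segments (SROH 7 Mb) plus a sub-Mb
    # decoy segment
    otof_key <- planted$key[planted$gene_symbol == "OTOF" &
                              grepl("2122", planted$hgvs_c)]
    special_id <- character(0)
    if (length(otof_key) == 1) {
      special_id <- het_assign$sample_id[het_assign$key == otof_key][1]
    }
    roh_pool <- setdiff(sample(unaffected_ids), special_id)
    roh_pool <- setdiff(roh_pool,
                        roh_pool[seq_len(config$n_no_roh_data)])
    assigned <- list()
    for (i in seq_len(nrow(profile))) {
      k <- profile$n[i]
      if (profile$class[i] == "no_evidence" && length(special_id) == 1) {
        k <- k - 1L
      }
      ids <- roh_pool[seq_len(k)]
      roh_pool <- roh_pool[-seq_len(k)]
      if (profile$class[i] == "no_evidence" && length(special_id) == 1) {
        ids <- c(ids, special_id)
      }
      roh_class[ids] <- profile$class[i]
      segs <- purrr::map_dfr(ids, function(id) {
        if (identical(id, special_id)) {
          lens <- c(3e6, 4e6, 4e5)
        } else {
          sroh <- stats::runif(1, profile$sroh_min[i], profile$sroh_max[i])
          k_seg <- sample(profile$nroh_min[i]:profile$nroh_max[i], 1)
          k_seg <- max(1L, min(k_seg, floor(sroh)))
          lens <- split_sroh(sroh, k_seg)
          if (stats::runif(1) < 0.3) lens <- c(lens, 4e5)  # sub-Mb decoy
        }
        tibble(
          contig = paste0("chr", sample(1:22, length(lens),
                                        replace = TRUE)),
          start0 = 30000000L + sample.int(50000L, length(lens)) * 1000L,
          length = as.integer(lens),
          sample_id = id
        )
      })
      assigned[[i]] <- segs
    }
    roh_rows <- bind_rows(assigned) |>
      mutate(end0 = .data$start0 + .data$length) |>
      select("contig", "start0", "end0", "sample_id")
  }
  if (is.null(roh_rows)) {
    roh_rows <- tibble(contig = character(), start0 = integer(),
                       end0 = integer(), sample_id = character())
  }
  readr::write_tsv(roh_rows, p("roh.bed"), col_names = FALSE)
  paths$roh_bed <- p("roh.bed")

  ## ---- phenotype table -------------------------------------------------
  hl_terms <- hl_hpo_terms()
  other_terms <- c("HP:0001250", "HP:0001263", "HP:0004322", "HP:0001631",
                   "HP:0000252", "HP:0001249", "HP:0000750", "HP:0002650")
  self_rep <- setNames(rep("unknown", n), sample_ids)
  if (!is.null(config$self_report)) {
    sr <- config$self_report
    high <- names(roh_class)[roh_class %in% c("probable", "evidence")]
    low <- setdiff(unaffected_ids, high)
    high <- sample(high)
    low <- sample(low)
    self_rep[high[seq_len(min(sr$yes_high, length(high)))]] <- "yes"
    high <- high[-seq_len(min(sr$yes_high, length(high)))]
    self_rep[high[seq_len(min(sr$no_high, length(high)))]] <- "no"
    self_rep[low[seq_len(min(sr$yes_low, length(low)))]] <- "yes"
    low <- low[-seq_len(min(sr$yes_low, length(low)))]
    self_rep[low[seq_len(min(sr$no_low, length(low)))]] <- "no"
  }
  pheno_terms <- purrr::map_chr(sample_ids, function(id) {
    base <- sample(other_terms, sample(1:3, 1))
    if (id %in% affected_ids) {
      base <- c(sample(hl_terms, 1), if (stats::runif(1) < 0.95) base)
    }
    paste(base, collapse = ";")
  })
  pheno <- tibble(sample_id = sample_ids, hpo_terms = pheno_terms,
                  consanguinity_self_report = unname(self_rep[sample_ids]))
  readr::write_tsv(pheno, p("phenotype.tsv"))
  paths$phenotype <- p("phenotype.tsv")

  ## ---- reference cohort ------------------------------------------------
  ref_tab <- tibble(contig = character(), pos = integer(),
                    ref = character(), alt = character(),
                    alt_allele_count = integer(), total_alleles = integer())
  if (!is.null(config$reference)) {
    ref_tab <- config$reference |>
      inner_join(planted |> select("gene_symbol", "hgvs_c", "contig",
                                   "pos", "ref", "alt"),
                 by = c("gene_symbol", "hgvs_c")) |>
      select("contig", "pos", "ref", "alt",
             alt_allele_count = "ref_alt", total_alleles = "ref_total")
  }
  readr::write_tsv(ref_tab, p("reference_counts.tsv"))
  paths$reference_counts <- p("reference_counts.tsv")

  ## ---- run config ------------------------------------------------------
  run_config <- list(
    paths = lapply(paths, normalizePath),
    thresholds = list(
      min_depth = 20, min_call_rate = 0.95, max_cnv_size_bp = 1000000,
      alpha = 0.05, autosome_length_mb = 2881, min_roh_len_bp = 1000000
    ),
    hl_terms = hl_terms,
    seed = config$seed
  )
  yaml::write_yaml(run_config, p("config.yaml"))
  paths$config <- p("config.yaml")
  run_config$paths$config <- normalizePath(p("config.yaml"))

  invisible(list(paths = paths, run_config = run_config))
}
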