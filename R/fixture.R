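# The frozen study fixture: a cohort configuration whose generated bundle,
# run through the full screen, reproduces the reference results end to end
# (2,199 -> 2,186 -> 2,097 samples; 996 detected -> 118 P/LP-submitted ->
# 89 curated sequence variants with 222 heterozygotes and 4 homozygotes;
# 5,285 -> 232 -> 12 CNVs in 54 carriers; per-gene combined allele
# frequencies; Hardy-Weinberg projections). Per-variant counts for the top
# variants are pinned; the remainder is distributed to satisfy the per-gene
# and cohort-level totals exactly.

# Planted sequence variants: per gene, heterozygote counts per variant (and
# homozygote counts where nonzero).
fixture_variant_plan <- function() {
  plan <- list(
    GJB2     = list(het = c(28, 23, 6, 2, 1, 1, 1, 1, 1),
                    hom = c(1, 0, 0, 0, 0, 0, 0, 0, 0),
                    hgvs_c = c("c.35del", "c.109G>A", "c.617A>G", NA, NA,
                               NA, NA, NA, NA),
                    hgvs_p = c("p.(Gly12fs)", "p.(Val37Ile)",
                               "p.(Asn206Ser)", NA, NA, NA, NA, NA, NA)),
    STRC     = list(het = 3),
    OTOA     = list(het = 25, hgvs_c = "c.2359G>T",
                    hgvs_p = "p.(Glu787Ter)"),
    TMPRSS3  = list(het = c(13, 2, 1, 1),
                    hgvs_c = c("c.1273G>A", NA, NA, NA),
                    hgvs_p = c("p.(Ala425Thr)", NA, NA, NA)),
    OTOF     = list(het = c(3, 2, 2, 2, 1, 1, 1),
                    hgvs_c = c(NA, NA, NA, NA, NA, NA, "c.2122C>T"),
                    hgvs_p = c(NA, NA, NA, NA, NA, NA, "p.(Arg708Ter)")),
    MYO7A    = list(het = c(3, 1, 1, 1, 1, 1, 1)),
    SLC26A4  = list(het = c(2, 1, 1, 1, 1, 1, 1, 1)),
    MPZL2    = list(het = 8, hgvs_c = "c.72del", hgvs_p = "p.(Ile24fs)"),
    COL11A2  = list(het = c(4, 3)),
    PDZD7    = list(het = c(4, 1, 1, 1)),
    # genes associated exclusively with dominant inheritance
    GJB6     = list(het = 2),
    KCNQ4    = list(het = c(2, 1)),
    POU4F3   = list(het = 2),
    TJP2     = list(het = c(1, 0), hom = c(0, 1),
                    hgvs_c = c(NA, "c.1234C>T"),
                    hgvs_p = c(NA, "p.(Arg412Ter)")),
    WFS1     = list(het = 2),
    # remaining dual-mode genes
    TBC1D24  = list(het = c(1, 2), hom = c(1, 0),
                    hgvs_c = c("c.724C>T", NA),
                    hgvs_p = c("p.(Arg242Cys)", NA)),
    TECTA    = list(het = c(2, 1)),
    MYO6     = list(het = c(2, 1)),
    # remaining recessive genes
    DCDC2    = list(het = 1, hom = 1, hgvs_c = "c.383C>G",
                    hgvs_p = "p.(Ser128Ter)"),
    MYO15A   = list(het = c(2, 1, 1)),
    LOXHD1   = list(het = c(2, 1, 1)),
    USH1C    = list(het = c(2, 1)),
    PCDH15   = list(het = c(1, 1)),
    CIB2     = list(het = c(1, 1)),
    CLDN14   = list(het = c(2, 1)),
    TMIE     = list(het = c(1, 1)),
    ESPN     = list(het = c(2, 1)),
    GIPC3    = list(het = c(1, 1)),
    LHFPL5   = list(het = c(1, 1)),
    MYO3A    = list(het = c(2, 1)),
    SLC26A5  = list(het = 2),
    BSND     = list(het = 3),
    RDX      = list(het = 2),
    TPRN     = list(het = 1),
    SYNE4    = list(het = 1),
    MARVELD2 = list(het = c(1, 1))
  )
  purrr::imap_dfr(plan, function(x, gene) {
    k <- length(x$het)
    tibble(
      gene_symbol = gene,
      n_het = as.integer(x$het),
      n_hom = as.integer(if (is.null(x$hom)) rep(0L, k) else x$hom),
      hgvs_c = if (is.null(x$hgvs_c)) rep(NA_character_, k) else x$hgvs_c,
      hgvs_p = if (is.null(x$hgvs_p)) rep(NA_character_, k) else x$hgvs_p
    )
  })
}

#' The frozen study-fixture configuration
#'
#' Returns the cohort configuration encoding the reference study conditions:
#' 2,199 individuals (13 sample-QC failures; 89 with hearing-loss phenotype
#' terms), 89 retained pathogenic/likely pathogenic sequence variants with
#' their pinned heterozygote/homozygote counts (222 heterozygous and 4
#' homozygous carriers among 2,097 unaffected), 29 preselected variants
#' curated out (28 VUS, 1 LB), decoy sets sized so the detected/preselected
#' funnel reads 996 -> 118 -> 89, the 12 clinically relevant CNVs with their
#' carrier counts (54 carriers) plus decoys sizing the CNV funnel
#' 5,285 -> 232 -> 12, ROH class profiles, self-report counts, and a
#' 13-variant reference-cohort table in which one variant (the OTOA
#' nonsense variant) is markedly more frequent in the reference.
#'
#' @param seed Integer seed for carrier assignment and noise (default 20220830).
#' @return A `nshl_cohort_config`.
#' @export
study_fixture_config <- function(seed = 20220830L) {
  plan <- fixture_variant_plan()
  # ACMG final classes: 44 pathogenic, 45 likely pathogenic
  retained <- plan |>
    mutate(
      final_class = if_else(row_number() <= 44L, "P", "LP"),
      aggregate_class = rep(c("P", "LP", "conflicting"),
                            length.out = nrow(plan)),
      any_plp_submitter = TRUE
    )
  curated_out <- tibble(
    gene_symbol = rep(c("CDH23", "ESPN", "MYO3A", "LOXHD1", "PCDH15",
                        "SLC26A4", "USH1C"), length.out = 29L),
    n_het = 1L, n_hom = 0L,
    hgvs_c = sprintf("c.%d>cur", seq_len(29L)),
    hgvs_p = "p.?",
    final_class = c(rep("VUS", 28L), "LB"),
    aggregate_class = "conflicting",
    any_plp_submitter = TRUE
  )
  variants <- bind_rows(retained, curated_out) |>
    mutate(hgvs_c = dplyr::coalesce(
      .data$hgvs_c, sprintf("c.%d_syn", row_number())
    ), hgvs_p = dplyr::coalesce(.data$hgvs_p, "p.?")) |>
    select("gene_symbol", "hgvs_c", "hgvs_p", "aggregate_class",
           "any_plp_submitter", "final_class", "n_het", "n_hom")

  cnvs <- tibble::tribble(
    ~contig, ~start_1based, ~end_1based, ~svtype, ~final_class, ~n_carriers,
    "chr15", 43600849L, 43658715L, "DEL", "P",  38L,  # STRC ex1-26 (57.9 kb)
    "chr15", 43557296L, 43603898L, "DEL", "LP", 1L,   # STRC ex22-29 (46.6 kb)
    "chr16", 21550000L, 21794199L, "DEL", "P",  4L,   # OTOA (244.2 kb)
    "chr16", 15394361L, 16199828L, "DEL", "P",  2L,   # ABCC1 (805.5 kb)
    "chr11", 78476555L, 78486991L, "DEL", "LP", 2L,   # NARS2 ex7-10
    "chr17", 18624545L, 19025057L, "DEL", "P",  1L,   # GRAP (400.5 kb)
    "chr15", 51437517L, 51457141L, "DEL", "LP", 1L,   # DMXL2 ex36-43
    "chr7",  24702446L, 24720157L, "DEL", "LP", 1L,   # GSDME ex3-8
    "chr11", 17603104L, 17613104L, "DEL", "LP", 1L,   # OTOG ex33-38
    "chr12", 80288802L, 80299740L, "DUP", "LP", 1L,   # OTOGL ex27
    "chr22", 37719702L, 37731543L, "DEL", "LP", 1L,   # TRIOBP ex5
    "chr11", 121163035L, 121174624L, "DEL", "LP", 1L  # TECTA ex16-19
  ) |>
    mutate(source = if_else(.data$contig %in% c("chr12", "chr22") &
                              .data$end_1based < 81000000L,
                            "sv_caller", "cnv_caller"))

  reference <- tibble::tribble(
    ~gene_symbol, ~hgvs_c,      ~ref_alt, ~ref_total,
    "OTOA",       "c.2359G>T",  60L,      2342L,  # enriched in reference
    "GJB2",       "c.35del",    17L,      2342L,
    "GJB2",       "c.109G>A",   13L,      2342L,
    "GJB2",       "c.617A>G",   4L,       2342L,
    "TMPRSS3",    "c.1273G>A",  7L,       2342L,
    "MPZL2",      "c.72del",    5L,       2342L,
    "DCDC2",      "c.383C>G",   2L,       2342L,
    "TBC1D24",    "c.724C>T",   2L,       2342L,
    "TJP2",       "c.1234C>T",  1L,       2342L,
    "OTOF",       "c.2122C>T",  1L,       2342L,
    "SLC26A4",    "c.30_syn",   1L,       2342L,
    "MYO7A",      "c.23_syn",   2L,       2342L,
    "COL11A2",    "c.39_syn",   2L,       2342L
  )

  roh_profile <- tibble::tribble(
    ~class,         ~n,    ~sroh_min, ~sroh_max, ~nroh_min, ~nroh_max,
    "no_evidence",  1478L, 2,         14,        1L,        5L,
    "probable_non", 370L,  23,        45,        5L,        12L,
    "probable",     150L,  79,        123,       14L,       22L,
    "evidence",     71L,   124,       520,       18L,       26L
  )

  cohort_config(
    n_individuals = 2199L,
    seed = seed,
    variants = variants,
    cnvs = cnvs,
    decoys = list(
      n_conflicting = 878L,   # detected, no P/LP submitter: 996 - 118
      n_benign = 5L,
      n_absent = 5L,
      n_low_depth = 1L,
      n_low_callrate = 1L,
      n_callrate_missing = 140L,
      n_catalogue_filler = 4217L  # searched coordinates never detected
    ),
    cnv_decoys = list(
      n_vus = 220L,           # survive filters, curated out: 232 - 12
      n_vus_sv_caller = 17L,  # with the 2 relevant SV-caller events: 19
      n_noncoding = 2011L,
      n_oversize = 800L,
      n_syndromic = 700L,
      n_hl_sample = 1500L
    ),
    n_hl_affected = 89L,
    n_qc_fail = 13L,
    roh_profile = roh_profile,
    n_no_roh_data = 28L,
    self_report = list(yes_high = 160L, yes_low = 31L, no_high = 55L,
                       no_low = 1369L),
    reference = reference
  )
}
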