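# Built-in curated NSHL gene panel.
#
# 137 gene x inheritance-mode association rows: 129 retained associations
# over 121 genes (42 AD-only, 65 AR-only, 8 AD/AR, 6 XL) plus 8 rows removed
# by curation filters (an invalid locus, a gene without a valid transcript,
# a non-Mendelian modifier, four disputed associations, and the refuted
# recessive form of GJB6, whose dominant form is retained). Clinical
# attributes (onset, predominant sound frequency, type, severity,
# progression) are per association: the dominant and recessive forms of a
# dual-mode gene may differ. Coordinates are schematic except for genes
# whose copy-number events the screen reproduces at their genomic positions.

# Gene regions that must carry real coordinates (CNV screening fixtures).
special_gene_coords <- function() {
  tibble::tribble(
    ~gene_symbol, ~contig,  ~start_1based, ~end_1based,
    "STRC",       "chr15",  43599500L,     43658750L,
    "OTOA",       "chr16",  21580000L,     21700000L,
    "ABCC1",      "chr16",  15949577L,     16143074L,
    "NARS2",      "chr11",  78460000L,     78494150L,
    "GRAP",       "chr17",  18900000L,     18970000L,
    "DMXL2",      "chr15",  51442000L,     51518150L,
    "GSDME",      "chr7",   24698000L,     24725150L,
    "OTOG",       "chr11",  17580000L,     17623750L,
    "OTOGL",      "chr12",  80230000L,     80348650L,
    "TRIOBP",     "chr22",  37700000L,     37755750L,
    "TECTA",      "chr11",  121120000L,    121182150L
  )
}

# Handcrafted exon starts (1-based, exon-number order; width 150 bp) for the
# special genes, laid out so each fixture CNV overlaps exactly its printed
# exon range. STRC and DMXL2 are numbered against the coordinate direction
# (minus-strand transcripts).
special_gene_exons <- function() {
  list(
    STRC = c(seq(43658600L, by = -2000L, length.out = 21L),
             seq(43603700L, by = -600L, length.out = 5L),
             c(43600400L, 43599900L, 43599500L)),
    OTOA = seq(21582000L, by = 4200L, length.out = 28L),
    ABCC1 = seq(15950000L, by = 6200L, length.out = 31L),
    NARS2 = c(seq(78460000L, by = 2000L, length.out = 6L),
              c(78477000L, 78480000L, 78483000L, 78486000L),
              seq(78488000L, by = 2000L, length.out = 4L)),
    GRAP = seq(18905000L, by = 12000L, length.out = 5L),
    DMXL2 = c(seq(51518000L, by = -1700L, length.out = 35L),
              seq(51456000L, by = -2000L, length.out = 8L)),
    GSDME = c(24698000L, 24700500L,
              seq(24703000L, by = 3000L, length.out = 6L),
              c(24722000L, 24725000L)),
    OTOG = c(seq(17580000L, by = 600L, length.out = 32L),
             c(17603500L, 17605000L, 17606500L, 17608000L, 17609500L,
               17611000L),
             seq(17614000L, by = 600L, length.out = 17L)),
    OTOGL = c(seq(80230000L, by = 2000L, length.out = 26L),
              80292000L,
              seq(80302000L, by = 1500L, length.out = 32L)),
    TRIOBP = c(seq(37700000L, by = 4000L, length.out = 4L),
               37725000L,
               seq(37734000L, by = 1200L, length.out = 19L)),
    TECTA = c(seq(121120000L, by = 2500L, length.out = 15L),
              c(121164000L, 121167000L, 121170000L, 121173000L),
              seq(121176000L, by = 2000L, length.out = 4L))
  )
}

# Syndromic critical regions (known contiguous-gene deletion/duplication
# syndrome loci) and one coding exon inside each, so events there carry
# coding overlap yet are excluded as syndromic.
syndromic_regions <- function() {
  tibble::tribble(
    ~contig, ~start_1based, ~end_1based,  ~label,
    "chr22", 19000001L,     21000000L,    "22q11.2_deletion",
    "chr15", 22000001L,     28000000L,    "15q11-q13_PWS_AS",
    "chr7",  72000001L,     74000000L,    "7q11.23_Williams",
    "chr17", 34800001L,     36200000L,    "17q11.2_NF1",
    "chr5",  175000001L,    177000000L,   "5q35_Sotos"
  )
}

syndromic_region_exons <- function() {
  tibble::tribble(
    ~gene_symbol, ~contig, ~exon_start,
    "TBX1",       "chr22", 19800001L,
    "UBE3A",      "chr15", 25400001L,
    "ELN",        "chr7",  73400001L,
    "NF1",        "chr17", 35100001L,
    "NSD1",       "chr5",  176500001L
  )
}

#' Built-in NSHL gene panel
#'
#' Returns the package's curated gene panel as a tibble in the panel-table
#' schema (see [read_gene_panel()]), including the associations that the
#' validity filter removes. Writing this tibble to TSV and reading it back
#' through [read_gene_panel()] is the identity.
#'
#' @return Tibble of 137 gene x mode association rows.
#' @export
builtin_panel <- function() {
  mk <- function(gene, mode, validity, onset, freq) {
    tibble(gene_symbol = gene, inheritance_mode = mode, validity = validity,
           onset = onset, frequency_band = freq)
  }
  cyc <- function(n, labels) rep(labels, length.out = n)

  ad <- bind_rows(
    mk(c("CRYM", "GREB1L", "KITLG", "PLS1"), "AD", NA, "prelingual", "all"),
    mk(c("SIX1", "SLC12A2"), "AD", NA, "prelingual", "high"),
    mk("WFS1", "AD", NA, "prelingual", "low"),
    mk(c("ACTG1", "CCDC50", "CD164", "CEACAM16", "COCH", "DIAPH1", "DMXL2",
         "EYA4", "GJB6", "GRHL2", "GSDME", "HOMER2", "KCNQ4", "LMX1A",
         "MCM2", "MIR96", "MYH14"), "AD", NA, "postlingual", "high"),
    mk(c("MYH9", "NLRP3", "OSBPL2", "P2RX2", "PDE1C", "POU4F3", "REST",
         "SLC17A8"), "AD", NA, "postlingual", "all"),
    mk(c("TJP2", "TNC", "ABCC1", "ATP11A"), "AD", NA, "postlingual",
       "middle-high"),
    mk(c("SCD5", "THBS2", "TRRAP"), "AD", NA, "postlingual", "middle"),
    mk("DIABLO", "AD", NA, "postlingual", "low-middle"),
    mk(c("SLC44A4", "NCOA3"), "AD", NA, "postlingual", "low")
  )
  ad$validity <- cyc(nrow(ad), c("limited", "definitive", "limited",
                                 "moderate", "limited", "definitive",
                                 "limited", "moderate", "strong", "limited"))

  ar <- bind_rows(
    mk(c("STRC", "OTOA", "DCDC2", "NARS2", "GRAP", "OTOG", "OTOGL",
         "TRIOBP", "MYO15A", "LOXHD1", "USH1C", "PCDH15", "CIB2", "CLDN14",
         "TMIE", "ESPN", "GIPC3", "LHFPL5", "MYO3A", "SLC26A5", "BSND",
         "RDX", "TPRN", "SYNE4", "MARVELD2", "ADCY1", "BDP1", "CABP2",
         "CLIC5", "ELMOD3", "EPS8", "EPS8L2", "ESRRB", "RIPOR2"),
       "AR", NA, "prelingual", "all"),
    mk(c("SLC26A4", "MPZL2", "GPSM2", "GRXCR2", "HGF"), "AR", NA,
       "prelingual", "high"),
    mk(c("OTOF", "ILDR1"), "AR", NA, "prelingual", "middle-high"),
    mk("GRXCR1", "AR", NA, "prelingual", "middle"),
    mk(c("CDC14A", "ESRP1", "GAB1", "MET", "SPNS2", "TMEM132E", "KARS1",
         "LRTOMT", "MSRB3", "PJVK", "PNPT1", "S1PR2", "SERPINB6"),
       "AR", NA, "prelingual", "unknown"),
    mk(c("PDZD7", "WHRN", "WBP2"), "AR", NA, "postlingual", "all"),
    mk(c("CLDN9", "COL9A2", "CDH23", "ROR1"), "AR", NA, "postlingual",
       "high"),
    mk("CLRN2", "AR", NA, "postlingual", "middle-high"),
    mk(c("TMPRSS3", "CLRN1"), "AR", NA, "postlingual", "unknown")
  )
  ar$validity <- cyc(nrow(ar), c("definitive", "limited", "moderate",
                                 "definitive", "limited", "strong",
                                 "limited", "definitive", "moderate",
                                 "limited"))
  ar_overrides <- c(STRC = "definitive", OTOA = "definitive",
                    TMPRSS3 = "definitive", OTOF = "definitive",
                    SLC26A4 = "strong", MPZL2 = "strong",
                    PDZD7 = "definitive")
  hit <- ar$gene_symbol %in% names(ar_overrides)
  ar$validity[hit] <- unname(ar_overrides[ar$gene_symbol[hit]])

  adar <- bind_rows(
    mk("GJB2", "AD", "definitive", "postlingual", "high"),
    mk("GJB2", "AR", "definitive", "prelingual", "all"),
    mk("MYO7A", "AD", "definitive", "postlingual", "unknown"),
    mk("MYO7A", "AR", "limited", "prelingual", "all"),
    mk("COL11A2", "AD", "moderate", "postlingual", "middle"),
    mk("COL11A2", "AR", "moderate", "prelingual", "all"),
    mk("TECTA", "AD", "definitive", "prelingual", "middle"),
    mk("TECTA", "AR", "definitive", "prelingual", "middle"),
    mk("MYO6", "AD", "definitive", "postlingual", "high"),
    mk("MYO6", "AR", "limited", "prelingual", "all"),
    mk("TMC1", "AD", "definitive", "postlingual", "high"),
    mk("TMC1", "AR", "definitive", "prelingual", "all"),
    mk("PTPRQ", "AD", "limited", "postlingual", "high"),
    mk("PTPRQ", "AR", "definitive", "prelingual", "all"),
    mk("TBC1D24", "AD", "limited", "postlingual", "all"),
    mk("TBC1D24", "AR", "limited", "prelingual", "unknown")
  )

  xl <- bind_rows(
    mk(c("AIFM1", "SMPX"), "XL", "definitive", "postlingual", "all"),
    mk("POU3F4", "XL", "definitive", "prelingual", "all"),
    mk(c("COL4A6", "GPRASP2", "PRPS1"), "XL", "limited", "prelingual",
       "all")
  )

  excluded <- bind_rows(
    mk("DFNX3", "XL", "limited", "unknown", "unknown"),
    mk("KCNJ10", "AR", "disputed", "prelingual", "unknown"),
    mk("ATP2B2", "AD", "limited", "postlingual", "unknown"),
    mk("FOXI1", "AR", "disputed", "prelingual", "all"),
    mk("GJB3", "AD", "disputed", "postlingual", "high"),
    mk("TSPEAR", "AR", "disputed", "prelingual", "all"),
    mk("MYO1A", "AD", "refuted", "postlingual", "unknown"),
    mk("GJB6", "AR", "refuted", "prelingual", "all")
  )
  excluded$no_valid_transcript <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                                    FALSE, FALSE)
  excluded$non_mendelian <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                              FALSE, FALSE)

  panel <- bind_rows(ad, ar, adar, xl, excluded) |>
    mutate(
      no_valid_transcript = dplyr::coalesce(.data$no_valid_transcript,
                                            FALSE),
      non_mendelian = dplyr::coalesce(.data$non_mendelian, FALSE),
      hl_type = if_else(.data$gene_symbol == "SLC26A4", "mixed",
                        "sensorineural"),
      severity = dplyr::case_when(
        .data$inheritance_mode == "AD" ~ "moderate",
        .data$inheritance_mode == "AR" ~ "profound",
        TRUE ~ "range"
      ),
      progression = dplyr::case_when(
        .data$inheritance_mode == "AD" ~ "progressive",
        .data$inheritance_mode == "AR" ~ "stable",
        TRUE ~ "progressive"
      )
    )

  tx_overrides <- c(GJB2 = "NM_004004.6", OTOA = "NM_144672.4",
                    TMPRSS3 = "NM_001256317.3", MPZL2 = "NM_005797.4",
                    DCDC2 = "NM_016356.5", TBC1D24 = "NM_001199107.2",
                    TJP2 = "NM_004817.4", OTOF = "NM_194248.3")
  genes <- unique(panel$gene_symbol)
  tx <- setNames(sprintf("NM_%06d.1", seq_along(genes) + 100000L), genes)
  tx[names(tx_overrides)] <- tx_overrides
  panel$transcript_id <- unname(tx[panel$gene_symbol])
  panel$transcript_id[panel$gene_symbol == "DFNX3"] <- ""

  # Coordinates: real regions for CNV-bearing genes, schematic elsewhere
  # (150 Mb upwards, clear of the fixture CNV loci and syndromic regions).
  special <- special_gene_coords()
  plain <- setdiff(genes, special$gene_symbol)
  is_x <- vapply(plain, function(g) {
    any(panel$inheritance_mode[panel$gene_symbol == g] == "XL")
  }, logical(1))
  auto <- plain[!is_x]
  xg <- plain[is_x]
  coords <- bind_rows(
    tibble(
      gene_symbol = auto,
      contig = paste0("chr", (seq_along(auto) - 1L) %% 22L + 1L),
      start_1based = 150000001L + ((seq_along(auto) - 1L) %/% 22L) * 1000000L
    ),
    tibble(
      gene_symbol = xg,
      contig = "chrX",
      start_1based = 10000001L + (seq_along(xg) - 1L) * 1000000L
    )
  ) |>
    mutate(end_1based = .data$start_1based + 99999L) |>
    bind_rows(special)
  panel |>
    left_join(coords, by = "gene_symbol") |>
    select("gene_symbol", "inheritance_mode", "validity", "onset",
           "hl_type", "severity", "progression", "frequency_band",
           "transcript_id", "no_valid_transcript", "non_mendelian",
           "contig", "start_1based", "end_1based")
}

#' Hearing-loss HPO terms
#'
#' The fixed set of Human Phenotype Ontology identifiers defining
#' hearing-loss phenotypes; an individual whose terms intersect this set is
#' classified as affected and excluded from the unaffected cohort.
#'
#' @return Character vector of HPO ids.
#' @export
hl_hpo_terms <- function() {
  c("HP:0000365", "HP:0000399", "HP:0000407", "HP:0008527", "HP:0008610",
    "HP:0008619", "HP:0008625", "HP:0011476", "HP:0011474", "HP:0000405",
    "HP:0040119", "HP:0008513", "HP:0012716", "HP:0000408", "HP:0008504",
    "HP:0000410", "HP:0001757", "HP:0008573", "HP:0008598", "HP:0008587",
    "HP:0008596", "HP:0005101", "HP:0000364", "HP:0008615", "HP:0009900")
}

# Coding-exon map for the built-in panel as a 1-based tibble
# (gene_symbol, exon_number, start_1based, end_1based): handcrafted layouts
# for the special genes, three schematic exons elsewhere, plus one exon per
# syndromic-region gene.
builtin_exon_map <- function(panel = builtin_panel()) {
  special <- special_gene_exons()
  gene_iv <- panel |>
    distinct(.data$gene_symbol, .data$contig, .data$start_1based)
  rows <- purrr::map_dfr(seq_len(nrow(gene_iv)), function(i) {
    g <- gene_iv$gene_symbol[i]
    if (g %in% names(special)) {
      starts <- special[[g]]
      width <- 150L
    } else {
      starts <- gene_iv$start_1based[i] + c(10000L, 50000L, 90000L)
      width <- 200L
    }
    tibble(gene_symbol = g, contig = gene_iv$contig[i],
           exon_number = seq_along(starts),
           start_1based = as.integer(starts),
           end_1based = as.integer(starts) + width - 1L)
  })
  syn <- syndromic_region_exons() |>
    mutate(exon_number = 1L, start_1based = .data$exon_start,
           end_1based = .data$exon_start + 199L) |>
    select("gene_symbol", "contig", "exon_number", "start_1based",
           "end_1based")
  bind_rows(rows, syn)
}
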