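# Sample QC, phenotype exclusion, genotype counting, allele frequencies,
# per-gene combined summaries, and carrier categorization.

mk_qc <- function(n = 1, ...) {
  base <- tibble::tibble(
    sample_id = sprintf("I%03d", seq_len(n)),
    mapped_read_pct = 99, autosome_median_coverage = 35,
    uniformity_pct = 90, contamination_pct = 0.5, callability_pct = 98,
    q30_pct = 93, chimeric_pct = 1, duplicate_pct = 5
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

test_that("sample QC boundaries follow the printed comparators exactly", {
  # coverage exactly 20X passes (inclusive); mapped reads exactly 98 fails
  expect_equal(nrow(apply_sample_qc(
    mk_qc(autosome_median_coverage = 20))$passing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(mapped_read_pct = 98))$failing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(contamination_pct = 2))$failing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(callability_pct = 95))$passing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(uniformity_pct = 80))$passing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(q30_pct = 90))$passing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(chimeric_pct = 5))$failing), 1)
  expect_equal(nrow(apply_sample_qc(mk_qc(duplicate_pct = 10))$failing), 1)
  failing <- apply_sample_qc(mk_qc(mapped_read_pct = 98))$failing
  expect_equal(failing$failed_metrics, "mapped_read_pct")
  expect_error(apply_sample_qc(mk_qc()[, -3]), "missing metric")
  expect_error(apply_sample_qc(mk_qc(q30_pct = NA)), "Missing")
})

test_that("phenotype exclusion is set intersection with the HL term list", {
  hl <- hl_hpo_terms()
  ind <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    hpo_terms = c("HP:0001250;HP:0000365", "HP:0001250", "")
  )
  sp <- split_by_phenotype(ind, hl)
  expect_equal(sp$affected$sample_id, "A")
  expect_setequal(sp$unaffected$sample_id, c("B", "C"))
  expect_error(split_by_phenotype(ind, character(0)), "non-empty")

  # random assignment equals a brute-force set-intersection scan
  set.seed(17)
  pool <- c(hl[1:5], sprintf("HP:%07d", 1:20))
  for (i in 1:10) {
    ind <- tibble::tibble(
      sample_id = sprintf("I%03d", 1:40),
      hpo_terms = vapply(1:40, function(j) {
        paste(sample(pool, sample(0:4, 1)), collapse = ";")
      }, character(1))
    )
    sp <- split_by_phenotype(ind, hl)
    want <- vapply(strsplit(ind$hpo_terms, ";"),
                   function(t) length(intersect(t, hl)) > 0, logical(1))
    expect_setequal(sp$affected$sample_id, ind$sample_id[want])
  }
})

test_that("genotype counting matches a brute-force tally and the printed example", {
  samples <- sprintf("I%04d", 1:2097)
  plant <- tibble::tibble(
    key = "chr13:1000:AC:A",
    sample_id = samples[1:29],
    genotype = c(rep("het", 28), "hom_alt"),
    depth = 30L
  )
  calls <- make_calls("chr13:1000:AC:A", samples, plant)
  got <- count_genotypes(calls, n_cohort = 2097)
  expect_equal(got$het_count, 28)
  expect_equal(got$hom_count, 1)
  expect_equal(got$n_genotyped, 2097)
  expect_equal(got$allele_count, 30)

  # no carriers
  empty <- count_genotypes(make_calls("chr1:1:A:G", samples[1:50]),
                           n_cohort = 50)
  expect_equal(c(empty$het_count, empty$hom_count), c(0, 0))

  # random genotype matrices vs direct tally
  set.seed(23)
  keys <- sprintf("chr2:%d:A:G", 1:4 * 50)
  for (i in 1:10) {
    plant <- tibble::tibble(
      key = sample(keys, 30, replace = TRUE),
      sample_id = sample(samples[1:60], 30, replace = TRUE),
      genotype = sample(c("het", "hom_alt", "hemi_alt", "missing"), 30,
                        replace = TRUE),
      depth = 30L
    ) |> dplyr::distinct(key, sample_id, .keep_all = TRUE)
    calls <- make_calls(keys, samples[1:60], plant)
    got <- count_genotypes(calls, n_cohort = 60) |> dplyr::arrange(key)
    want <- calls |>
      dplyr::group_by(key) |>
      dplyr::summarise(het = sum(genotype == "het"),
                       hom = sum(genotype == "hom_alt"),
                       hemi = sum(genotype == "hemi_alt"),
                       ngt = 60 - sum(genotype == "missing")) |>
      dplyr::arrange(key)
    expect_equal(got$het_count, want$het)
    expect_equal(got$hom_count, want$hom)
    expect_equal(got$hemi_count, want$hemi)
    expect_equal(got$n_genotyped, want$ngt)
  }
})

test_that("allele frequency reproduces the printed percentages at 2 decimals", {
  expect_equal(round_half_up(100 * allele_frequency(28, 1, 2097), 2), 0.72)
  expect_equal(round_half_up(100 * allele_frequency(23, 0, 2097), 2), 0.55)
  expect_equal(allele_frequency(0, 0, 2097), 0)
  expect_equal(allele_frequency(1, 0, 10, hemi_count = 1), 2 / 20)
  expect_error(allele_frequency(1, 0, 0), "positive")
})

test_that("per-gene combined summary sums allele counts across mechanisms", {
  vc <- tibble::tibble(
    gene_symbol = c("STRC", "STRC", "STRC", "GJB2", "GJB2"),
    key = c("v1", "cnv1", "cnv2", "v2", "v3"),
    mechanism = c("sequence", "cnv", "cnv", "sequence", "sequence"),
    het_count = c(3L, 38L, 1L, 28L, 36L),
    hom_count = c(0L, 0L, 0L, 1L, 0L),
    allele_count = c(3L, 38L, 1L, 30L, 36L)
  )
  gs <- summarize_gene_burden(vc, n_cohort = 2097)
  strc <- gs[gs$gene_symbol == "STRC" & gs$mechanism == "combined", ]
  expect_equal(strc$allele_count, 42)
  expect_equal(round(strc$combined_af, 4), 0.0100)
  gjb2 <- gs[gs$gene_symbol == "GJB2" & gs$mechanism == "combined", ]
  expect_equal(gjb2$allele_count, 66)
  expect_equal(round(gjb2$combined_af, 4), 0.0157)
  seq_strc <- gs[gs$gene_symbol == "STRC" & gs$mechanism == "sequence", ]
  expect_equal(seq_strc$allele_count, 3)
  # no variants -> absent gene; zero-count row behaves
  expect_equal(nrow(gs[gs$gene_symbol == "OTOF", ]), 0)
})

test_that("allele-count aggregation stays exact when carriers share variants", {
  # one individual carries two variants of the same gene: summing per-variant
  # AFs would double-count the carrier, allele counts do not
  vc <- tibble::tibble(
    gene_symbol = "G", key = c("v1", "v2"), mechanism = "sequence",
    het_count = c(1L, 1L), hom_count = 0L, allele_count = c(1L, 1L)
  )
  gs <- summarize_gene_burden(vc, n_cohort = 100)
  comb <- gs[gs$mechanism == "combined", ]
  expect_equal(comb$allele_count, 2)
  expect_equal(comb$combined_af, 2 / 200)
})

test_that("carrier categories follow the AD > AD/AR > AR precedence and partition", {
  panel <- tiny_panel()  # GENEA AR-only, GENEB AD-only, GENEC AD/AR
  carriers <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S3", "S4", "S4"),
    gene_symbol = c("GENEA", "GENEC", "GENEB", "GENEA", "GENEC", "GENEA"),
    mechanism = "sequence"
  )
  got <- classify_carriers(carriers, panel)
  cats <- tibble::deframe(got$per_individual)
  expect_equal(unname(cats[c("S1", "S2", "S3", "S4")]),
               c("AR_only", "AD_AR_gene", "AD_only", "AD_AR_gene"))
  expect_equal(sum(got$tallies$n),
               dplyr::n_distinct(carriers$sample_id))
  expect_equal(got$n_ad_implicated, 3)        # S2, S3, S4
  expect_equal(got$n_recessive_implicated, 4) # all touch an AR-capable gene
  expect_error(classify_carriers(
    tibble::tibble(sample_id = "S9", gene_symbol = "NOPE",
                   mechanism = "sequence"), panel
  ), "absent from retained panel")
})
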