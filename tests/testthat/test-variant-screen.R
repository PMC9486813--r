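# Catalogue preselection, call-level QC, curation, and the mitochondrial
# lookup screen.

random_catalogue <- function(n, genes) {
  tibble::tibble(
    contig = "chr1",
    pos = seq_len(n) * 10L,
    ref = "A", alt = "G",
    gene_symbol = sample(genes, n, replace = TRUE),
    hgvs_c = sprintf("c.%d", seq_len(n)),
    hgvs_p = "p.?",
    aggregate_class = sample(c("P", "LP", "conflicting", "VUS", "LB", "B"),
                             n, replace = TRUE),
    any_plp_submitter = sample(c(TRUE, FALSE), n, replace = TRUE)
  ) |>
    dplyr::mutate(key = variant_key(contig, pos, ref, alt))
}

test_that("preselection keeps P/LP and conflicting-with-P/LP records on panel genes", {
  set.seed(41)
  panel <- tiny_panel()
  for (i in 1:20) {
    cat <- random_catalogue(40, c("GENEA", "GENEB", "GENEC", "OFFPANEL"))
    got <- preselect_variants(cat, panel)
    # brute-force row scan with the same predicate
    want <- cat[cat$gene_symbol %in% panel$gene_symbol &
                  (cat$aggregate_class %in% c("P", "LP") |
                     (cat$aggregate_class == "conflicting" &
                        cat$any_plp_submitter)), ]
    expect_identical(got$preselected, want)
    expect_true(all(got$skipped_off_panel$gene_symbol == "OFFPANEL"))
  }
})

test_that("a catalogue of only benign records preselects nothing", {
  cat <- random_catalogue(10, "GENEA") |>
    dplyr::mutate(aggregate_class = rep(c("B", "LB"), 5))
  expect_equal(nrow(preselect_variants(cat, tiny_panel())$preselected), 0)
})

test_that("call-rate QC applies the >=95% boundary over the cohort denominator", {
  samples <- sprintf("I%03d", 1:100)
  calls94 <- make_calls("chr1:100:A:G", samples)
  calls94$genotype[1:6] <- "missing"
  out <- apply_call_qc(calls94, n_samples = 100)
  expect_equal(out$dropped_variants$key, "chr1:100:A:G")
  expect_equal(out$dropped_variants$call_rate, 0.94)

  calls95 <- make_calls("chr1:100:A:G", samples)
  calls95$genotype[1:5] <- "missing"
  out <- apply_call_qc(calls95, n_samples = 100)
  expect_equal(nrow(out$dropped_variants), 0)
})

test_that("depth under 20X silences a call; exactly 20X passes", {
  samples <- sprintf("I%03d", 1:10)
  plant <- tibble::tibble(
    key = "chr1:100:A:G", sample_id = c("I001", "I002"),
    genotype = "het", depth = c(19L, 20L)
  )
  calls <- make_calls("chr1:100:A:G", samples, plant)
  out <- apply_call_qc(calls, n_samples = 10, min_call_rate = 0)
  got <- out$retained_calls
  expect_equal(got$genotype[got$sample_id == "I001"], "missing")
  expect_equal(got$genotype[got$sample_id == "I002"], "het")
})

test_that("QC with zeroed thresholds is the identity on non-missing calls", {
  samples <- sprintf("I%03d", 1:20)
  plant <- tibble::tibble(key = "chr1:100:A:G", sample_id = "I003",
                          genotype = "het", depth = 5L)
  calls <- make_calls(c("chr1:100:A:G", "chr1:200:C:T"), samples, plant,
                      depth = 7L)
  out <- apply_call_qc(calls, min_depth = 0, min_call_rate = 0,
                       n_samples = 20)
  expect_identical(out$retained_calls, calls)
  expect_equal(nrow(out$dropped_variants), 0)
})

test_that("surviving call set equals a brute-force recount on random cohorts", {
  set.seed(42)
  samples <- sprintf("I%03d", 1:50)
  keys <- sprintf("chr1:%d:A:G", 1:8 * 100)
  for (i in 1:10) {
    plant <- tibble::tibble(
      key = sample(keys, 60, replace = TRUE),
      sample_id = sample(samples, 60, replace = TRUE),
      genotype = sample(c("het", "hom_alt", "missing"), 60, replace = TRUE),
      depth = sample(c(5L, 15L, 25L, 40L), 60, replace = TRUE)
    ) |> dplyr::distinct(key, sample_id, .keep_all = TRUE)
    calls <- make_calls(keys, samples, plant)
    out <- apply_call_qc(calls, n_samples = 50)
    # oracle: recount from first principles
    eff <- calls
    eff$genotype[eff$depth < 20] <- "missing"
    rate <- tapply(eff$genotype != "missing", eff$key, mean)
    keep <- names(rate)[rate >= 0.95]
    expect_setequal(unique(out$retained_calls$key), keep)
    expect_setequal(out$dropped_variants$key, setdiff(keys, keep))
    expect_identical(
      out$retained_calls |> dplyr::arrange(key, sample_id),
      eff[eff$key %in% keep, ] |> dplyr::arrange(key, sample_id)
    )
  }
})

test_that("screening order does not matter: permuting rows permutes outputs", {
  set.seed(7)
  samples <- sprintf("I%03d", 1:30)
  calls <- make_calls(sprintf("chr1:%d:A:G", 1:5 * 100), samples)
  perm <- sample(nrow(calls))
  a <- apply_call_qc(calls, n_samples = 30)$retained_calls
  b <- apply_call_qc(calls[perm, ], n_samples = 30)$retained_calls
  expect_identical(a |> dplyr::arrange(key, sample_id),
                   b |> dplyr::arrange(key, sample_id))
})

test_that("curation keeps only P/LP and demands a decision for every variant", {
  pres <- random_catalogue(6, "GENEA") |>
    dplyr::mutate(aggregate_class = "P", any_plp_submitter = TRUE)
  dec <- pres |>
    dplyr::transmute(key, final_class = c("P", "LP", "VUS", "VUS", "LB",
                                          "P"))
  got <- apply_curation(pres, dec)
  expect_equal(nrow(got), 3)
  expect_true(all(got$final_class %in% c("P", "LP")))

  all_p <- pres |> dplyr::transmute(key, final_class = "P")
  expect_identical(apply_curation(pres, all_p) |> dplyr::select(-final_class),
                   pres)

  expect_error(apply_curation(pres, dec[-2, ]), pres$key[2], fixed = TRUE)
})

test_that("filters compose monotonically: each stage returns a subset", {
  set.seed(11)
  panel <- tiny_panel()
  cat <- random_catalogue(30, c("GENEA", "GENEB", "GENEC"))
  pres <- preselect_variants(cat, panel)$preselected
  expect_true(all(pres$key %in% cat$key))
  samples <- sprintf("I%03d", 1:40)
  calls <- make_calls(pres$key, samples)
  qc <- apply_call_qc(calls, n_samples = 40)
  expect_true(all(unique(qc$retained_calls$key) %in% pres$key))
  dec <- pres |> dplyr::transmute(
    key, final_class = sample(c("P", "VUS"), nrow(pres), replace = TRUE)
  )
  cur <- apply_curation(pres, dec)
  expect_true(all(cur$key %in% pres$key))
})

test_that("mitochondrial screen is an exact join on position and alleles", {
  set.seed(5)
  mito <- tibble::tibble(
    contig = "chrM", pos = c(1555L, 3243L, 7445L), ref = c("A", "A", "A"),
    alt = c("G", "G", "G")
  ) |> dplyr::mutate(key = variant_key(contig, pos, ref, alt))
  samples <- sprintf("I%03d", 1:10)
  calls0 <- make_calls(c("chrM:100:A:G", "chr1:500:C:T"), samples)
  expect_equal(nrow(screen_mito(calls0, mito)), 0)

  plant <- tibble::tibble(key = "chrM:1555:A:G", sample_id = "I004",
                          genotype = "hemi_alt", depth = 30L)
  calls1 <- make_calls(c("chrM:1555:A:G", "chrM:100:A:G"), samples, plant)
  got <- screen_mito(calls1, mito)
  expect_equal(nrow(got), 1)
  expect_equal(got$sample_id, "I004")

  # random plantings match a brute-force join
  for (i in 1:5) {
    keys <- sprintf("chrM:%d:A:G", sample(1000:8000, 6))
    plant <- tibble::tibble(
      key = sample(keys, 8, replace = TRUE),
      sample_id = sample(samples, 8, replace = TRUE),
      genotype = "het", depth = 30L
    ) |> dplyr::distinct(key, sample_id, .keep_all = TRUE)
    calls <- make_calls(keys, samples, plant)
    got <- screen_mito(calls, mito)
    want <- plant[plant$key %in% mito$key, ]
    expect_setequal(paste(got$key, got$sample_id),
                    paste(want$key, want$sample_id))
  }
})

test_that("VCF parsing handles phase separators, missing calls, and hemizygotes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=250000000>",
    "##contig=<ID=chrX,length=160000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:30\t1|1:25\t./.:0",
    "chrX\t500\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1:22\t0/0:28\t0|1:31"
  ), path)
  calls <- read_vcf_genotypes(path)
  expect_equal(nrow(calls), 6)
  g <- function(k, s) calls$genotype[calls$key == k & calls$sample_id == s]
  expect_equal(g("chr1:100:A:G", "S1"), "het")
  expect_equal(g("chr1:100:A:G", "S2"), "hom_alt")
  expect_equal(g("chr1:100:A:G", "S3"), "missing")
  expect_equal(g("chrX:500:C:T", "S1"), "hemi_alt")
  expect_equal(g("chrX:500:C:T", "S3"), "het")
  expect_equal(calls$depth[calls$key == "chrX:500:C:T" &
                             calls$sample_id == "S1"], 22L)
  # sample restriction
  expect_setequal(unique(read_vcf_genotypes(path, samples = c("S1", "S2"))
                         $sample_id), c("S1", "S2"))
})

test_that("multi-allelic sites are rejected rather than silently mismatched", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2"
  ), path)
  expect_error(read_vcf_genotypes(path), "Multi-allelic")
})
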