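# CNV coding-overlap, size and syndromic filtering, annotation, recurrence
# aggregation, and curation.

mk_events <- function(contig, start, end, svtype = "DEL",
                      sample_id = sprintf("I%03d", seq_along(start)),
                      source = "cnv_caller") {
  tibble::tibble(
    sample_id = sample_id, contig = contig, start_1based = as.integer(start),
    end_1based = as.integer(end), svtype = svtype, source = source
  ) |>
    dplyr::mutate(size_bp = end_1based - start_1based + 1L,
                  key = paste(contig, start_1based, end_1based, svtype,
                              sep = ":"))
}

mk_regions <- function(contig, start, end, label = "x") {
  tibble::tibble(contig = contig, start_1based = as.integer(start),
                 end_1based = as.integer(end), label = label)
}

test_that("coding filter keeps >=1 bp overlap, including a single shared base", {
  exons <- mk_regions("chr1", c(1000, 5000), c(1200, 5200))
  ev <- mk_events("chr1",
                  start = c(2000, 1200, 600, 5200),
                  end = c(4000, 1500, 999, 6000))
  got <- filter_coding_overlap(ev, exons)
  # intronic event dropped; events sharing exactly one terminal base kept
  expect_setequal(got$start_1based, c(1200L, 5200L))
  expect_error(filter_coding_overlap(ev, exons[0, ]), "Empty")
})

test_that("interval overlap equals the brute-force pairwise scan", {
  set.seed(13)
  for (i in 1:20) {
    q <- mk_events(sample(c("chr1", "chr2"), 15, replace = TRUE),
                   start = sample(1:500, 15), end = 0)
    q$end_1based <- q$start_1based + sample(0:80, 15, replace = TRUE)
    s <- mk_regions(sample(c("chr1", "chr2"), 10, replace = TRUE),
                    start = sample(1:500, 10), end = 0)
    s$end_1based <- s$start_1based + sample(0:40, 10, replace = TRUE)
    got <- nshlcarrier:::overlap_pairs(q, s) |>
      dplyr::arrange(query_row, subject_row)
    want <- brute_overlap(q, s) |>
      dplyr::arrange(query_row, subject_row)
    expect_equal(got, want)
  }
})

test_that("size filter drops events strictly over 1 Mb and logs syndromic hits", {
  syn <- mk_regions("chr22", 19000001, 21000000, "22q11")
  ev <- mk_events("chr22",
                  start = c(100, 100, 19500000, 30000000),
                  end = c(1000099, 1000100, 19700000, 30010000))
  out <- filter_cnv_size_syndromic(ev, syn)
  expect_setequal(out$retained$start_1based, c(100L, 30000000L))
  expect_equal(out$retained$size_bp[out$retained$start_1based == 100L],
               1000000L)
  log <- out$excluded_log
  expect_equal(log$reason[log$key == ev$key[2]], "oversize")
  expect_equal(log$reason[log$key == ev$key[3]], "syndromic")
})

test_that("coding and size filters commute", {
  set.seed(3)
  exons <- mk_regions("chr1", 1:6 * 100000, 1:6 * 100000 + 300)
  syn <- mk_regions("chr1", 900000, 950000, "syn")
  for (i in 1:10) {
    ev <- mk_events("chr1", start = sample(1:1200000, 25), end = 0)
    ev$end_1based <- ev$start_1based + sample(c(10, 1000, 2000000), 25,
                                              replace = TRUE)
    ev$size_bp <- ev$end_1based - ev$start_1based + 1L
    a <- filter_cnv_size_syndromic(filter_coding_overlap(ev, exons),
                                   syn)$retained
    b <- filter_coding_overlap(
      filter_cnv_size_syndromic(ev, syn)$retained, exons
    )
    expect_setequal(a$key, b$key)
  }
})

test_that("the recurrent STRC microdeletion annotates to exons 1-26 of 29", {
  panel <- filter_gene_panel(builtin_panel())$retained
  exons <- nshlcarrier:::builtin_exon_map() |>
    dplyr::mutate(label = paste(gene_symbol, exon_number, sep = "|"))
  ev <- mk_events("chr15", 43600849, 43658715)
  expect_equal(ev$size_bp, 57867L)  # ~57.9 kb, 1-based inclusive size
  ann <- annotate_cnv_genes(ev, panel, exons)
  expect_true("STRC" %in% ann$panel_genes_hit)
  strc <- ann$exon_spans[ann$exon_spans$gene_symbol == "STRC", ]
  expect_equal(c(strc$exon_min, strc$exon_max), c(1L, 26L))
  expect_equal(max(exons$exon_number[exons$gene_symbol == "STRC"]), 29L)
  # the non-recurrent deletion covers the other end of the gene
  ann2 <- annotate_cnv_genes(mk_events("chr15", 43557296, 43603898),
                             panel, exons)
  strc2 <- ann2$exon_spans[ann2$exon_spans$gene_symbol == "STRC", ]
  expect_equal(c(strc2$exon_min, strc2$exon_max), c(22L, 29L))
})

test_that("an event with no exon overlap annotates to empty lists", {
  panel <- filter_gene_panel(builtin_panel())$retained
  exons <- nshlcarrier:::builtin_exon_map()
  ann <- annotate_cnv_genes(mk_events("chr9", 1000, 2000), panel, exons)
  expect_length(ann$panel_genes_hit, 0)
  expect_equal(nrow(ann$exon_spans), 0)
})

test_that("identical events across samples aggregate to one distinct CNV", {
  ev <- mk_events("chr15", rep(43600849, 38), rep(43658715, 38),
                  sample_id = sprintf("I%03d", 1:38))
  agg <- aggregate_recurrent_cnvs(ev)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_carriers, 38)
})

test_that("exact-coordinate duplicates across callers prefer the CNV caller", {
  ev <- dplyr::bind_rows(
    mk_events("chr1", 100, 200, sample_id = "I001", source = "sv_caller"),
    mk_events("chr1", 100, 200, sample_id = "I001", source = "cnv_caller"),
    mk_events("chr1", 100, 200, sample_id = "I002", source = "sv_caller")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ev |> dplyr::select(sample_id:source), path)
  got <- read_cnv_calls(path)
  expect_equal(nrow(got), 2)
  expect_equal(got$source[got$sample_id == "I001"], "cnv_caller")
  expect_equal(got$source[got$sample_id == "I002"], "sv_caller")
})

test_that("CNV curation requires a decision per event and keeps P/LP only", {
  ev <- mk_events("chr1", c(100, 300, 500), c(200, 400, 600))
  dec <- ev |>
    dplyr::distinct(contig, start_1based, end_1based, svtype) |>
    dplyr::mutate(final_class = c("P", "VUS", "LP"),
                  key = paste(contig, start_1based, end_1based, svtype,
                              sep = ":"))
  got <- apply_cnv_curation(ev, dec)
  expect_setequal(got$start_1based, c(100L, 500L))
  all_vus <- dec |> dplyr::mutate(final_class = "VUS")
  expect_equal(nrow(apply_cnv_curation(ev, all_vus)), 0)
  expect_error(apply_cnv_curation(ev, dec[-1, ]), ev$key[1], fixed = TRUE)
})

test_that("interval convention converters are bit-exact both ways", {
  s1 <- c(1L, 100L, 43600849L)
  e1 <- c(1L, 200L, 43658715L)
  bed <- nshlcarrier:::to_bed0(s1, e1)
  back <- nshlcarrier:::from_bed0(bed$start, bed$end)
  expect_identical(back$start_1based, s1)
  expect_identical(back$end_1based, e1)
  expect_identical(bed$end - bed$start, e1 - s1 + 1L)
})
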