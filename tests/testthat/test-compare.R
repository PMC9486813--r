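# From-scratch two-tailed Fisher exact test and Benjamini-Hochberg FDR,
# cross-checked against enumeration, base fisher.test and p.adjust.

test_that("symmetric and degenerate tables give p = 1", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 7), 1)   # empty row
  expect_equal(fisher_exact_2x2(0, 4, 0, 6), 1)   # empty column
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals hypergeometric enumeration for margins up to 60", {
  set.seed(43)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    got <- fisher_exact_2x2(a, b, c, d)
    expect_equal(got, enum_fisher(a, b, c, d), tolerance = 1e-9)
    # independent cross-check against the standard implementation
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(got, min(ft, 1), tolerance = 1e-6)
  }
})

test_that("Fisher p is symmetric under swapping rows or columns", {
  set.seed(47)
  for (i in 1:50) {
    x <- sample(0:25, 4, replace = TRUE)
    p0 <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_2x2(x[3], x[4], x[1], x[2]), p0,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(x[2], x[1], x[4], x[3]), p0,
                 tolerance = 1e-12)
  }
})

test_that("log-space computation survives large counts", {
  p <- fisher_exact_2x2(25, 4169, 60, 2282)
  expect_true(is.finite(p) && p > 0 && p < 1e-6)
})

test_that("BH adjustment matches its step-up definition and p.adjust", {
  expect_equal(adjust_bh(0.02), 0.02)
  expect_equal(adjust_bh(rep(0.3, 5)), rep(0.3, 5))
  set.seed(53)
  for (i in 1:50) {
    m <- sample(1:20, 1)
    p <- runif(m)^2
    got <- adjust_bh(p)
    expect_equal(got, def_bh(p), tolerance = 1e-12)
    expect_equal(got, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_bh(c(0.5, 1.1)), "\\(0, 1\\]")
})

test_that("BH is permutation-equivariant and monotone in raw p", {
  set.seed(59)
  p <- runif(12)
  perm <- sample(12)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  q <- p; q[4] <- min(1, q[4] + 0.2)
  expect_true(all(adjust_bh(q) >= adjust_bh(p) - 1e-12))
  expect_true(all(adjust_bh(p) >= p))
})

test_that("cohort comparison flags match oracle recomputation", {
  set.seed(61)
  keys <- sprintf("chr1:%d:A:G", 1:8 * 100)
  study <- tibble::tibble(
    key = keys,
    allele_count = sample(0:30, 8),
    n_genotyped = 2000L
  )
  reference <- tibble::tibble(
    key = keys,
    alt_allele_count = sample(0:60, 8),
    total_alleles = 2400L
  )
  out <- compare_allele_counts(study, reference, alpha = 0.05)
  cmp <- out$comparisons
  p_want <- mapply(function(sa, ra) {
    enum_p <- stats::fisher.test(matrix(c(sa, 4000 - sa, ra, 2400 - ra),
                                        2, byrow = TRUE))$p.value
    min(enum_p, 1)
  }, cmp$study_alt, cmp$ref_alt)
  expect_equal(cmp$p_value, unname(p_want), tolerance = 1e-6)
  expect_equal(cmp$significant,
               stats::p.adjust(cmp$p_value, "BH") < 0.05)
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
})

test_that("identical cohorts yield no significant differences", {
  study <- tibble::tibble(key = c("a", "b"), allele_count = c(10L, 3L),
                          n_genotyped = 1000L)
  reference <- tibble::tibble(key = c("a", "b"),
                              alt_allele_count = c(10L, 3L),
                              total_alleles = 2000L)
  out <- compare_allele_counts(study, reference)
  expect_false(any(out$comparisons$significant))
  expect_equal(out$comparisons$p_value, c(1, 1))
})

test_that("variants with a zero allele total are skipped with a log entry", {
  study <- tibble::tibble(key = c("a", "b"), allele_count = c(1L, 2L),
                          n_genotyped = c(0L, 100L))
  reference <- tibble::tibble(key = c("a", "b"),
                              alt_allele_count = c(1L, 2L),
                              total_alleles = c(200L, 200L))
  out <- compare_allele_counts(study, reference)
  expect_equal(out$skipped$key, "a")
  expect_equal(out$comparisons$key, "b")
})
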