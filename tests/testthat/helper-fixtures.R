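# Small in-code fixtures shared across tests.

# Minimal clean panel: one AR gene, one AD gene, one dual-mode gene.
tiny_panel <- function() {
  tibble::tibble(
    gene_symbol = c("GENEA", "GENEB", "GENEC", "GENEC"),
    inheritance_mode = c("AR", "AD", "AD", "AR"),
    validity = c("definitive", "limited", "strong", "moderate"),
    onset = c("prelingual", "postlingual", "postlingual", "prelingual"),
    hl_type = "sensorineural",
    severity = c("profound", "moderate", "moderate", "profound"),
    progression = c("stable", "progressive", "progressive", "stable"),
    frequency_band = c("all", "high", "high", "all"),
    transcript_id = "NM_000001.1",
    no_valid_transcript = FALSE,
    non_mendelian = FALSE,
    contig = "chr1",
    start_1based = c(1000000L, 2000000L, 3000000L, 3000000L),
    end_1based = c(1099999L, 2099999L, 3099999L, 3099999L)
  )
}

# Long-format genotype calls for a synthetic matrix of samples x variants.
# `plant` is a tibble (key, sample_id, genotype, depth).
make_calls <- function(keys, sample_ids, plant = NULL, depth = 30L) {
  calls <- tidyr::expand_grid(key = keys, sample_id = sample_ids) |>
    dplyr::mutate(
      contig = sub(":.*", "", key),
      pos = as.integer(vapply(strsplit(key, ":"), `[`, "", 2)),
      genotype = "hom_ref", depth = depth
    )
  if (!is.null(plant)) {
    idx <- match(paste(plant$key, plant$sample_id),
                 paste(calls$key, calls$sample_id))
    calls$genotype[idx] <- plant$genotype
    if (!is.null(plant$depth)) calls$depth[idx] <- plant$depth
  }
  calls
}

# Brute-force 1-based interval overlap scan: the O(n*m) oracle for the
# IRanges-backed implementation.
brute_overlap <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$contig[i] == subject$contig[j] &&
            query$start_1based[i] <= subject$end_1based[j] &&
            subject$start_1based[j] <= query$end_1based[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(query_row = integer(), subject_row = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(query_row = m[, 1], subject_row = m[, 2])
}

# Exhaustive two-sided Fisher p by enumerating the hypergeometric support
# in plain arithmetic (no log space): the independent oracle.
enum_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by its step-up definition, literally.
def_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(vapply(which(p >= p[i]), function(j) m * p[j] / r[j],
                      numeric(1))))
  }, numeric(1))
}

# A small complete cohort configuration for round-trip tests.
small_config <- function(seed, n = 80L, panel = builtin_panel()) {
  variants <- tibble::tibble(
    gene_symbol = c("GJB2", "GJB2", "STRC", "KCNQ4", "MYO7A"),
    hgvs_c = sprintf("c.%d_t", 1:5),
    hgvs_p = "p.?",
    aggregate_class = c("P", "LP", "conflicting", "P", "LP"),
    any_plp_submitter = TRUE,
    final_class = c("P", "LP", "P", "P", "VUS"),
    n_het = c(4L, 2L, 3L, 1L, 1L),
    n_hom = c(1L, 0L, 0L, 0L, 0L)
  )
  cnvs <- tibble::tibble(
    contig = "chr15", start_1based = 43600849L, end_1based = 43658715L,
    svtype = "DEL", source = "cnv_caller", final_class = "P",
    n_carriers = 3L
  )
  cohort_config(
    n_individuals = n, seed = seed, variants = variants, cnvs = cnvs,
    decoys = list(n_conflicting = 4L, n_benign = 2L, n_absent = 2L,
                  n_low_depth = 1L, n_low_callrate = 1L,
                  n_callrate_missing = as.integer(ceiling(0.06 * (n - 7L))),
                  n_catalogue_filler = 10L),
    cnv_decoys = list(n_vus = 3L, n_noncoding = 3L, n_oversize = 2L,
                      n_syndromic = 2L, n_hl_sample = 2L),
    n_hl_affected = 4L, n_qc_fail = 3L,
    panel = panel
  )
}
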