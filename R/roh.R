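# Runs-of-homozygosity metrics and consanguinity classification.
#
# NROH counts autosomal ROH segments of at least 1 Mb; SROH is their summed
# length in Mb; FROH divides SROH by the autosomal genome length (default
# 2,881 Mb, GRCh38). SROH thresholds classify consanguinity evidence:
# > 123 Mb evidence; 79-123 Mb probable; < 79 Mb probable non-consanguinity,
# except <= 22 Mb which is no evidence (the tighter rule takes precedence).

CONSANGUINITY_CLASSES <- c("no_evidence", "probable_non", "probable",
                           "evidence")

#' Read ROH segments from BED
#'
#' @param path BED file (0-based half-open) whose 4th column is the sample
#'   id.
#' @return Tibble: `sample_id`, `contig`, `start0`, `end0`, `length_bp`.
#' @export
read_roh_segments <- function(path) {
  stopifnot_file(path, "ROH BED")
  bed <- readr::read_tsv(path, col_names = c("contig", "start0", "end0",
                                             "sample_id"),
                         col_types = "ciic", progress = FALSE)
  bed <- bed |> mutate(length_bp = .data$end0 - .data$start0)
  if (any(bed$length_bp <= 0)) abort("ROH segment with non-positive length")
  bed |> select("sample_id", "contig", "start0", "end0", "length_bp")
}

#' Per-sample ROH metrics
#'
#' Counts and sums autosomal segments of at least `min_len_bp`; segments on
#' X, Y or M contigs are excluded. Order-invariant; splitting a qualifying
#' segment into two adjacent qualifying halves leaves SROH unchanged and
#' increments NROH.
#'
#' @param segments ROH tibble (from [read_roh_segments()]), one or more
#'   samples.
#' @param min_len_bp Minimum qualifying segment length (default 1 Mb).
#' @param autosome_length_mb FROH denominator in Mb (default 2,881, the
#'   GRCh38 autosomal length).
#' @return Tibble: `sample_id`, `nroh`, `sroh_mb`, `froh`,
#'   `consanguinity_class`.
#' @export
roh_sample_metrics <- function(segments, min_len_bp = 1000000,
                               autosome_length_mb = 2881) {
  if (any(segments$length_bp < 0)) abort("Negative-length ROH segment")
  metrics <- segments |>
    filter(!.data$contig %in% c("chrX", "chrY", "chrM", "X", "Y", "MT")) |>
    filter(.data$length_bp >= min_len_bp) |>
    group_by(.data$sample_id) |>
    summarise(
      nroh = dplyr::n(),
      sroh_mb = sum(.data$length_bp) / 1e6,
      .groups = "drop"
    )
  absent <- setdiff(unique(segments$sample_id), metrics$sample_id)
  if (length(absent) > 0) {
    metrics <- bind_rows(metrics,
                         tibble(sample_id = absent, nroh = 0L, sroh_mb = 0))
  }
  metrics |>
    mutate(
      froh = .data$sroh_mb / autosome_length_mb,
      consanguinity_class = classify_consanguinity(.data$sroh_mb)
    ) |>
    arrange(.data$sample_id)
}

#' Classify consanguinity evidence from SROH
#'
#' Step function, non-decreasing in SROH: <= 22 Mb no evidence; (22, 79) Mb
#' probable non-consanguinity; \[79, 123\] Mb probable consanguinity;
#' > 123 Mb evidence of consanguinity. The <= 22 Mb rule takes precedence
#' over the < 79 Mb rule where they overlap.
#'
#' @param sroh_mb Summed qualifying ROH length in Mb (vectorized, >= 0).
#' @return Character vector of classes.
#' @export
classify_consanguinity <- function(sroh_mb) {
  if (any(sroh_mb < 0)) abort("sroh_mb must be non-negative")
  dplyr::case_when(
    sroh_mb > 123 ~ "evidence",
    sroh_mb >= 79 ~ "probable",
    sroh_mb > 22 ~ "probable_non",
    TRUE ~ "no_evidence"
  )
}

#' Reconcile ROH-based classes with self-reported consanguinity
#'
#' A mismatch is a positive self-report with an ROH class below probable, or
#' a negative self-report with an ROH class of probable or above. Unknown or
#' absent self-reports are excluded from the rate denominator.
#'
#' @param metrics Tibble from [roh_sample_metrics()].
#' @param individuals Tibble with `sample_id` and
#'   `consanguinity_self_report` (yes/no/unknown).
#' @return List: `table` (per-individual join with `mismatch` flag),
#'   `mismatch_rate` (fraction among known self-reports with ROH data).
#' @export
reconcile_consanguinity <- function(metrics, individuals) {
  joined <- individuals |>
    select("sample_id", "consanguinity_self_report") |>
    inner_join(metrics, by = "sample_id") |>
    mutate(mismatch = dplyr::case_when(
      .data$consanguinity_self_report == "yes" &
        .data$consanguinity_class %in% c("probable_non", "no_evidence") ~ TRUE,
      .data$consanguinity_self_report == "no" &
        .data$consanguinity_class %in% c("probable", "evidence") ~ TRUE,
      .data$consanguinity_self_report %in% c("yes", "no") ~ FALSE,
      TRUE ~ NA
    ))
  known <- joined |> filter(!is.na(.data$mismatch))
  list(
    table = joined,
    mismatch_rate = if (nrow(known) > 0) mean(known$mismatch) else NA_real_
  )
}
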