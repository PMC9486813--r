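# Gene panel: loading, gene-disease validity filtering, and summary.
#
# One row of the panel table is one gene x inheritance-mode association
# carrying a ClinGen-style gene-disease validity label (definitive, strong,
# moderate, limited, disputed, refuted) and curated clinical attributes
# (onset, type, severity, progression, predominant sound frequency). Validity
# is an input, not computed: expert curation is judgement, not an algorithm.

PANEL_MODES <- c("AD", "AR", "XL")
PANEL_VALIDITY <- c("definitive", "strong", "moderate", "limited",
                    "disputed", "refuted")
PANEL_ONSET <- c("prelingual", "postlingual", "unknown")
PANEL_HL_TYPE <- c("sensorineural", "conductive", "mixed", "central",
                   "unknown")
PANEL_SEVERITY <- c("mild", "moderate", "severe", "profound", "range",
                    "unknown")
PANEL_PROGRESSION <- c("progressive", "stable", "variable", "unknown")
PANEL_FREQUENCY <- c("low", "low-middle", "middle", "middle-high", "high",
                     "all", "unknown")

panel_required_cols <- c(
  "gene_symbol", "inheritance_mode", "validity", "onset", "hl_type",
  "severity", "progression", "frequency_band", "transcript_id",
  "no_valid_transcript", "non_mendelian", "contig", "start_1based",
  "end_1based"
)

#' Read a gene panel table
#'
#' Reads a tab-separated panel of gene x inheritance-mode associations,
#' normalizes enumeration labels (case-insensitive, whitespace-stripped) and
#' validates the schema. Duplicate (gene, mode) rows are rejected: a gene may
#' appear once per inheritance mode only.
#'
#' @param path Path to a UTF-8 TSV with columns `gene_symbol`,
#'   `inheritance_mode` (AD/AR/XL), `validity` (definitive, strong, moderate,
#'   limited, disputed, refuted), `onset`, `hl_type`, `severity`,
#'   `progression`, `frequency_band`, `transcript_id`, flag columns
#'   `no_valid_transcript` and `non_mendelian` (0/1), and genomic interval
#'   columns `contig`, `start_1based`, `end_1based` (1-based inclusive).
#' @return A tibble with one row per association, labels normalized.
#' @export
read_gene_panel <- function(path) {
  stopifnot_file(path, "Gene panel")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(panel_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Panel table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_row <- which(is.na(raw$gene_symbol) | trimws(raw$gene_symbol) == "")
  if (length(bad_row) > 0) {
    abort(sprintf("Malformed panel row (empty gene_symbol) at line %d",
                  bad_row[1] + 1L))
  }
  entries <- tibble(
    gene_symbol = trimws(raw$gene_symbol),
    inheritance_mode = toupper(trimws(raw$inheritance_mode)),
    validity = normalize_enum(raw$validity, PANEL_VALIDITY, "validity"),
    onset = normalize_enum(raw$onset, PANEL_ONSET, "onset"),
    hl_type = normalize_enum(raw$hl_type, PANEL_HL_TYPE, "hl_type"),
    severity = normalize_enum(raw$severity, PANEL_SEVERITY, "severity"),
    progression = normalize_enum(raw$progression, PANEL_PROGRESSION,
                                 "progression"),
    frequency_band = normalize_enum(raw$frequency_band, PANEL_FREQUENCY,
                                    "frequency_band"),
    transcript_id = dplyr::coalesce(trimws(raw$transcript_id), ""),
    no_valid_transcript = as.integer(raw$no_valid_transcript) == 1L,
    non_mendelian = as.integer(raw$non_mendelian) == 1L,
    contig = trimws(raw$contig),
    start_1based = as.integer(raw$start_1based),
    end_1based = as.integer(raw$end_1based)
  )
  bad_mode <- setdiff(unique(entries$inheritance_mode), PANEL_MODES)
  if (length(bad_mode) > 0) {
    abort(sprintf("Invalid inheritance_mode label(s): %s",
                  paste(bad_mode, collapse = ", ")))
  }
  if (any(entries$start_1based > entries$end_1based, na.rm = TRUE)) {
    abort("Panel interval with start_1based > end_1based")
  }
  dup <- entries |>
    count(.data$gene_symbol, .data$inheritance_mode) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (gene, mode) panel rows: %s",
                  paste(dup$gene_symbol, dup$inheritance_mode,
                        sep = "/", collapse = ", ")))
  }
  entries
}

#' Filter a gene panel on gene-disease validity
#'
#' Removes associations whose validity is `disputed` or `refuted`, and
#' associations flagged as lacking a valid transcript or as non-Mendelian.
#' Exclusion is per association: a gene survives if at least one of its
#' inheritance modes survives (e.g. a gene whose recessive form is refuted
#' keeps its dominant form). Idempotent and monotone.
#'
#' @param entries Panel tibble from [read_gene_panel()].
#' @return A list with `retained` (tibble, subset of `entries`) and
#'   `exclusion_log` (tibble: gene_symbol, inheritance_mode, reason).
#' @export
filter_gene_panel <- function(entries) {
  reason <- dplyr::case_when(
    entries$no_valid_transcript ~ "no_valid_transcript",
    entries$non_mendelian ~ "non_mendelian",
    entries$validity %in% c("disputed", "refuted") ~ entries$validity,
    TRUE ~ NA_character_
  )
  list(
    retained = entries[is.na(reason), , drop = FALSE],
    exclusion_log = tibble(
      gene_symbol = entries$gene_symbol[!is.na(reason)],
      inheritance_mode = entries$inheritance_mode[!is.na(reason)],
      reason = reason[!is.na(reason)]
    )
  )
}

# Inheritance class of a gene given its surviving modes: genes with both AD
# and AR associations form their own AD/AR class; XL is exclusive.
gene_inheritance_class <- function(retained) {
  retained |>
    group_by(.data$gene_symbol) |>
    summarise(
      class = if (all(.data$inheritance_mode == "XL")) "XL"
      else if (all(.data$inheritance_mode == "AD")) "AD"
      else if (all(.data$inheritance_mode == "AR")) "AR"
      else "AD/AR",
      .groups = "drop"
    )
}

#' Summarize a filtered gene panel
#'
#' Cross-tabulates the retained associations by inheritance class (AD-only,
#' AR-only, AD/AR, XL), predominant frequency band and onset, and counts
#' unique genes per class. Genes carrying both AD and AR modes are counted
#' once in the AD/AR class, but each of their two associations contributes a
#' cell to the cross-tab (the two modes may differ in onset and frequency).
#' Unknown clinical attributes are tallied as their own `"unknown"` category
#' rather than dropped.
#'
#' @param retained Retained panel tibble from [filter_gene_panel()].
#' @return A list with `gene_counts` (class, n_genes), `crosstab` (class,
#'   frequency_band, onset, n_associations), `n_unique_genes` and
#'   `n_associations`.
#' @export
summarize_gene_panel <- function(retained) {
  classes <- gene_inheritance_class(retained)
  tab <- retained |>
    left_join(classes, by = "gene_symbol") |>
    count(.data$class, .data$frequency_band, .data$onset,
          name = "n_associations")
  gene_counts <- classes |>
    count(.data$class, name = "n_genes")
  list(
    gene_counts = gene_counts,
    crosstab = tab,
    n_unique_genes = dplyr::n_distinct(retained$gene_symbol),
    n_associations = nrow(retained)
  )
}
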