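# Copy-number / small unbalanced SV screening: coding-overlap, size and
# syndromic-critical-region filters, panel-gene and exon-span annotation,
# recurrence aggregation, and curation.
#
# Coordinate conventions: event tables carry 1-based inclusive coordinates
# (size_bp = end - start + 1, so the recurrent STRC deletion
# chr15:43600849_43658715 measures 57,867 bp); BED region maps are 0-based
# half-open and converted on read. Overlap queries run through IRanges.

#' Read CNV / small-SV calls
#'
#' Deduplicates exact-coordinate duplicates per sample across sources in
#' favor of the `cnv_caller` record (small unbalanced SVs re-detected by the
#' CNV caller are the same event).
#'
#' @param path TSV with columns `sample_id`, `contig`, `start_1based`,
#'   `end_1based`, `svtype` (DEL/DUP), `source` (cnv_caller/sv_caller).
#' @return Tibble with `size_bp` and `key` columns.
#' @export
read_cnv_calls <- function(path) {
  stopifnot_file(path, "CNV calls")
  ev <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", contig = "c", start_1based = "i", end_1based = "i",
    svtype = "c", source = "c"
  ), progress = FALSE)
  bad <- setdiff(unique(ev$svtype), c("DEL", "DUP"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown svtype label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(ev$start_1based > ev$end_1based)) {
    abort("CNV event with start > end")
  }
  ev |>
    mutate(
      size_bp = .data$end_1based - .data$start_1based + 1L,
      key = cnv_key(.data$contig, .data$start_1based, .data$end_1based,
                    .data$svtype),
      source = factor(.data$source, levels = c("cnv_caller", "sv_caller"))
    ) |>
    arrange(.data$source) |>
    distinct(.data$sample_id, .data$key, .keep_all = TRUE) |>
    mutate(source = as.character(.data$source)) |>
    arrange(.data$sample_id, .data$contig, .data$start_1based)
}

#' Read a BED region map
#'
#' @param path BED file (0-based half-open) whose 4th column is a label:
#'   `gene|exon_number` for coding-exon maps, a syndrome label for syndromic
#'   critical-region maps.
#' @return Tibble: `contig`, `start_1based`, `end_1based`, `label` (plus
#'   `gene_symbol`/`exon_number` when labels carry them).
#' @export
read_region_bed <- function(path) {
  stopifnot_file(path, "Region BED")
  bed <- readr::read_tsv(path, col_names = c("contig", "start0", "end0",
                                             "label"),
                         col_types = "ciic", progress = FALSE)
  if (any(bed$end0 <= bed$start0)) abort("Malformed BED interval (end <= start)")
  out <- bed |>
    mutate(start_1based = .data$start0 + 1L, end_1based = .data$end0) |>
    select("contig", "start_1based", "end_1based", "label")
  if (all(grepl("|", out$label, fixed = TRUE))) {
    parts <- stringr::str_split_fixed(out$label, stringr::fixed("|"), 2)
    out$gene_symbol <- parts[, 1]
    out$exon_number <- suppressWarnings(as.integer(parts[, 2]))
  }
  out
}

# IRanges-backed overlap: returns a tibble (query_row, subject_row) of all
# >= 1 bp overlaps between two interval tibbles (1-based inclusive),
# per-contig. The brute-force pairwise scan is the test oracle.
overlap_pairs <- function(query, subject) {
  hits <- purrr::map_dfr(intersect(unique(query$contig),
                                   unique(subject$contig)), function(ctg) {
    qi <- which(query$contig == ctg)
    si <- which(subject$contig == ctg)
    qr <- IRanges::IRanges(query$start_1based[qi], query$end_1based[qi])
    sr <- IRanges::IRanges(subject$start_1based[si], subject$end_1based[si])
    ov <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    tibble(query_row = qi[S4Vectors::queryHits(ov)],
           subject_row = si[S4Vectors::subjectHits(ov)])
  })
  if (nrow(hits) == 0) {
    hits <- tibble(query_row = integer(), subject_row = integer())
  }
  hits
}

#' Filter CNV events on coding overlap
#'
#' Keeps events overlapping at least one base pair of any coding interval;
#' events confined to noncoding sequence are dropped. A single shared
#' terminal base counts as overlap.
#'
#' @param events CNV tibble from [read_cnv_calls()].
#' @param exons Coding-exon region map from [read_region_bed()].
#' @return Subset of `events`.
#' @export
filter_coding_overlap <- function(events, exons) {
  if (nrow(exons) == 0) abort("Empty coding-exon map")
  if (nrow(events) == 0) return(events)
  hits <- overlap_pairs(events, exons)
  events[sort(unique(hits$query_row)), , drop = FALSE]
}

#' Filter CNV events on size and syndromic critical regions
#'
#' Drops events larger than `max_size_bp` (strictly greater: a 1,000,000 bp
#' event is retained, 1,000,001 bp is dropped) and events overlapping any
#' syndromic critical region (known microdeletion/microduplication syndrome
#' loci), logging a reason per exclusion.
#'
#' @param events Coding-filtered CNV tibble.
#' @param syndromic Syndromic-region map from [read_region_bed()].
#' @param max_size_bp Maximum event size (default 1 Mb).
#' @return List: `retained` (tibble), `excluded_log` (tibble: sample_id, key,
#'   reason in {oversize, syndromic}).
#' @export
filter_cnv_size_syndromic <- function(events, syndromic,
                                      max_size_bp = 1000000L) {
  reason <- rep(NA_character_, nrow(events))
  reason[events$size_bp > max_size_bp] <- "oversize"
  if (nrow(events) > 0 && nrow(syndromic) > 0) {
    hits <- overlap_pairs(events, syndromic)
    syn <- setdiff(unique(hits$query_row), which(!is.na(reason)))
    reason[syn] <- "syndromic"
  }
  list(
    retained = events[is.na(reason), , drop = FALSE],
    excluded_log = tibble(
      sample_id = events$sample_id[!is.na(reason)],
      key = events$key[!is.na(reason)],
      reason = reason[!is.na(reason)]
    )
  )
}

#' Annotate a CNV event with panel genes and exon spans
#'
#' @param event One-row CNV tibble (or a list with `contig`, `start_1based`,
#'   `end_1based`).
#' @param panel Retained panel tibble (gene intervals).
#' @param exons Coding-exon map carrying `gene_symbol` and `exon_number`.
#' @return List: `panel_genes_hit` (character), `exon_spans` (tibble:
#'   gene_symbol, exon_min, exon_max, n_exons).
#' @export
annotate_cnv_genes <- function(event, panel, exons) {
  ev <- tibble(contig = event$contig[1],
               start_1based = event$start_1based[1],
               end_1based = event$end_1based[1])
  gene_iv <- panel |>
    distinct(.data$gene_symbol, .data$contig, .data$start_1based,
             .data$end_1based)
  ghits <- overlap_pairs(ev, gene_iv)
  genes <- sort(unique(gene_iv$gene_symbol[ghits$subject_row]))
  spans <- tibble(gene_symbol = character(), exon_min = integer(),
                  exon_max = integer(), n_exons = integer())
  if (!is.null(exons$exon_number)) {
    ehits <- overlap_pairs(ev, exons)
    if (nrow(ehits) > 0) {
      spans <- exons[ehits$subject_row, , drop = FALSE] |>
        filter(.data$gene_symbol %in% genes) |>
        group_by(.data$gene_symbol) |>
        summarise(exon_min = min(.data$exon_number),
                  exon_max = max(.data$exon_number),
                  n_exons = dplyr::n(), .groups = "drop")
    }
  }
  list(panel_genes_hit = genes, exon_spans = spans)
}

#' Aggregate recurrent CNV events across samples
#'
#' Exact-coordinate identity defines recurrence: events sharing (contig,
#' start, end, svtype) across samples aggregate to one distinct CNV with a
#' carrier count. No reciprocal-overlap clustering is attempted.
#'
#' @param events CNV tibble.
#' @return Tibble: one row per distinct CNV with `n_carriers`.
#' @export
aggregate_recurrent_cnvs <- function(events) {
  events |>
    group_by(.data$key, .data$contig, .data$start_1based, .data$end_1based,
             .data$svtype, .data$size_bp) |>
    summarise(n_carriers = dplyr::n_distinct(.data$sample_id),
              .groups = "drop") |>
    arrange(.data$contig, .data$start_1based)
}

#' Read CNV curation decisions
#'
#' @param path TSV with columns `contig`, `start_1based`, `end_1based`,
#'   `svtype`, `final_class`, `acmg_criteria`.
#' @return Tibble with a `key` column.
#' @export
read_cnv_decisions <- function(path) {
  stopifnot_file(path, "CNV curation decisions")
  dec <- readr::read_tsv(path, col_types = readr::cols(
    contig = "c", start_1based = "i", end_1based = "i", svtype = "c",
    final_class = "c", acmg_criteria = "c"
  ), progress = FALSE)
  bad <- setdiff(unique(dec$final_class), FINAL_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown final_class label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dec <- dec |>
    mutate(key = cnv_key(.data$contig, .data$start_1based, .data$end_1based,
                         .data$svtype))
  if (anyDuplicated(dec$key)) {
    abort(sprintf("Multiple CNV decisions for event %s",
                  dec$key[duplicated(dec$key)][1]))
  }
  dec
}

#' Apply curation decisions to CNV events
#'
#' Every surviving event must carry a decision keyed by (contig, start, end,
#' svtype); only events curated P or LP survive.
#'
#' @param events Filtered CNV tibble.
#' @param decisions Tibble from [read_cnv_decisions()].
#' @return Subset of `events` with a `final_class` column.
#' @export
apply_cnv_curation <- function(events, decisions) {
  missing_keys <- setdiff(events$key, decisions$key)
  if (length(missing_keys) > 0) {
    abort(sprintf("No curation decision for CNV event(s): %s",
                  paste(utils::head(missing_keys, 5), collapse = ", ")))
  }
  events |>
    inner_join(decisions |> select("key", "final_class"), by = "key") |>
    filter(.data$final_class %in% c("P", "LP"))
}
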