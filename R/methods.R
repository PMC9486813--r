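# S3 methods for screen results: print, broom-style tidy()/glance(), and a
# ggplot2 autoplot() of the selection funnel.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.nshl_screen <- function(x, ...) {
  cs <- x$carrier_stats
  cat("<nshl_screen>\n")
  cat(sprintf("  Unaffected cohort: %d individuals\n", cs$n_cohort))
  cat(sprintf("  Sequence-variant heterozygotes: %d (%s)\n",
              cs$n_seq_het, format_pct(cs$n_seq_het / cs$n_cohort)))
  cat(sprintf("  CNV heterozygotes: %d (%s)\n",
              cs$n_cnv_het, format_pct(cs$n_cnv_het / cs$n_cohort)))
  cat(sprintf("  Homozygotes: %d (%s)\n",
              cs$n_hom, format_pct(cs$n_hom / cs$n_cohort)))
  cat(sprintf("  Retained P/LP sequence variants: %d in %d genes\n",
              nrow(x$variants$per_variant),
              dplyr::n_distinct(x$variants$per_variant$gene_symbol)))
  cat(sprintf("  Clinically relevant CNVs: %d distinct in %d carriers\n",
              nrow(x$cnvs$summary), sum(x$cnvs$summary$n_carriers)))
  cat(sprintf("  Projected AR disease burden: %.2f per 1,000 (1:%d)\n",
              x$hw$all$per_1000, as.integer(x$hw$all$one_in_x)))
  invisible(x)
}

#' Tidy a screen result
#'
#' One row per gene and molecular mechanism with carrier counts and
#' combined allele frequency.
#'
#' @param x An `nshl_screen` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nshl_screen
#' @export
tidy.nshl_screen <- function(x, ...) {
  x$gene_summary |>
    mutate(af_pct = round_half_up(100 * .data$combined_af, 2))
}

#' One-row summary of a screen result
#'
#' Cohort sizes, carrier counts and fractions, funnel endpoints, and the
#' projected autosomal-recessive disease burden.
#'
#' @param x An `nshl_screen` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance nshl_screen
#' @export
glance.nshl_screen <- function(x, ...) {
  cs <- x$carrier_stats
  fun <- function(entity, stage) {
    x$funnel$n[x$funnel$entity == entity & x$funnel$stage == stage]
  }
  tibble(
    n_preselected = fun("samples", "preselected"),
    n_qc_pass = fun("samples", "sample_qc_pass"),
    n_unaffected = cs$n_cohort,
    n_variants_detected = fun("variants", "detected"),
    n_variants_plp = fun("variants", "plp_preselected"),
    n_variants_retained = fun("variants", "curated_relevant"),
    n_cnv_curated = fun("cnvs", "distinct_filtered"),
    n_cnv_relevant = fun("cnvs", "distinct_relevant"),
    n_seq_het = cs$n_seq_het,
    pct_seq_het = round_half_up(100 * cs$n_seq_het / cs$n_cohort, 2),
    n_cnv_het = cs$n_cnv_het,
    pct_cnv_het = round_half_up(100 * cs$n_cnv_het / cs$n_cohort, 2),
    n_any_het = cs$n_any_het,
    pct_any_het = round_half_up(100 * cs$n_any_het / cs$n_cohort, 2),
    n_hom = cs$n_hom,
    pct_hom = round_half_up(100 * cs$n_hom / cs$n_cohort, 2),
    n_ad_implicated = cs$n_ad_implicated,
    pct_ad_implicated = round_half_up(
      100 * cs$n_ad_implicated / cs$n_cohort, 2),
    n_recessive_implicated = cs$n_recessive_implicated,
    ar_burden_per_1000 = x$hw$all$per_1000,
    ar_burden_one_in = x$hw$all$one_in_x
  )
}

#' Plot the selection funnel of a screen
#'
#' Bar chart of entity counts per pipeline stage (samples, sequence
#' variants, CNVs), mirroring the monotone selection workflow.
#'
#' @param object An `nshl_screen` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nshl_screen
#' @export
autoplot.nshl_screen <- function(object, ...) {
  df <- object$funnel |>
    group_by(.data$entity) |>
    mutate(stage = factor(.data$stage, levels = .data$stage)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::facet_wrap(~entity, scales = "free") +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(c(0, 0.15))) +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Selection funnel: samples, variants, CNVs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-gene combined allele frequencies
#'
#' Horizontal bars of the top genes' combined pathogenic allele frequencies
#' split by molecular mechanism.
#'
#' @param x An `nshl_screen` object.
#' @param top_n Number of genes (by combined AF) to show.
#' @return A ggplot.
#' @export
plot_gene_burden <- function(x, top_n = 10) {
  top <- x$gene_summary |>
    filter(.data$mechanism == "combined") |>
    arrange(dplyr::desc(.data$combined_af)) |>
    utils::head(top_n) |>
    pull(.data$gene_symbol)
  df <- x$gene_summary |>
    filter(.data$gene_symbol %in% top, .data$mechanism != "combined") |>
    mutate(gene_symbol = factor(.data$gene_symbol, levels = rev(top)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_symbol,
                                   y = 100 * .data$combined_af,
                                   fill = .data$mechanism)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "combined allele frequency (%)",
                  fill = "mechanism") +
    ggplot2::theme_minimal()
}
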