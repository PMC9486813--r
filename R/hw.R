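# Hardy-Weinberg projection of autosomal-recessive disease frequency.
#
# For a recessive gene, the fraction of affected individuals (homozygotes or
# compound heterozygotes for pathogenic alleles) at Hardy-Weinberg
# equilibrium is q^2, where q is the gene's combined pathogenic allele
# frequency. Carrier frequency (2pq) observed in heterozygote screening
# relates to q via q = cf / 2 under the approximation p ~ 1, adequate while
# q is small; an exact mode solving 2q(1 - q) = cf is provided for
# sensitivity analysis.

#' Carrier frequency to allele frequency
#'
#' Under p ~ 1, q = carrier_frequency / 2. With `exact = TRUE`, solves the
#' Hardy-Weinberg relation 2q(1 - q) = cf for the smaller root instead; the
#' two differ by O(q^2).
#'
#' @param carrier_frequency Fraction of heterozygous individuals, in [0, 1].
#' @param exact Solve the quadratic instead of halving (default FALSE, the
#'   standard screening approximation).
#' @return Pathogenic allele frequency q.
#' @export
carrier_to_q <- function(carrier_frequency, exact = FALSE) {
  if (any(carrier_frequency < 0 | carrier_frequency > 1)) {
    abort("carrier_frequency must be in [0, 1]")
  }
  if (!exact) {
    carrier_frequency / 2
  } else {
    if (any(carrier_frequency > 0.5)) {
      abort("Exact mode requires carrier_frequency <= 0.5 (2q(1-q) <= 1/2)")
    }
    (1 - sqrt(1 - 2 * carrier_frequency)) / 2
  }
}

#' Project affected frequency from allele frequency
#'
#' @param q Pathogenic allele frequency, in [0, 1] (vectorized).
#' @param gene_symbol Optional gene labels carried through.
#' @return Tibble: `gene_symbol`, `q`, `q_squared`, `per_1000` (q^2 x 1,000,
#'   half-up to 2 decimals), `one_in_x` (1/q^2 rounded to nearest integer;
#'   NA at q = 0).
#' @export
hw_affected_frequency <- function(q, gene_symbol = NA_character_) {
  if (any(q < 0 | q > 1)) abort("q must be in [0, 1]")
  q2 <- q * q
  tibble(
    gene_symbol = gene_symbol,
    q = q,
    q_squared = q2,
    per_1000 = round_half_up(q2 * 1000, 2),
    one_in_x = if_else(q2 > 0, round_half_up(1 / q2, 0), NA_real_)
  )
}

#' Combined autosomal-recessive disease burden
#'
#' Sums projected affected frequencies (q^2) over genes with a recessive
#' mode. Genes associated exclusively with dominant (or X-linked)
#' inheritance must not be passed in: heterozygotes for those genes are not
#' recessive carriers, and the contract is enforced with an error.
#'
#' The headline 1-in-X figure is derived from the per-1,000 value after its
#' two-decimal display rounding (0.45/1,000 -> 1:2,222), matching how such
#' summaries are printed; `one_in_x_exact` carries the unrounded reciprocal.
#'
#' @param estimates Tibble from [hw_affected_frequency()] (per-gene rows).
#' @param retained_panel Retained panel tibble used to verify every gene has
#'   an AR mode; omit to skip the check.
#' @return List: `sum_q_squared`, `per_1000`, `one_in_x`, `one_in_x_exact`.
#' @export
combined_recessive_burden <- function(estimates, retained_panel = NULL) {
  if (!is.null(retained_panel) && nrow(estimates) > 0) {
    classes <- gene_inheritance_class(retained_panel)
    eligible <- classes$gene_symbol[classes$class %in% c("AR", "AD/AR")]
    bad <- setdiff(estimates$gene_symbol, eligible)
    if (length(bad) > 0) {
      abort(sprintf(
        "Gene(s) without an autosomal-recessive mode in burden input: %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  s <- sum(estimates$q_squared)
  per_1000 <- round_half_up(s * 1000, 2)
  list(
    sum_q_squared = s,
    per_1000 = per_1000,
    one_in_x = if (per_1000 > 0) round_half_up(1000 / per_1000, 0) else NA_real_,
    one_in_x_exact = if (s > 0) 1 / s else NA_real_
  )
}
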