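#' @importFrom rlang .data abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n bind_rows rename
#'   count across if_else row_number pull relocate first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.725 -> 0.73 at two digits), the
#' convention used for the printed percentages in clinical reports, as opposed
#' to [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.7153 * 100, 2)  # 71.53 -> 71.53; display in percent
#' round_half_up(0.125, 2)         # 0.13, not 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalize a hand-curated enumeration column: trim whitespace, lower-case,
# then validate against the allowed labels. `what` names the column in errors.
normalize_enum <- function(x, allowed, what) {
  out <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(out[!is.na(out)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid %s label(s): %s (allowed: %s)",
      what, paste(shQuote(bad), collapse = ", "),
      paste(allowed, collapse = ", ")
    ))
  }
  out
}

# Canonical variant key used to join catalogue, calls, decisions and
# reference counts: "contig:pos:ref:alt".
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# Canonical CNV key: "contig:start:end:svtype" (1-based inclusive coords).
cnv_key <- function(contig, start, end, svtype) {
  paste(contig, start, end, svtype, sep = ":")
}

# 1-based inclusive <-> 0-based half-open converters for BED interchange.
# Bit-exact both ways.
to_bed0 <- function(start_1based, end_1based) {
  list(start = start_1based - 1L, end = end_1based)
}

from_bed0 <- function(start0, end0) {
  list(start_1based = start0 + 1L, end_1based = end0)
}

# Percent display string helper (two decimals, half-up).
format_pct <- function(frac) {
  sprintf("%.2f%%", round_half_up(100 * frac, 2))
}

stopifnot_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, as.character(path)[1]))
  }
  invisible(path)
}
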