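#' Add pseudocounts to a count table
#'
#' @param table Count tibble with a `count` column.
#' @param pc Non-negative pseudocount added to every
#'   (replicate, fraction, variant) cell (default 1).
#' @return The table with `count` incremented by `pc` (numeric when
#'   `pc` is fractional).
#' @export
add_pseudocounts <- function(table, pc = 1) {
  if (pc < 0) stop("pseudocount must be non-negative")
  if (pc == 0) return(table)
  dplyr::mutate(table, count = .data$count + pc)
}

#' Normalize counts within each sorting fraction
#'
#' Divides each (replicate, fraction) column by its own total so that read
#' frequencies are comparable across fractions sequenced to different
#' depths.
#'
#' @param table Count tibble (typically after [add_pseudocounts()]).
#' @return The table with a `freq` column; each (replicate, fraction) sums
#'   to 1.
#' @export
normalize_within_fraction <- function(table) {
  out <- table |>
    dplyr::group_by(.data$replicate, .data$fraction) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(out$.total == 0)) {
    bad <- out |>
      dplyr::filter(.data$.total == 0) |>
      dplyr::distinct(.data$replicate, .data$fraction)
    stop("fraction(s) with zero total counts: ",
         paste(paste0("replicate ", bad$replicate, "/", bad$fraction),
               collapse = ", "),
         "; use a positive pseudocount")
  }
  out |>
    dplyr::mutate(freq = .data$count / .data$.total) |>
    dplyr::select(-".total")
}

#' Normalize frequencies across fractions into fraction distributions
#'
#' For each (replicate, variant), rescales the K within-fraction frequencies
#' to sum to 1 — the per-mutant distribution of reads over sorted fractions,
#' the regression input.
#'
#' @param freqs Output of [normalize_within_fraction()].
#' @return Long tibble with an `x` column; each (replicate, variant) sums
#'   to 1 over fractions.
#' @export
normalize_across_fractions <- function(freqs) {
  freqs |>
    dplyr::group_by(.data$replicate, .data$variant_id) |>
    dplyr::mutate(x = .data$freq / sum(.data$freq)) |>
    dplyr::ungroup() |>
    dplyr::select(-"freq", -"count")
}

#' Counts to fraction distributions in one step
#'
#' The normalization scheme in order: pseudocount, within-fraction, then
#' across-fraction. Within-fraction normalization makes the result invariant
#' to per-fraction sequencing depth; across-fraction normalization turns
#' each variant's row into a probability vector over gates. Variants whose
#' total raw reads (over all fractions and replicates) are at or below
#' `min_reads` are flagged low-coverage; they still receive an `x`.
#'
#' @param table Raw count tibble (codon or aa level).
#' @param pc Pseudocount (default 1).
#' @param min_reads Low-coverage flag threshold (strict `>` to pass;
#'   default 10).
#' @return Long tibble: identity columns, `fraction`, `x`, `low_coverage`.
#' @export
fraction_distributions <- function(table, pc = 1, min_reads = 10L) {
  totals <- table |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(.total_raw = sum(.data$count), .groups = "drop")
  table |>
    add_pseudocounts(pc) |>
    normalize_within_fraction() |>
    normalize_across_fractions() |>
    dplyr::left_join(totals, by = "variant_id") |>
    dplyr::mutate(low_coverage = .data$.total_raw <= min_reads) |>
    dplyr::select(-".total_raw")
}

#' Fraction distributions as a variants-by-K matrix for one replicate
#'
#' @param fd Output of [fraction_distributions()].
#' @param replicate Replicate to extract.
#' @return Numeric matrix, rows named by `variant_id`, columns by fraction.
#' @export
fd_matrix <- function(fd, replicate) {
  wide <- fd |>
    dplyr::filter(.data$replicate == .env$replicate) |>
    dplyr::select("variant_id", "fraction", "x") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "x") |>
    dplyr::arrange(.data$variant_id)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$variant_id
  m[, order(colnames(m)), drop = FALSE]
}
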