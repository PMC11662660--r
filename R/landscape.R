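#' Assemble the position-by-amino-acid fitness landscape
#'
#' Places each amino-acid substitution's activity estimate into a long-form
#' landscape over all positions and mutant amino acids; cells absent from
#' the estimates are masked (missing, not zero). Wild-type identity cells
#' carry the WT estimate and are flagged. Stop (`"*"`) cells are excluded by
#' default, matching how fitness-landscape figures omit the nonsense row.
#'
#' @param estimates An `activity_estimates` tibble from [predict_all()].
#' @param design A `library_design`.
#' @param include_stop Keep the stop column (default `FALSE`).
#' @return Tibble (class `fitness_landscape`): `position`, `wt_aa`,
#'   `mut_aa`, `activity`, `confidence_sd`, `is_wt_cell`, `masked`,
#'   `low_coverage`; with attribute `wt_activity`.
#' @export
build_landscape <- function(estimates, design, include_stop = FALSE) {
  wt_row <- dplyr::filter(estimates, .data$variant_id == "WT")
  if (nrow(wt_row) != 1L) stop("estimates must contain exactly one WT row")
  aa_syms <- design$aa_alphabet
  if (!include_stop) aa_syms <- setdiff(aa_syms, "*")
  grid <- tidyr::expand_grid(position = design$mutable_positions,
                             mut_aa = aa_syms) |>
    dplyr::mutate(wt_aa = design$wt_aa[.data$position])
  ls <- grid |>
    dplyr::left_join(
      dplyr::select(estimates, "position", "mut_aa", "activity",
                    "confidence_sd", "low_coverage"),
      by = c("position", "mut_aa")
    ) |>
    dplyr::mutate(
      is_wt_cell = .data$mut_aa == .data$wt_aa,
      activity = dplyr::if_else(.data$is_wt_cell, wt_row$activity,
                                .data$activity),
      confidence_sd = dplyr::if_else(.data$is_wt_cell, wt_row$confidence_sd,
                                     .data$confidence_sd),
      low_coverage = dplyr::if_else(.data$is_wt_cell,
                                    isTRUE(wt_row$low_coverage),
                                    .data$low_coverage),
      masked = is.na(.data$activity)
    ) |>
    dplyr::select("position", "wt_aa", "mut_aa", "activity",
                  "confidence_sd", "is_wt_cell", "masked", "low_coverage")
  attr(ls, "wt_activity") <- wt_row$activity
  class(ls) <- c("fitness_landscape", class(ls))
  ls
}

mutant_cells <- function(ls, exclude_low_coverage = TRUE) {
  out <- dplyr::filter(ls, !.data$is_wt_cell, !.data$masked)
  if (exclude_low_coverage) {
    out <- dplyr::filter(out, !dplyr::coalesce(.data$low_coverage, FALSE))
  }
  out
}

#' Fraction of mutants as potent as the wild type
#'
#' Percentage of unmasked mutant cells whose activity is at least
#' `threshold_frac` times the wild-type activity (both on the mean
#' log-fluorescence scale) — the landscape's headline mutational-tolerance
#' statistic.
#'
#' @param ls A `fitness_landscape`.
#' @param threshold_frac Wild-type fraction threshold (default 0.9).
#' @param exclude_low_coverage Drop low-coverage cells (default `TRUE`).
#' @return Percentage (0-100).
#' @export
tolerant_fraction <- function(ls, threshold_frac = 0.9,
                              exclude_low_coverage = TRUE) {
  cells <- mutant_cells(ls, exclude_low_coverage)
  if (nrow(cells) == 0L) stop("no unmasked mutant cells")
  wt <- attr(ls, "wt_activity")
  100 * mean(cells$activity >= threshold_frac * wt)
}

#' Per-residue mean activity
#'
#' Arithmetic mean of unmasked mutant-cell activities per position;
#' positions with no unmasked mutant cells get `NA`, not zero.
#'
#' @inheritParams tolerant_fraction
#' @return Tibble `position`, `wt_aa`, `mean_activity`, `n_mutants`.
#' @export
residue_means <- function(ls, exclude_low_coverage = TRUE) {
  cells <- mutant_cells(ls, exclude_low_coverage)
  ls |>
    dplyr::distinct(.data$position, .data$wt_aa) |>
    dplyr::left_join(
      cells |>
        dplyr::group_by(.data$position) |>
        dplyr::summarise(mean_activity = mean(.data$activity),
                         n_mutants = dplyr::n(), .groups = "drop"),
      by = "position"
    ) |>
    dplyr::mutate(n_mutants = dplyr::coalesce(.data$n_mutants, 0L)) |>
    dplyr::arrange(.data$position)
}

#' Activity distributions by residue subgroup
#'
#' Assigns each unmasked mutant cell to its position's annotation group and
#' returns both the raw per-group value lists (violin-plot input) and
#' summary quartiles. Positions missing from the annotation fall into an
#' `"unannotated"` group, so group sizes always partition the cells.
#'
#' @param ls A `fitness_landscape`.
#' @param annotation Tibble with `position` and category columns (e.g.
#'   `burial`, `secondary`, `cas9_contact`, `idr`).
#' @param grouping Name of the category column to group by.
#' @param exclude_low_coverage Drop low-coverage cells (default `TRUE`).
#' @return List: `values` (tibble `group`, `position`, `mut_aa`,
#'   `activity`), `summary` (tibble `group`, `n`, `median`, `q25`, `q75`).
#' @export
group_distributions <- function(ls, annotation, grouping,
                                exclude_low_coverage = TRUE) {
  if (!grouping %in% names(annotation)) {
    stop("annotation has no column '", grouping, "'")
  }
  ann <- annotation |>
    dplyr::select("position", group = dplyr::all_of(grouping))
  values <- mutant_cells(ls, exclude_low_coverage) |>
    dplyr::left_join(ann, by = "position") |>
    dplyr::mutate(group = dplyr::coalesce(.data$group, "unannotated")) |>
    dplyr::select("group", "position", "mut_aa", "activity")
  summary <- values |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$activity),
                     q25 = stats::quantile(.data$activity, 0.25),
                     q75 = stats::quantile(.data$activity, 0.75),
                     .groups = "drop")
  list(values = values, summary = summary)
}

#' Correlation of mutant activity with residue conservation
#'
#' Pearson correlation (with a two-sided t-test p-value) between activities
#' and ConSurf-style conservation scores, either pairing every unmasked
#' mutant cell with its position's score (`level = "mutant"`) or using
#' per-residue mean activities (`level = "residue"`).
#'
#' @param ls A `fitness_landscape`.
#' @param annotation Tibble with `position` and `conservation_score`.
#' @param level `"mutant"` (default) or `"residue"`.
#' @param exclude_low_coverage Drop low-coverage cells (default `TRUE`).
#' @return Tibble with `pearson_r`, `p_value`, `n`.
#' @export
conservation_correlation <- function(ls, annotation,
                                     level = c("mutant", "residue"),
                                     exclude_low_coverage = TRUE) {
  level <- match.arg(level)
  if (!"conservation_score" %in% names(annotation)) {
    stop("annotation has no conservation_score column")
  }
  if (level == "mutant") {
    df <- mutant_cells(ls, exclude_low_coverage) |>
      dplyr::inner_join(
        dplyr::select(annotation, "position", "conservation_score"),
        by = "position")
    act <- df$activity; cons <- df$conservation_score
  } else {
    df <- residue_means(ls, exclude_low_coverage) |>
      dplyr::filter(.data$n_mutants > 0L) |>
      dplyr::inner_join(
        dplyr::select(annotation, "position", "conservation_score"),
        by = "position")
    act <- df$mean_activity; cons <- df$conservation_score
  }
  n <- length(act)
  if (n < 3L) stop("need at least 3 pairs for a correlation")
  if (sd(act) == 0 || sd(cons) == 0) {
    return(tibble(pearson_r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- cor.test(act, cons, method = "pearson")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
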