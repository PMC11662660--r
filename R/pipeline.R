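#' Run the full sort-seq DMS analysis pipeline
#'
#' End-to-end orchestration over pre-counted reads: aggregate codon counts
#' to amino-acid level, normalize into fraction distributions, select the
#' regularization strength by leave-one-out cross-validation on the
#' benchmark mutants, fit one affine model per biological replicate,
#' predict every variant's activity with cross-replicate confidence, and
#' assemble the fitness landscape with its summary statistics. Start from
#' [count_variants()] output when beginning from FASTQ, or from
#' [simulate_sequencing()] output on synthetic data — both paths yield
#' identical downstream results on the same table.
#'
#' @param counts Codon-level count tibble.
#' @param design A `library_design`.
#' @param benchmarks Benchmark flow measurements: events tibble
#'   (`variant_id`, `log_fluorescence`) or pre-binned rows (see
#'   [benchmark_histograms()]).
#' @param annotation Optional per-residue annotation tibble (categories and
#'   `conservation_score`).
#' @param pc Pseudocount (default 1).
#' @param min_reads Detection / low-coverage threshold (default 10).
#' @param B,range Histogram binning (defaults 20 bins on `[0, 14]`).
#' @param lambda_grid Grid for LOO-CV lambda selection.
#' @param lambda Fixed lambda overriding the grid search (optional).
#' @param method Fitting method for the final per-replicate models
#'   (default `"gd"`).
#' @param threshold_frac Wild-type fraction defining tolerance (default
#'   0.9).
#' @param ... Passed to the fitter.
#' @return List (class `sortscape_run`): `design`, `counts_aa`, `detected`,
#'   `fd`, `loo`, `lambda`, `estimates`, `landscape`, `annotation`,
#'   `summary` (a plain list of headline numbers).
#' @export
run_pipeline <- function(counts, design, benchmarks, annotation = NULL,
                         pc = 1, min_reads = 10L, B = 20L, range = c(0, 14),
                         lambda_grid = 10^seq(-4, 1, by = 0.5),
                         lambda = NULL, method = "gd",
                         threshold_frac = 0.9, ...) {
  counts_aa <- aggregate_to_aa(counts)
  detected <- detected_fraction(counts_aa, min_reads = min_reads)
  fd <- fraction_distributions(counts_aa, pc = pc, min_reads = min_reads)
  Y <- benchmark_histograms(benchmarks, B = B, range = range)
  missing <- setdiff(rownames(Y), fd$variant_id)
  if (length(missing) > 0L) {
    stop("benchmark variant(s) absent from the count data: ",
         paste(missing, collapse = ", "))
  }

  reps <- sort(unique(fd$replicate))
  loo_by_rep <- purrr::map(reps, function(r) {
    Xb <- fd_matrix(fd, r)[rownames(Y), , drop = FALSE]
    loo_cv(Xb, Y, lambda_grid = lambda_grid)
  })
  names(loo_by_rep) <- paste0("rep", reps)
  loo_summary <- purrr::imap_dfr(loo_by_rep, function(l, nm) {
    dplyr::mutate(l$summary, replicate = nm)
  }) |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_mse = mean(.data$mean_mse), .groups = "drop")
  selected_lambda <- lambda %||%
    loo_summary$lambda[which.min(loo_summary$mean_mse)]

  estimates <- predict_all(fd, Y, selected_lambda, method = method,
                           range = range, ...)
  ls <- build_landscape(estimates, design)
  tol <- tolerant_fraction(ls, threshold_frac = threshold_frac)
  cons <- if (!is.null(annotation) &&
              "conservation_score" %in% names(annotation)) {
    conservation_correlation(ls, annotation)
  } else NULL

  out <- list(
    design = design, counts_aa = counts_aa, detected = detected, fd = fd,
    loo = list(by_replicate = loo_by_rep, summary = loo_summary),
    lambda = selected_lambda, estimates = estimates, landscape = ls,
    annotation = annotation,
    summary = list(
      percent_detected = detected$percent_detected,
      selected_lambda = selected_lambda,
      mean_loo_mse = min(loo_summary$mean_mse),
      wt_activity = attr(ls, "wt_activity"),
      tolerant_fraction = tol,
      conservation_pearson_r = if (is.null(cons)) NA_real_ else cons$pearson_r,
      conservation_p_value = if (is.null(cons)) NA_real_ else cons$p_value
    )
  )
  class(out) <- "sortscape_run"
  out
}

#' @export
print.sortscape_run <- function(x, ...) {
  s <- x$summary
  cat("<sortscape_run>\n")
  cat(sprintf("  detected mutants: %.1f%% (> min reads)\n", s$percent_detected))
  cat(sprintf("  selected lambda:  %g (mean LOO MSE %.3g)\n",
              s$selected_lambda, s$mean_loo_mse))
  cat(sprintf("  WT activity:      %.2f mean log fluorescence\n", s$wt_activity))
  cat(sprintf("  tolerant mutants: %.1f%% (>= 90%% of WT)\n",
              s$tolerant_fraction))
  if (!is.na(s$conservation_pearson_r)) {
    cat(sprintf("  conservation:     r = %.2f (p = %.2g)\n",
                s$conservation_pearson_r, s$conservation_p_value))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the stage tables as headered TSV (fraction distributions,
#' activity estimates, landscape long format, LOO-CV table), the fitted
#' models as JSON, and the summary as JSON.
#'
#' @param run A `sortscape_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "sortscape_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$fd, file.path(dir, "fraction_distributions.tsv"))
  readr::write_tsv(dplyr::select(run$estimates, -dplyr::any_of("qc_flag")),
                   file.path(dir, "activity_estimates.tsv"))
  readr::write_tsv(as_tibble(run$landscape), file.path(dir, "landscape.tsv"))
  readr::write_tsv(
    purrr::imap_dfr(run$loo$by_replicate,
                    function(l, nm) dplyr::mutate(l$table, replicate = nm)),
    file.path(dir, "loo_cv.tsv"))
  models <- purrr::map(attr(run$estimates, "models"), function(m) {
    list(W = unname(as.matrix(m$W)), b = m$b, lambda = m$lambda,
         method = m$method, fit_meta = m$fit_meta)
  })
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a truth table as TSV
#'
#' @param truth A `variant_truth` table.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(as_tibble(truth), path)
}
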