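#' Bin log-fluorescence events into a normalized histogram
#'
#' Events are assigned to `B` equally spaced half-open bins
#' `[edge_i, edge_{i+1})` over `range`, the last bin right-closed; values
#' outside the range are clamped into the edge bins. The histogram is
#' normalized to sum to one.
#'
#' @param events Numeric vector of log-fluorescence values.
#' @param B Number of bins (default 20).
#' @param range Axis range (default `c(0, 14)`).
#' @return Numeric probability vector of length `B` with attributes
#'   `bin_edges` and `bin_centers`.
#' @export
bin_events <- function(events, B = 20L, range = c(0, 14)) {
  if (length(events) == 0L) stop("cannot bin an empty event list")
  if (B < 2L) stop("need at least 2 bins")
  lo <- range[1L]; hi <- range[2L]
  if (lo >= hi) stop("invalid range")
  width <- (hi - lo) / B
  idx <- floor((events - lo) / width) + 1L
  idx <- pmin(pmax(idx, 1L), B)
  y <- tabulate(idx, nbins = B) / length(events)
  attr(y, "bin_edges") <- seq(lo, hi, length.out = B + 1L)
  attr(y, "bin_centers") <- bin_centers(B, range)
  y
}

#' Bin centers of the log-fluorescence histogram axis
#'
#' @param B Number of bins.
#' @param range Axis range.
#' @return Numeric vector of `B` midpoints.
#' @export
bin_centers <- function(B = 20L, range = c(0, 14)) {
  edges <- seq(range[1L], range[2L], length.out = B + 1L)
  (edges[-1L] + edges[-(B + 1L)]) / 2
}

#' Benchmark histograms from flow events or pre-binned rows
#'
#' @param benchmarks Either a `benchmark_events` tibble
#'   (`variant_id`, `log_fluorescence`) or a tibble with `variant_id` and
#'   pre-binned columns `bin_0` ... `bin_{B-1}` (renormalized to sum 1).
#' @param B,range Binning parameters.
#' @return Matrix (benchmarks x B), rows named by `variant_id`.
#' @export
benchmark_histograms <- function(benchmarks, B = 20L, range = c(0, 14)) {
  if ("log_fluorescence" %in% names(benchmarks)) {
    ids <- unique(benchmarks$variant_id)
    Y <- t(vapply(ids, function(id) {
      as.numeric(bin_events(
        benchmarks$log_fluorescence[benchmarks$variant_id == id], B, range))
    }, numeric(B)))
    rownames(Y) <- ids
    return(Y)
  }
  bin_cols <- grep("^bin_", names(benchmarks), value = TRUE)
  if (length(bin_cols) == 0L) {
    stop("benchmarks must carry log_fluorescence events or bin_* columns")
  }
  bin_cols <- bin_cols[order(as.integer(sub("^bin_", "", bin_cols)))]
  Y <- as.matrix(benchmarks[, bin_cols])
  Y <- Y / rowSums(Y)
  rownames(Y) <- benchmarks$variant_id
  Y
}

new_affine_model <- function(W, b, lambda, method, fit_meta,
                             fraction_labels = colnames(W),
                             range = c(0, 14)) {
  structure(
    list(W = W, b = as.numeric(b), lambda = lambda, method = method,
         fit_meta = fit_meta, fraction_labels = fraction_labels,
         range = range),
    class = "affine_model"
  )
}

#' Closed-form ridge solution of the affine sort-seq regression
#'
#' Minimizes `sum_i ||W x_i + b - y_i||^2 + lambda ||W||_F^2` exactly via
#' the normal equations on the bias-augmented design; the bias column is
#' unpenalized. Serves as the analytic counterpart of the gradient-descent
#' fit (the objective is convex, so both share one optimum).
#'
#' @param X Benchmarks-by-K matrix of fraction distributions.
#' @param Y Benchmarks-by-B matrix of measured fluorescence histograms.
#' @param lambda L2 strength on `W`.
#' @return An `affine_model`.
#' @export
ridge_closed_form <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1L)
  K <- ncol(X)
  A <- cbind(X, 1)
  if (lambda > 0) {
    M <- crossprod(A) + lambda * diag(c(rep(1, K), 0))
    theta <- tryCatch(
      solve(M, crossprod(A, Y)),
      error = function(e) {
        stop("normal equations are singular; use lambda > 0 (",
             conditionMessage(e), ")")
      }
    )
  } else {
    # min-norm least-squares solution: the limit zero-initialized gradient
    # descent converges to when the system is underdetermined
    s <- svd(A)
    pos <- s$d > max(s$d) * 1e-12
    if (!any(pos)) stop("design matrix is zero; use lambda > 0")
    theta <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% Y) / s$d[pos])
  }
  W <- t(theta[seq_len(K), , drop = FALSE])
  colnames(W) <- colnames(X)
  loss <- sum((A %*% theta - Y)^2) + lambda * sum(W^2)
  new_affine_model(W, theta[K + 1L, ], lambda, "closed_form",
                   list(final_loss = loss, iterations = 0L,
                        converged = TRUE))
}

#' Gradient-descent fit of the affine sort-seq regression
#'
#' Zero-initialized full-batch gradient descent on the squared-error
#' objective with L2 regularization on the weights (bias unpenalized);
#' stops when the objective decrease over an iteration falls below `tol`
#' or after `max_iters`. Deterministic: no randomness enters the fit.
#'
#' @inheritParams ridge_closed_form
#' @param lr Learning rate (default 1e-2).
#' @param max_iters Iteration cap (default 1e5).
#' @param tol Objective-decrease stopping tolerance (default 1e-10).
#' @return An `affine_model` with `fit_meta` recording learning rate,
#'   iterations, final loss and a convergence flag.
#' @export
fit_affine_gd <- function(X, Y, lambda, lr = 1e-2, max_iters = 1e5L,
                          tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  res <- .affine_gd(X, Y, lambda, lr, as.integer(max_iters), tol)
  W <- res$W
  colnames(W) <- colnames(X)
  new_affine_model(W, res$b, lambda, "gd",
                   list(lr = lr, max_iters = max_iters, tol = tol,
                        final_loss = res$final_loss,
                        iterations = res$iterations,
                        converged = res$converged))
}

#' Fit the affine model by either method
#'
#' @inheritParams fit_affine_gd
#' @param method `"gd"` (the reference procedure) or `"closed_form"` (the
#'   analytic ridge solution of the same convex objective).
#' @param ... Passed to the gradient-descent fitter.
#' @return An `affine_model`.
#' @export
fit_affine <- function(X, Y, lambda, method = c("gd", "closed_form"), ...) {
  method <- match.arg(method)
  switch(method,
         gd = fit_affine_gd(X, Y, lambda, ...),
         closed_form = ridge_closed_form(X, Y, lambda))
}

#' Predict a fluorescence histogram from a fraction distribution
#'
#' Computes `W x + b`, clips negative entries to zero and renormalizes to
#' sum one (the raw affine output is not constrained to be a distribution).
#'
#' @param model An `affine_model`.
#' @param x Fraction-distribution vector (length K), or a variants-by-K
#'   matrix for many variants at once.
#' @return A probability vector of length B, or a variants-by-B matrix.
#' @export
predict_histogram <- function(model, x) {
  stopifnot(inherits(model, "affine_model"))
  if (is.matrix(x)) {
    raw <- x %*% t(model$W)
    raw <- sweep(raw, 2L, model$b, "+")
    raw[raw < 0] <- 0
    s <- rowSums(raw)
    if (any(s < 1e-6)) {
      stop("degenerate prediction (post-clip mass < 1e-6) for variant(s): ",
           paste(head(rownames(x)[s < 1e-6], 5L), collapse = ", "))
    }
    return(raw / s)
  }
  raw <- as.numeric(model$W %*% x + model$b)
  raw[raw < 0] <- 0
  s <- sum(raw)
  if (s < 1e-6) stop("degenerate prediction: post-clip mass < 1e-6")
  raw / s
}

#' Mean log fluorescence intensity of a histogram
#'
#' The expectation of the binned histogram — the activity proxy: high mean
#' log fluorescence means the anti-CRISPR blocks dCas9 effectively and the
#' reporter is expressed.
#'
#' @param h Probability vector over B bins (or a variants-by-B matrix).
#' @param range Axis range the bins cover.
#' @return Scalar (or vector over rows).
#' @export
mean_log_intensity <- function(h, range = c(0, 14)) {
  if (is.matrix(h)) {
    return(as.numeric(h %*% bin_centers(ncol(h), range)))
  }
  sum(h * bin_centers(length(h), range))
}

#' Leave-one-out cross-validation of the affine model
#'
#' For each lambda on the grid and each benchmark, fits the model on the
#' remaining benchmarks, predicts the held-out histogram, and records the
#' mean squared error over bins. Reports the per-mutant MSE table and the
#' lambda minimizing the mean MSE.
#'
#' @param X Benchmarks-by-K fraction-distribution matrix (rows named by
#'   variant id).
#' @param Y Benchmarks-by-B measured histogram matrix (same row order).
#' @param lambda_grid Lambdas to evaluate (default a log grid 1e-4 .. 10).
#' @param method Fitting method (default `"closed_form"`; identical optimum
#'   to `"gd"` within its convergence tolerance).
#' @param ... Passed to the fitter.
#' @return List: `table` (lambda, variant_id, mse), `summary`
#'   (lambda, mean_mse), `best_lambda`.
#' @export
loo_cv <- function(X, Y, lambda_grid = 10^seq(-4, 1, by = 0.5),
                   method = "closed_form", ...) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n == nrow(Y), n >= 2L)
  ids <- rownames(X) %||% as.character(seq_len(n))
  tab <- purrr::map_dfr(lambda_grid, function(lam) {
    mse <- vapply(seq_len(n), function(i) {
      fit <- fit_affine(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                        lam, method = method, ...)
      pred <- predict_histogram(fit, X[i, ])
      mean((pred - Y[i, ])^2)
    }, numeric(1L))
    tibble(lambda = lam, variant_id = ids, mse = mse)
  })
  summary <- tab |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_mse = mean(.data$mse), .groups = "drop")
  list(table = tab, summary = summary,
       best_lambda = summary$lambda[which.min(summary$mean_mse)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict activities for every library variant
#'
#' Fits one affine model per biological replicate (that replicate's
#' benchmark fraction distributions against the shared benchmark
#' histograms), predicts each variant's fluorescence histogram per
#' replicate, and summarizes the per-replicate mean log intensities into an
#' activity (mean over replicates) and a confidence standard deviation
#' (sample sd over replicates; high sd means low confidence).
#'
#' @param fd Fraction-distribution tibble from [fraction_distributions()]
#'   at amino-acid level.
#' @param benchmark_Y Benchmark histogram matrix (rows named by aa variant
#'   id) from [benchmark_histograms()].
#' @param lambda L2 strength (e.g. `loo_cv()$best_lambda`).
#' @param method Fitting method (default `"gd"`).
#' @param range Log-fluorescence axis range.
#' @param ... Passed to the fitter.
#' @return Tibble (class `activity_estimates`): `variant_id`, `position`,
#'   `wt_aa`, `mut_aa`, per-replicate `mean_rep*` columns, `activity`,
#'   `confidence_sd`, `low_coverage`. Carries the per-replicate models as
#'   attribute `models`.
#' @export
predict_all <- function(fd, benchmark_Y, lambda, method = "gd",
                        range = c(0, 14), ...) {
  reps <- sort(unique(fd$replicate))
  bench_ids <- rownames(benchmark_Y)
  missing <- setdiff(bench_ids, fd$variant_id)
  if (length(missing) > 0L) {
    stop("benchmark variant(s) absent from the count data: ",
         paste(missing, collapse = ", "))
  }
  models <- list()
  per_rep <- purrr::map(reps, function(r) {
    Xall <- fd_matrix(fd, r)
    Xb <- Xall[bench_ids, , drop = FALSE]
    fit <- fit_affine(Xb, benchmark_Y, lambda, method = method, ...)
    models[[as.character(r)]] <<- fit
    pred <- predict_histogram(fit, Xall)
    tibble(variant_id = rownames(Xall),
           replicate = r,
           mean_log = mean_log_intensity(pred, range))
  }) |> dplyr::bind_rows()

  key <- fd |>
    dplyr::distinct(.data$variant_id, .data$position, .data$wt_aa,
                    .data$mut_aa, .data$low_coverage)
  wide <- per_rep |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "mean_log",
                       names_prefix = "mean_rep")
  rep_cols <- paste0("mean_rep", reps)
  if (length(reps) < 2L) {
    warning("fewer than 2 replicates: confidence_sd reported as NA")
  }
  out <- key |>
    dplyr::left_join(wide, by = "variant_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      activity = mean(dplyr::c_across(dplyr::all_of(rep_cols))),
      confidence_sd = if (length(reps) < 2L) NA_real_ else
        sd(dplyr::c_across(dplyr::all_of(rep_cols)))
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(!is.na(.data$position), .data$position, .data$mut_aa)
  attr(out, "models") <- models
  class(out) <- c("activity_estimates", class(out))
  out
}

#' @export
print.affine_model <- function(x, ...) {
  cat("<affine_model> ", nrow(x$W), " bins x ", ncol(x$W), " fractions, ",
      "lambda = ", format(x$lambda), ", method = ", x$method, "\n", sep = "")
  cat("  final loss ", format(x$fit_meta$final_loss),
      if (isTRUE(x$fit_meta$converged)) " (converged)" else " (not converged)",
      "\n", sep = "")
  invisible(x)
}

#' Tidy an affine sort-seq model
#'
#' @param x An `affine_model`.
#' @param ... Unused.
#' @return Long tibble of coefficients: `bin`, `term` (a fraction label or
#'   `"(offset)"`), `estimate`.
#' @export
tidy.affine_model <- function(x, ...) {
  B <- nrow(x$W)
  fr <- x$fraction_labels %||% paste0("F", seq_len(ncol(x$W)))
  dplyr::bind_rows(
    tidyr::expand_grid(bin = seq_len(B), term = fr) |>
      dplyr::mutate(estimate = as.numeric(t(x$W))),
    tibble(bin = seq_len(B), term = "(offset)", estimate = x$b)
  ) |>
    dplyr::arrange(.data$bin, .data$term)
}

#' One-row summary of an affine sort-seq model
#'
#' @param x An `affine_model`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `method`, `final_loss`, `iterations`,
#'   `converged`, `n_bins`, `n_fractions`.
#' @export
glance.affine_model <- function(x, ...) {
  tibble(lambda = x$lambda, method = x$method,
         final_loss = x$fit_meta$final_loss,
         iterations = x$fit_meta$iterations %||% NA_integer_,
         converged = isTRUE(x$fit_meta$converged),
         n_bins = nrow(x$W), n_fractions = ncol(x$W))
}
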