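#' FACS gate scheme over the log-fluorescence axis
#'
#' Gates are contiguous half-open intervals covering the working
#' log-fluorescence range (natural-log units, `[0, 14]` by default); the last
#' gate is right-closed. Equal cell numbers are sorted per gate, so the
#' simulator conditions on the gate rather than thinning a common pool.
#'
#' @param edges Increasing breakpoints, first 0 and last 14 by default; K+1
#'   values for K fractions.
#' @param cells_per_fraction Sorted cell count per gate.
#' @return An object of class `gate_scheme`.
#' @export
gate_scheme <- function(edges = c(0, 4, 7, 9, 14), cells_per_fraction = 1e6) {
  edges <- as.numeric(edges)
  if (length(edges) < 3L) stop("need at least 2 fractions (3 edges)")
  if (any(diff(edges) <= 0)) stop("gate edges must be strictly increasing")
  structure(
    list(edges = edges, n_fractions = length(edges) - 1L,
         cells_per_fraction = cells_per_fraction,
         fraction_labels = paste0("F", seq_len(length(edges) - 1L))),
    class = "gate_scheme"
  )
}

#' Scenario configuration for the synthetic experiment generator
#'
#' Defines the latent fluorescence truth model the generator draws from.
#' Every variant's log-fluorescence follows a 1-2 component Gaussian mixture
#' hard-clamped to the working range: active (wild-type-like) variants sit at
#' the high-fluorescence peak of the CRISPRi reporter (the anti-CRISPR blocks
#' dCas9, restoring RFP expression), dead variants at the low no-Acr peak,
#' and intermediates in between. Truths are assigned per amino-acid
#' substitution; synonymous codon variants share the wild-type truth, and
#' nonsense (stop) variants are dead.
#'
#' @param wt_mixture Tibble/data frame with columns `weight`, `mean`, `sd`
#'   for the wild-type fluorescence mixture.
#' @param dead_mixture Same, for dead (no-inhibition) variants.
#' @param tolerance_prob Probability that a missense substitution is
#'   wild-type-like; scalar, or a per-position vector (1-based, length of
#'   the protein) to plant mutation-intolerant segments.
#' @param dead_given_intolerant Probability that a non-tolerated substitution
#'   is fully dead (otherwise intermediate).
#' @param intermediate_range Range of mean log-fluorescence for intermediate
#'   variants.
#' @param intermediate_sd Component sd for intermediate variants.
#' @param tolerant_jitter_sd,dead_jitter_sd Per-variant jitter (sd of a
#'   Gaussian shift applied to all component means) for tolerated and dead
#'   missense substitutions; mutation effects are continuous, so even
#'   "wild-type-like" variants differ slightly. Synonymous variants encode
#'   the same protein and get no jitter.
#' @param bimodal If `TRUE`, the wild-type mixture gets a second,
#'   low-fluorescence component (an AcrIIA5-like bimodal shape).
#' @param bimodal_low_weight Weight of that low component.
#' @param dirichlet_conc Dirichlet concentration for codon-variant library
#'   frequencies (smaller = more uneven library).
#' @param range Working log-fluorescence range.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(wt_mixture = tibble(weight = 1, mean = 10, sd = 0.8),
                         dead_mixture = tibble(weight = 1, mean = 3, sd = 0.8),
                         tolerance_prob = 0.7,
                         dead_given_intolerant = 0.5,
                         intermediate_range = c(4.5, 8),
                         intermediate_sd = 0.8,
                         tolerant_jitter_sd = 0.25,
                         dead_jitter_sd = 0.15,
                         bimodal = FALSE,
                         bimodal_low_weight = 0.3,
                         dirichlet_conc = 5,
                         range = c(0, 14)) {
  wt_mixture <- as_tibble(wt_mixture)
  dead_mixture <- as_tibble(dead_mixture)
  check_mixture <- function(m, what) {
    if (!all(c("weight", "mean", "sd") %in% names(m))) {
      stop(what, " mixture needs columns weight, mean, sd")
    }
    if (abs(sum(m$weight) - 1) > 1e-9) stop(what, " mixture weights must sum to 1")
    if (any(m$sd <= 0)) stop(what, " mixture sds must be positive")
  }
  if (bimodal && nrow(wt_mixture) == 1L) {
    wt_mixture <- tibble(
      weight = c(bimodal_low_weight, 1 - bimodal_low_weight),
      mean = c(dead_mixture$mean[1L] + 0.5, wt_mixture$mean[1L]),
      sd = c(dead_mixture$sd[1L], wt_mixture$sd[1L])
    )
  }
  check_mixture(wt_mixture, "wild-type")
  check_mixture(dead_mixture, "dead")
  if (any(tolerance_prob < 0 | tolerance_prob > 1)) {
    stop("tolerance_prob must lie in [0, 1]")
  }
  structure(
    list(wt_mixture = wt_mixture, dead_mixture = dead_mixture,
         tolerance_prob = tolerance_prob,
         dead_given_intolerant = dead_given_intolerant,
         intermediate_range = intermediate_range,
         intermediate_sd = intermediate_sd,
         tolerant_jitter_sd = tolerant_jitter_sd,
         dead_jitter_sd = dead_jitter_sd,
         dirichlet_conc = dirichlet_conc, range = range),
    class = "sim_scenario"
  )
}

mixture_cols <- function(m) {
  list(w1 = m$weight[1L], mu1 = m$mean[1L], sd1 = m$sd[1L],
       w2 = if (nrow(m) > 1L) m$weight[2L] else NA_real_,
       mu2 = if (nrow(m) > 1L) m$mean[2L] else NA_real_,
       sd2 = if (nrow(m) > 1L) m$sd[2L] else NA_real_)
}

#' Mean log fluorescence of a clamped Gaussian mixture
#'
#' Expectation of the mixture after hard-clamping to `[lo, hi]`: mass below
#' `lo` contributes at `lo`, mass above `hi` at `hi`.
#'
#' @param w,mu,sdev Component weights, means, sds (NAs in trailing
#'   components ignored).
#' @param lo,hi Clamp range.
#' @return Scalar mean.
#' @export
mixture_mean_clamped <- function(w, mu, sdev, lo = 0, hi = 14) {
  keep <- !is.na(w)
  w <- w[keep]; mu <- mu[keep]; sdev <- sdev[keep]
  comp <- function(wi, m, s) {
    a <- (lo - m) / s
    b <- (hi - m) / s
    inner <- m * (pnorm(b) - pnorm(a)) - s * (stats::dnorm(b) - stats::dnorm(a))
    wi * (lo * pnorm(a) + inner + hi * (1 - pnorm(b)))
  }
  sum(mapply(comp, w, mu, sdev))
}

#' Assign fluorescence truths and library frequencies to a library
#'
#' Deterministic given `seed`. Truth mixtures are assigned at the
#' amino-acid level and inherited by codon variants; library frequencies are
#' a Dirichlet draw over codon variants plus wild type.
#'
#' @param design A `library_design`.
#' @param scenario A `sim_scenario`.
#' @param seed Integer seed.
#' @return A tibble (class `variant_truth`) at codon level with columns
#'   `variant_id`, `position`, `wt_aa`, `mut_aa`, `codon`, mixture columns
#'   `w1,mu1,sd1,w2,mu2,sd2`, `library_frequency`, and `truth_mean` (mean of
#'   the clamped mixture). The wild type is the `"WT"` row.
#' @export
sample_truth <- function(design, scenario = sim_scenario(), seed = 1L) {
  stopifnot(inherits(design, "library_design"), inherits(scenario, "sim_scenario"))
  set.seed(seed)
  tol <- scenario$tolerance_prob
  if (length(tol) == 1L) tol <- rep(tol, design$protein_length)
  if (length(tol) != design$protein_length) {
    stop("tolerance_prob must be scalar or one value per residue")
  }

  aa_univ <- variant_universe(design, level = "aa") |>
    dplyr::filter(.data$variant_id != "WT")
  wt_mix <- mixture_cols(scenario$wt_mixture)
  dead_mix <- mixture_cols(scenario$dead_mixture)

  u_class <- runif(nrow(aa_univ))
  u_dead <- runif(nrow(aa_univ))
  int_mean <- runif(nrow(aa_univ), scenario$intermediate_range[1L],
                    scenario$intermediate_range[2L])
  cls <- dplyr::case_when(
    aa_univ$mut_aa == "*" ~ "dead",
    u_class < tol[aa_univ$position] ~ "tolerant",
    u_dead < scenario$dead_given_intolerant ~ "dead",
    TRUE ~ "intermediate"
  )
  jitter <- rnorm(nrow(aa_univ)) *
    dplyr::case_when(cls == "tolerant" ~ scenario$tolerant_jitter_sd,
                     cls == "dead" ~ scenario$dead_jitter_sd,
                     TRUE ~ 0)
  aa_truth <- aa_univ |>
    dplyr::mutate(
      truth_class = cls,
      w1 = dplyr::case_when(cls == "tolerant" ~ wt_mix$w1,
                            cls == "dead" ~ dead_mix$w1, TRUE ~ 1),
      mu1 = dplyr::case_when(cls == "tolerant" ~ wt_mix$mu1 + jitter,
                             cls == "dead" ~ dead_mix$mu1 + jitter,
                             TRUE ~ int_mean),
      sd1 = dplyr::case_when(cls == "tolerant" ~ wt_mix$sd1,
                             cls == "dead" ~ dead_mix$sd1,
                             TRUE ~ scenario$intermediate_sd),
      w2 = dplyr::case_when(cls == "tolerant" ~ wt_mix$w2,
                            cls == "dead" ~ dead_mix$w2, TRUE ~ NA_real_),
      mu2 = dplyr::case_when(cls == "tolerant" ~ wt_mix$mu2 + jitter,
                             cls == "dead" ~ dead_mix$mu2 + jitter,
                             TRUE ~ NA_real_),
      sd2 = dplyr::case_when(cls == "tolerant" ~ wt_mix$sd2,
                             cls == "dead" ~ dead_mix$sd2, TRUE ~ NA_real_)
    )

  codon_univ <- variant_universe(design, level = "codon")
  wt_row <- codon_univ |>
    dplyr::filter(.data$variant_id == "WT") |>
    dplyr::mutate(truth_class = "wt", !!!wt_mix)
  mut <- codon_univ |>
    dplyr::filter(.data$variant_id != "WT")
  syn <- mut |>
    dplyr::filter(.data$mut_aa == .data$wt_aa) |>
    dplyr::mutate(truth_class = "tolerant", !!!wt_mix)
  nonsyn <- mut |>
    dplyr::filter(.data$mut_aa != .data$wt_aa) |>
    dplyr::left_join(
      dplyr::select(aa_truth, "position", "mut_aa", "truth_class",
                    "w1", "mu1", "sd1", "w2", "mu2", "sd2"),
      by = c("position", "mut_aa")
    )
  truth <- dplyr::bind_rows(wt_row, syn, nonsyn) |>
    dplyr::arrange(!is.na(.data$position), .data$position, .data$codon)

  freq <- rgamma(nrow(truth), shape = scenario$dirichlet_conc, rate = 1)
  truth <- truth |>
    dplyr::mutate(
      library_frequency = freq / sum(freq),
      truth_mean = purrr::pmap_dbl(
        list(.data$w1, .data$mu1, .data$sd1, .data$w2, .data$mu2, .data$sd2),
        function(w1, mu1, sd1, w2, mu2, sd2) {
          mixture_mean_clamped(c(w1, w2), c(mu1, mu2), c(sd1, sd2),
                               scenario$range[1L], scenario$range[2L])
        })
    )
  class(truth) <- c("variant_truth", class(truth))
  truth
}

#' Amino-acid-level truth activities
#'
#' Collapses a codon-level truth table to one row per amino-acid variant
#' (synonymous variants merge into WT, which keeps the wild-type truth).
#'
#' @param truth A `variant_truth` table from [sample_truth()].
#' @return Tibble with `variant_id`, `position`, `wt_aa`, `mut_aa`,
#'   `truth_class`, `truth_mean`.
#' @export
truth_aa <- function(truth) {
  truth |>
    dplyr::mutate(
      variant_id = dplyr::if_else(
        is.na(.data$position) | .data$mut_aa == .data$wt_aa, "WT",
        paste0(.data$wt_aa, .data$position, .data$mut_aa)),
      position = dplyr::if_else(.data$variant_id == "WT", NA_integer_,
                                .data$position),
      wt_aa = dplyr::if_else(.data$variant_id == "WT", NA_character_, .data$wt_aa),
      mut_aa = dplyr::if_else(.data$variant_id == "WT", NA_character_, .data$mut_aa)
    ) |>
    dplyr::distinct(.data$variant_id, .data$position, .data$wt_aa,
                    .data$mut_aa, .data$truth_class, .data$w1, .data$mu1,
                    .data$sd1, .data$w2, .data$mu2, .data$sd2,
                    .data$truth_mean)
}

#' Gate probabilities for variant truths
#'
#' For each variant, the probability that a cell's log fluorescence falls in
#' each sorted gate under the clamped Gaussian mixture: CDF differences at
#' the gate edges, with mass outside the working range folded into the edge
#' gates (hard clamping) and the last gate right-closed.
#'
#' @param truth A `variant_truth` table (or any tibble with mixture columns).
#' @param gates A `gate_scheme`.
#' @return Matrix of dimension variants x K, rows named by `variant_id`,
#'   each row summing to 1.
#' @export
gate_probabilities <- function(truth, gates) {
  stopifnot(inherits(gates, "gate_scheme"))
  edges <- gates$edges
  K <- gates$n_fractions
  cdf <- matrix(0, nrow(truth), length(edges))
  for (comp in list(c("w1", "mu1", "sd1"), c("w2", "mu2", "sd2"))) {
    w <- truth[[comp[1L]]]; mu <- truth[[comp[2L]]]; s <- truth[[comp[3L]]]
    ok <- !is.na(w)
    if (!any(ok)) next
    for (j in seq_along(edges)) {
      cdf[ok, j] <- cdf[ok, j] + w[ok] * pnorm(edges[j], mu[ok], s[ok])
    }
  }
  p <- cdf[, -1L, drop = FALSE] - cdf[, -length(edges), drop = FALSE]
  p[, 1L] <- p[, 1L] + cdf[, 1L]
  p[, K] <- p[, K] + (1 - cdf[, length(edges)])
  rownames(p) <- truth$variant_id
  colnames(p) <- gates$fraction_labels
  p
}

#' Simulate FACS sorting of the library
#'
#' For each replicate and each gate, `cells_per_fraction` cells are drawn
#' multinomially from the library conditional on landing in that gate
#' (probability proportional to library frequency times gate probability) —
#' the sorter collects a fixed number of cells per fraction.
#'
#' @param truth A `variant_truth` table.
#' @param gates A `gate_scheme`.
#' @param n_replicates Number of biological replicates.
#' @param seed Integer seed.
#' @return Long tibble: `replicate`, `fraction`, `variant_id`, `position`,
#'   `wt_aa`, `mut_aa`, `codon`, `cells`.
#' @export
simulate_sort <- function(truth, gates, n_replicates = 3L, seed = 1L) {
  set.seed(seed)
  G <- gate_probabilities(truth, gates)
  key <- dplyr::select(truth, "variant_id", "position", "wt_aa", "mut_aa",
                       "codon")
  out <- vector("list", n_replicates * gates$n_fractions)
  i <- 0L
  for (r in seq_len(n_replicates)) {
    for (f in seq_len(gates$n_fractions)) {
      p <- truth$library_frequency * G[, f]
      if (sum(p) <= 0) {
        stop("gate ", gates$fraction_labels[f],
             " has zero total probability across the library")
      }
      cells <- as.integer(rmultinom(1L, gates$cells_per_fraction, p))
      i <- i + 1L
      out[[i]] <- dplyr::mutate(key, replicate = r,
                                fraction = gates$fraction_labels[f],
                                cells = cells)
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("replicate", "fraction", dplyr::everything())
}

#' Simulate amplicon sequencing of sorted fractions
#'
#' Reads per (replicate, fraction) are drawn multinomially from the sorted
#' cell proportions (amplicon sampling noise), or copied verbatim when
#' `resample = FALSE`.
#'
#' @param sorted_counts Output of [simulate_sort()].
#' @param reads_per_fraction Sequencing depth per (replicate, fraction).
#' @param seed Integer seed.
#' @param resample If `FALSE`, counts equal the sorted cell counts (identity
#'   mode; `reads_per_fraction` ignored).
#' @return Codon-level count tibble: `replicate`, `fraction`, `variant_id`,
#'   `position`, `wt_aa`, `mut_aa`, `codon`, `count`.
#' @export
simulate_sequencing <- function(sorted_counts, reads_per_fraction = 2e5,
                                seed = 1L, resample = TRUE) {
  set.seed(seed)
  if (!resample) {
    return(dplyr::rename(sorted_counts, count = "cells"))
  }
  sorted_counts |>
    dplyr::group_by(.data$replicate, .data$fraction) |>
    dplyr::group_modify(function(df, key) {
      df$count <- if (reads_per_fraction == 0 || sum(df$cells) == 0) {
        0L
      } else {
        as.integer(rmultinom(1L, reads_per_fraction, df$cells))
      }
      df$cells <- NULL
      df
    }) |>
    dplyr::ungroup()
}

#' Simulate individual flow-cytometry measurements for benchmark mutants
#'
#' Draws per-event log-fluorescence values from each benchmark's truth
#' mixture, hard-clamped to the working range — the synthetic analogue of
#' cloning a mutant individually and recording its reporter histogram.
#'
#' @param truth A `variant_truth` table (codon or aa level; ids matched on
#'   `variant_id`).
#' @param benchmark_ids Variant ids to measure.
#' @param events_per_mutant Number of flow events per benchmark.
#' @param seed Integer seed.
#' @param range Clamp range.
#' @return Tibble `variant_id`, `log_fluorescence` (class `benchmark_events`).
#' @export
simulate_benchmark_flow <- function(truth, benchmark_ids,
                                    events_per_mutant = 2e4, seed = 1L,
                                    range = c(0, 14)) {
  set.seed(seed)
  missing <- setdiff(benchmark_ids, truth$variant_id)
  if (length(missing) > 0L) {
    stop("benchmark variant(s) not in the truth table: ",
         paste(missing, collapse = ", "))
  }
  rows <- truth[match(benchmark_ids, truth$variant_id), ]
  purrr::map2_dfr(seq_len(nrow(rows)), benchmark_ids, function(i, id) {
    w <- c(rows$w1[i], rows$w2[i]); mu <- c(rows$mu1[i], rows$mu2[i])
    s <- c(rows$sd1[i], rows$sd2[i])
    keep <- !is.na(w)
    comp <- sample.int(sum(keep), events_per_mutant, replace = TRUE,
                       prob = w[keep])
    x <- rnorm(events_per_mutant, mu[keep][comp], s[keep][comp])
    tibble(variant_id = id,
           log_fluorescence = pmin(pmax(x, range[1L]), range[2L]))
  })
}

#' Pick benchmark mutants spanning the activity range
#'
#' Orders amino-acid variants by truth mean log fluorescence and takes
#' evenly spaced ranks, mirroring how benchmark mutants are chosen to cover
#' the diversity of observed fraction distributions.
#'
#' @param truth A `variant_truth` table.
#' @param n Number of benchmarks (default 16).
#' @return Character vector of aa-level variant ids.
#' @export
select_benchmarks <- function(truth, n = 16L) {
  aa <- truth_aa(truth) |>
    dplyr::filter(.data$variant_id != "WT", .data$mut_aa != "*") |>
    dplyr::arrange(.data$truth_mean)
  if (nrow(aa) < n) {
    stop("requested ", n, " benchmarks from a universe of ", nrow(aa),
         " mutants")
  }
  idx <- unique(round(seq(1L, nrow(aa), length.out = n)))
  k <- 0L
  while (length(idx) < n) {  # fill rank collisions with neighbours
    k <- k + 1L
    idx <- unique(c(idx, pmin(nrow(aa), idx + k)))
  }
  aa$variant_id[sort(idx)[seq_len(n)]]
}

#' Synthetic per-residue annotation table
#'
#' Emulates the structural annotations consumed by the landscape module:
#' core/surface burial, loop/structured secondary structure, Cas9-contact
#' sites, IDR membership, and a ConSurf-style conservation score constructed
#' to correlate negatively with per-residue mutational tolerance (conserved
#' residues tolerate fewer substitutions) plus noise.
#'
#' @param design A `library_design`.
#' @param truth A `variant_truth` table (used for the planted
#'   conservation-tolerance relation).
#' @param seed Integer seed.
#' @param noise_sd Noise on the conservation score.
#' @return Tibble: `position`, `burial`, `secondary`, `cas9_contact`, `idr`,
#'   `conservation_score`.
#' @export
synth_annotation <- function(design, truth, seed = 1L, noise_sd = 1) {
  set.seed(seed)
  pos_mean <- truth_aa(truth) |>
    dplyr::filter(.data$variant_id != "WT", .data$mut_aa != "*") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(m = mean(.data$truth_mean), .groups = "drop")
  L <- design$protein_length
  m <- rep(NA_real_, L)
  m[pos_mean$position] <- pos_mean$m
  m[is.na(m)] <- mean(pos_mean$m)
  z <- as.numeric(scale(m))
  tibble(
    position = seq_len(L),
    burial = sample(c("core", "surface"), L, replace = TRUE, prob = c(0.3, 0.7)),
    secondary = sample(c("loop", "structured"), L, replace = TRUE),
    cas9_contact = sample(c("yes", "no"), L, replace = TRUE, prob = c(0.2, 0.8)),
    idr = sample(c("yes", "no"), L, replace = TRUE, prob = c(0.15, 0.85)),
    conservation_score = -z + rnorm(L, sd = noise_sd)
  )
}

#' Generate a complete synthetic Flow-seq experiment
#'
#' One call producing everything downstream stages consume: a truth table,
#' sorted-cell and read-count tables for each replicate and fraction,
#' benchmark flow-cytometry events, and a per-residue annotation table.
#' Deterministic given `seed` (stage seeds are derived from it).
#'
#' @param design A `library_design`.
#' @param scenario A `sim_scenario`.
#' @param gates A `gate_scheme`.
#' @param n_replicates Biological replicates (default 3).
#' @param reads_per_fraction Sequencing depth per (replicate, fraction).
#' @param n_benchmarks Number of benchmark mutants (default 16).
#' @param events_per_benchmark Flow events per benchmark.
#' @param seed Integer master seed.
#' @return List with elements `design`, `scenario`, `gates`, `truth`,
#'   `sorted`, `counts` (codon level), `benchmark_ids`, `benchmark_events`,
#'   `annotation`, `seed`.
#' @export
simulate_experiment <- function(design,
                                scenario = sim_scenario(),
                                gates = gate_scheme(cells_per_fraction = 5e4),
                                n_replicates = 3L,
                                reads_per_fraction = 2e5,
                                n_benchmarks = 16L,
                                events_per_benchmark = 2e4,
                                seed = 1L) {
  seeds <- (seed * 7L + c(11L, 23L, 37L, 53L)) %% 2147483647L
  truth <- sample_truth(design, scenario, seed = seeds[1L])
  sorted <- simulate_sort(truth, gates, n_replicates, seed = seeds[2L])
  counts <- simulate_sequencing(sorted, reads_per_fraction, seed = seeds[3L])
  benchmark_ids <- select_benchmarks(truth, n_benchmarks)
  bench <- simulate_benchmark_flow(truth_aa(truth), benchmark_ids,
                                   events_per_benchmark, seed = seeds[4L])
  ann <- synth_annotation(design, truth, seed = seeds[1L])
  list(design = design, scenario = scenario, gates = gates, truth = truth,
       sorted = sorted, counts = counts, benchmark_ids = benchmark_ids,
       benchmark_events = bench, annotation = ann, seed = seed)
}
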