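# Small programmatic fixtures shared across test files.

# Random in-frame ORF built from NNB codons (so it never contains an
# internal stop: the only NNB stop, TAG, is excluded from the draw).
toy_orf <- function(n_codons = 9L, seed = 1L, terminal_stop = TRUE) {
  set.seed(seed)
  body <- sample(setdiff(nnb_codons(), "TAG"), n_codons - 1L -
                   as.integer(terminal_stop), replace = TRUE)
  paste(c("ATG", body, if (terminal_stop) "TAA"), collapse = "")
}

# Rows drawn from a flat Dirichlet: valid fraction distributions/histograms.
rdirichlet_rows <- function(n, k) {
  g <- matrix(rgamma(n * k, shape = 1), nrow = n)
  g / rowSums(g)
}

# One-component truth row in the column layout sample_truth() emits.
truth_row <- function(id, mean, sd, w2 = NA_real_, mu2 = NA_real_,
                      sd2 = NA_real_, freq = 1) {
  tibble::tibble(variant_id = id, position = NA_integer_,
                 wt_aa = NA_character_, mut_aa = NA_character_,
                 codon = NA_character_,
                 w1 = if (is.na(w2)) 1 else 1 - w2, mu1 = mean, sd1 = sd,
                 w2 = w2, mu2 = mu2, sd2 = sd2, library_frequency = freq)
}

# Codon-level count table over a design's universe with a given default.
counts_template <- function(design, replicate = 1L, fraction = "F1",
                            count = 0L) {
  dplyr::mutate(variant_universe(design, "codon"),
                replicate = replicate, fraction = fraction, count = count)
}
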