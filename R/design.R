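#' The 48 NNB codons
#'
#' NNB degenerate codons have any base at positions 1-2 and C, G or T at
#' position 3. The set encodes all 20 amino acids and a single stop codon
#' (TAG), which is why NNB saturation libraries are a compact way to cover
#' every substitution while keeping only one stop per position.
#'
#' @return Character vector of the 48 NNB codons.
#' @export
nnb_codons <- function() {
  bases <- c("A", "C", "G", "T")
  third <- c("C", "G", "T")
  grid <- expand.grid(b3 = third, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$b1, grid$b2, grid$b3))
}

#' Translate a vector of DNA codons
#'
#' Uses the standard genetic code; stop codons translate to `"*"`.
#'
#' @param codons Character vector of length-3 DNA codons.
#' @return Character vector of one-letter amino acids (`"*"` for stop).
#' @export
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  bad <- !codons %in% names(code)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  }
  unname(code[codons])
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGT).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

split_codons <- function(orf) {
  n <- nchar(orf) / 3L
  substring(orf, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Design a single-codon NNB saturation library
#'
#' Given an in-frame wild-type ORF, enumerates the variant universe of a
#' single-codon NNB saturation library: the wild type plus, at every mutable
#' position, each of the 48 NNB codons that differs from the wild-type codon.
#' A terminal stop codon, when present, is kept as part of the ORF but is not
#' mutated; the start codon is excluded from mutagenesis by default because
#' mutating it abolishes expression trivially.
#'
#' @param wt_orf In-frame DNA string (ACGT only, length divisible by 3, no
#'   internal stop codon; a single terminal stop codon is allowed).
#' @param mutate_start Logical; include position 1 in the mutagenesis
#'   (default `FALSE`).
#' @return An object of class `library_design`: a list with `orf_codons`,
#'   `wt_aa` (translated protein, excluding a terminal stop),
#'   `protein_length`, `mutable_positions`, `nnb_codons`, `aa_alphabet`
#'   (20 amino acids plus `"*"`), and `design_hash`.
#' @export
design_library <- function(wt_orf, mutate_start = FALSE) {
  wt_orf <- toupper(wt_orf)
  if (grepl("[^ACGT]", wt_orf)) {
    stop("wild-type ORF contains non-ACGT characters")
  }
  if (nchar(wt_orf) %% 3L != 0L) {
    stop("wild-type ORF length must be divisible by 3")
  }
  codons <- split_codons(wt_orf)
  aa <- translate_codons(codons)
  n <- length(codons)
  has_stop <- aa[n] == "*"
  coding <- if (has_stop) seq_len(n - 1L) else seq_len(n)
  if (any(aa[coding] == "*")) {
    stop("wild-type ORF contains an internal stop codon")
  }
  orf_codons <- codons[coding]
  wt_aa <- aa[coding]
  first <- if (mutate_start) 1L else 2L
  if (length(orf_codons) < first) stop("ORF too short to mutagenize")
  design <- structure(
    list(
      orf_codons = orf_codons,
      stop_codon = if (has_stop) codons[n] else NULL,
      wt_aa = wt_aa,
      protein_length = length(wt_aa),
      mutable_positions = seq(first, length(orf_codons)),
      nnb_codons = nnb_codons(),
      aa_alphabet = c(sort(unique(unname(Biostrings::GENETIC_CODE))[
        unique(unname(Biostrings::GENETIC_CODE)) != "*"]), "*")
    ),
    class = "library_design"
  )
  design$design_hash <- sum(utf8ToInt(paste(codons, collapse = "")) *
                              seq_len(3L * n)) %% 2147483647L
  design
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  cat("  protein length:", x$protein_length, "residues\n")
  cat("  mutable positions:", min(x$mutable_positions), "-",
      max(x$mutable_positions), "\n")
  cat("  codon-level mutant universe:",
      nrow(variant_universe(x, level = "codon")) - 1L, "variants + WT\n")
  invisible(x)
}

#' Enumerate the variant universe of a design
#'
#' At codon level, one row per admissible (position, mutant codon) pair plus
#' the wild type. At amino-acid level, one row per (position, mutant amino
#' acid) pair reachable through NNB codons (all 20 amino acids and the stop
#' symbol `"*"` are reachable at every position), plus the wild type;
#' synonymous codon changes collapse into the WT class.
#'
#' @param design A `library_design`.
#' @param level `"codon"` or `"aa"`.
#' @return A tibble with columns `variant_id`, `position`, `wt_aa`,
#'   `mut_aa` and, at codon level, `codon`. The wild type has
#'   `variant_id = "WT"` and `NA` position.
#' @export
variant_universe <- function(design, level = c("codon", "aa")) {
  level <- match.arg(level)
  stopifnot(inherits(design, "library_design"))
  pos <- design$mutable_positions
  nnb <- design$nnb_codons
  wt_row <- tibble(variant_id = "WT", position = NA_integer_,
                   wt_aa = NA_character_, mut_aa = NA_character_)
  if (level == "codon") {
    tab <- tidyr::expand_grid(position = pos, codon = nnb) |>
      dplyr::mutate(
        wt_codon = design$orf_codons[.data$position],
        wt_aa = design$wt_aa[.data$position],
        mut_aa = translate_codons(.data$codon)
      ) |>
      dplyr::filter(.data$codon != .data$wt_codon) |>
      dplyr::mutate(variant_id = paste0(.data$wt_aa, .data$position,
                                        .data$mut_aa, ":", .data$codon)) |>
      dplyr::select("variant_id", "position", "wt_aa", "mut_aa", "codon")
    dplyr::bind_rows(dplyr::mutate(wt_row, codon = NA_character_), tab)
  } else {
    tab <- tidyr::expand_grid(position = pos,
                              mut_aa = design$aa_alphabet) |>
      dplyr::mutate(wt_aa = design$wt_aa[.data$position]) |>
      dplyr::filter(.data$mut_aa != .data$wt_aa) |>
      dplyr::mutate(variant_id = paste0(.data$wt_aa, .data$position,
                                        .data$mut_aa)) |>
      dplyr::select("variant_id", "position", "wt_aa", "mut_aa")
    dplyr::bind_rows(wt_row, tab)
  }
}

#' Build the mutant ORF sequence for a codon-level variant
#'
#' @param design A `library_design`.
#' @param position Residue position (1-based), or `NA` for wild type.
#' @param codon Mutant codon, or `NA` for wild type.
#' @return DNA string of the full ORF (including a terminal stop codon when
#'   the design has one).
#' @export
variant_orf <- function(design, position = NA, codon = NA) {
  codons <- design$orf_codons
  if (!is.na(position)) codons[position] <- codon
  paste(c(codons, design$stop_codon), collapse = "")
}

#' Read a wild-type ORF from a FASTA file
#'
#' @param path FASTA file with a single in-frame ORF record.
#' @param ... Passed to [design_library()].
#' @return A `library_design`.
#' @export
read_orf_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record, got ",
                               length(seqs))
  design_library(as.character(seqs[[1L]]), ...)
}
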