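#' Emit paired-end amplicon FASTQ files for a simulated count table
#'
#' Writes one R1/R2 FASTQ pair per (replicate, fraction) plus a manifest TSV.
#' R1 is the first `read_length` bases of each variant ORF; R2 is the
#' reverse complement of the last `read_length` bases (sequencer
#' orientation), so each pair covers the full ORF with an overlap of
#' `2 * read_length - ORF length` bases. Base qualities are constant;
#' substitution errors are injected independently per base at `error_rate`
#' (no indels — amplicon reads of fixed design).
#'
#' @param counts Codon-level count table from [simulate_sequencing()].
#' @param design A `library_design`.
#' @param dir Output directory (created if missing).
#' @param read_length Read length in bases.
#' @param overlap_length Minimum overlap the pair must achieve; it is an
#'   error if `2 * read_length - overlap_length` is less than the ORF length.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed (used only when `error_rate > 0`).
#' @param quality_char Constant Phred quality character (default `"I"`, Q40).
#' @return The manifest tibble (`replicate`, `fraction`, `r1_path`,
#'   `r2_path`), invisibly also written to `file.path(dir, "manifest.tsv")`.
#' @export
emit_fastq <- function(counts, design, dir, read_length, overlap_length,
                       error_rate = 0, seed = 1L, quality_char = "I") {
  stopifnot(inherits(design, "library_design"))
  orf_len <- 3L * length(design$orf_codons) +
    if (is.null(design$stop_codon)) 0L else 3L
  if (read_length > orf_len) {
    stop("read_length exceeds the ORF length (", orf_len, ")")
  }
  if (2L * read_length - overlap_length < orf_len) {
    stop("read_length ", read_length, " cannot cover the ", orf_len,
         "-base ORF with an overlap of ", overlap_length)
  }
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  key <- counts |>
    dplyr::distinct(.data$variant_id, .data$position, .data$codon) |>
    dplyr::mutate(orf = purrr::map2_chr(.data$position, .data$codon,
                                        ~ variant_orf(design, .x, .y)))
  r1_of <- substr(key$orf, 1L, read_length)
  r2_of <- revcomp(substr(key$orf, orf_len - read_length + 1L, orf_len))
  names(r1_of) <- key$variant_id
  names(r2_of) <- key$variant_id

  qual <- strrep(quality_char, read_length)
  groups <- counts |>
    dplyr::group_by(.data$replicate, .data$fraction) |>
    dplyr::group_split()
  manifest <- purrr::map_dfr(groups, function(df) {
    rep_i <- df$replicate[1L]
    frac <- df$fraction[1L]
    stem <- sprintf("rep%s_%s", rep_i, frac)
    r1_path <- file.path(dir, paste0(stem, "_R1.fastq"))
    r2_path <- file.path(dir, paste0(stem, "_R2.fastq"))
    df <- dplyr::filter(df, .data$count > 0L)
    r1 <- rep(unname(r1_of[df$variant_id]), df$count)
    r2 <- rep(unname(r2_of[df$variant_id]), df$count)
    if (error_rate > 0 && length(r1) > 0L) {
      r1 <- inject_substitutions(r1, error_rate)
      r2 <- inject_substitutions(r2, error_rate)
    }
    ids <- sprintf("%s:%06d", stem, seq_along(r1))
    write_fastq(r1_path, ids, r1, qual)
    write_fastq(r2_path, ids, r2, qual)
    tibble(replicate = rep_i, fraction = frac,
           r1_path = r1_path, r2_path = r2_path)
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

inject_substitutions <- function(seqs, error_rate) {
  len <- nchar(seqs[1L])
  n_err <- stats::rbinom(length(seqs), len, error_rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(len, n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

write_fastq <- function(path, ids, seqs, qual) {
  if (length(seqs) == 0L) {
    x <- Biostrings::DNAStringSet()
    Biostrings::writeXStringSet(x, path, format = "fastq")
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(qual, length(seqs)))
  )
  invisible(path)
}

read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("R1/R2 record counts differ: ", r1_path, " vs ", r2_path)
  }
  tibble(
    r1_seq = as.character(r1),
    r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
    r2_seq = as.character(r2),
    r2_qual = as.character(S4Vectors::mcols(r2)$qualities)
  )
}
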