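#' Merge a paired-end amplicon read pair by its overlap
#'
#' R2 is given in sequencer orientation and is reverse-complemented first.
#' Candidate overlap lengths from `min_overlap` up to the shorter read are
#' scored as matches minus mismatches; a candidate is admissible when its
#' mismatch fraction is at most `max_mismatch_frac`. The best-scoring
#' admissible overlap wins; in the overlap the base with the higher Phred
#' quality is kept, ties going to R1.
#'
#' @param r1_seq,r1_qual R1 sequence and Phred-33 quality string.
#' @param r2_seq,r2_qual R2 sequence and quality string (sequencer
#'   orientation).
#' @param min_overlap Minimum admissible overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return A list with `status` (`"merged"` or `"reject"`), `sequence`,
#'   `n_overlap_mismatches`, and `reject_reason` (`"NO_OVERLAP"` or
#'   `"AMBIGUOUS_OVERLAP"`).
#' @export
merge_pairs <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                        min_overlap = 10L, max_mismatch_frac = 0.1) {
  rc2 <- revcomp(r2_seq)
  q2r <- paste(rev(strsplit(r2_qual, "", fixed = TRUE)[[1L]]), collapse = "")
  c1 <- strsplit(r1_seq, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(rc2, "", fixed = TRUE)[[1L]]
  p1 <- utf8ToInt(r1_qual) - 33L
  p2 <- utf8ToInt(q2r) - 33L
  len1 <- length(c1); len2 <- length(c2)
  max_o <- min(len1, len2)
  if (max_o < min_overlap) {
    return(list(status = "reject", sequence = NA_character_,
                n_overlap_mismatches = NA_integer_,
                reject_reason = "NO_OVERLAP"))
  }
  os <- seq.int(min_overlap, max_o)
  mism <- vapply(os, function(o) {
    sum(c1[(len1 - o + 1L):len1] != c2[seq_len(o)])
  }, integer(1L))
  admissible <- mism / os <= max_mismatch_frac
  if (!any(admissible)) {
    return(list(status = "reject", sequence = NA_character_,
                n_overlap_mismatches = NA_integer_,
                reject_reason = "NO_OVERLAP"))
  }
  score <- ifelse(admissible, (os - mism) - mism, -Inf)
  best <- max(score)
  if (sum(score == best) > 1L) {
    return(list(status = "reject", sequence = NA_character_,
                n_overlap_mismatches = NA_integer_,
                reject_reason = "AMBIGUOUS_OVERLAP"))
  }
  o <- os[which.max(score)]
  i1 <- (len1 - o + 1L):len1
  i2 <- seq_len(o)
  cons <- ifelse(p2[i2] > p1[i1], c2[i2], c1[i1])
  merged <- paste(c(c1[seq_len(len1 - o)], cons,
                    if (o < len2) c2[(o + 1L):len2]), collapse = "")
  list(status = "merged", sequence = merged,
       n_overlap_mismatches = mism[match(o, os)], reject_reason = NA_character_)
}

#' Classify a merged read against the library design
#'
#' Codon-by-codon comparison to the wild-type ORF in its fixed reading frame
#' (no realignment). Zero differing codons is wild type; exactly one
#' differing codon at a mutable position whose mutant codon lies in the NNB
#' set is a single-codon variant; everything else — two or more differing
#' codons, a mutant codon outside NNB, or a change at a non-mutable position
#' (start or stop codon) — is a sequence not contained in the original
#' library and is rejected.
#'
#' @param merged Merged read sequence spanning the full ORF.
#' @param design A `library_design`.
#' @return A list with `class` (`"WT"`, `"SINGLE_CODON"`, `"REJECT"`),
#'   `position`, `codon`, `reject_reason` (`"MULTI_CODON"`, `"NOT_NNB"`,
#'   `"NOT_MUTABLE"`).
#' @export
classify_read <- function(merged, design) {
  full <- c(design$orf_codons, design$stop_codon)
  if (nchar(merged) != 3L * length(full)) {
    stop("merged read length ", nchar(merged),
         " does not match the ORF length ", 3L * length(full))
  }
  codons <- split_codons(merged)
  diff <- which(codons != full)
  if (length(diff) == 0L) {
    return(list(class = "WT", position = NA_integer_, codon = NA_character_,
                reject_reason = NA_character_))
  }
  if (length(diff) > 1L) {
    return(list(class = "REJECT", position = NA_integer_,
                codon = NA_character_, reject_reason = "MULTI_CODON"))
  }
  pos <- diff
  if (!pos %in% design$mutable_positions) {
    return(list(class = "REJECT", position = NA_integer_,
                codon = NA_character_, reject_reason = "NOT_MUTABLE"))
  }
  if (!codons[pos] %in% design$nnb_codons) {
    return(list(class = "REJECT", position = NA_integer_,
                codon = NA_character_, reject_reason = "NOT_NNB"))
  }
  list(class = "SINGLE_CODON", position = pos, codon = codons[pos],
       reject_reason = NA_character_)
}

#' Count single-codon variants from paired FASTQ files
#'
#' Streams each (replicate, fraction) file pair from the manifest, merges
#' pairs by overlap, classifies merged reads against the design, and
#' increments counts for wild-type and single-codon calls. Identical
#' (sequence, quality) pairs are merged and classified once and weighted by
#' their multiplicity, which is exact because both steps are deterministic
#' per pair.
#'
#' @param manifest Tibble with `replicate`, `fraction`, `r1_path`,
#'   `r2_path`, or the path of a manifest TSV.
#' @param design A `library_design`.
#' @param min_overlap,max_mismatch_frac Merge parameters, see
#'   [merge_pairs()].
#' @return Codon-level count tibble covering the full variant universe
#'   (zero-filled): `replicate`, `fraction`, `variant_id`, `position`,
#'   `wt_aa`, `mut_aa`, `codon`, `count`; with a `qc` attribute tallying
#'   per-file totals, retained reads and reject reasons (see
#'   [count_qc()]).
#' @export
count_variants <- function(manifest, design, min_overlap = 10L,
                           max_mismatch_frac = 0.1) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  missing <- manifest$r1_path[!file.exists(manifest$r1_path)]
  missing <- c(missing, manifest$r2_path[!file.exists(manifest$r2_path)])
  if (length(missing) > 0L) {
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  universe <- variant_universe(design, level = "codon")

  per_file <- purrr::pmap(manifest, function(replicate, fraction, r1_path,
                                             r2_path, ...) {
    pairs <- read_fastq_pairs(r1_path, r2_path)
    n_pairs <- nrow(pairs)
    if (n_pairs == 0L) {
      return(list(
        counts = dplyr::mutate(universe, replicate = replicate,
                               fraction = fraction, count = 0L),
        qc = tibble(replicate = replicate, fraction = fraction,
                    n_pairs = 0L, n_retained = 0L, NO_OVERLAP = 0L,
                    AMBIGUOUS_OVERLAP = 0L, MULTI_CODON = 0L, NOT_NNB = 0L,
                    NOT_MUTABLE = 0L)
      ))
    }
    grp <- pairs |>
      dplyr::count(.data$r1_seq, .data$r1_qual, .data$r2_seq, .data$r2_qual,
                   name = "mult")
    call <- purrr::pmap(grp, function(r1_seq, r1_qual, r2_seq, r2_qual, mult) {
      m <- merge_pairs(r1_seq, r1_qual, r2_seq, r2_qual,
                       min_overlap, max_mismatch_frac)
      if (m$status == "reject") {
        return(list(key = NA_character_, reason = m$reject_reason))
      }
      full_len <- 3L * (length(design$orf_codons) +
                          as.integer(!is.null(design$stop_codon)))
      if (nchar(m$sequence) != full_len) {
        return(list(key = NA_character_, reason = "MULTI_CODON"))
      }
      cl <- classify_read(m$sequence, design)
      if (cl$class == "REJECT") {
        return(list(key = NA_character_, reason = cl$reject_reason))
      }
      key <- if (cl$class == "WT") "WT" else paste0(cl$position, ":", cl$codon)
      list(key = key, reason = NA_character_)
    })
    keys <- purrr::map_chr(call, "key")
    reasons <- purrr::map_chr(call, "reason")
    tallies <- tapply(grp$mult, factor(
      ifelse(is.na(keys), reasons, "retained"),
      levels = c("retained", "NO_OVERLAP", "AMBIGUOUS_OVERLAP",
                 "MULTI_CODON", "NOT_NNB", "NOT_MUTABLE")), sum,
      default = 0L)
    cnt <- tibble(key = keys[!is.na(keys)], mult = grp$mult[!is.na(keys)]) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(count = sum(.data$mult), .groups = "drop")
    counts <- universe |>
      dplyr::mutate(
        key = dplyr::if_else(.data$variant_id == "WT", "WT",
                             paste0(.data$position, ":", .data$codon))
      ) |>
      dplyr::left_join(cnt, by = "key") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                    replicate = replicate, fraction = fraction) |>
      dplyr::select(-"key")
    qc <- tibble(replicate = replicate, fraction = fraction,
                 n_pairs = n_pairs, n_retained = as.integer(tallies[["retained"]]),
                 NO_OVERLAP = as.integer(tallies[["NO_OVERLAP"]]),
                 AMBIGUOUS_OVERLAP = as.integer(tallies[["AMBIGUOUS_OVERLAP"]]),
                 MULTI_CODON = as.integer(tallies[["MULTI_CODON"]]),
                 NOT_NNB = as.integer(tallies[["NOT_NNB"]]),
                 NOT_MUTABLE = as.integer(tallies[["NOT_MUTABLE"]]))
    list(counts = counts, qc = qc)
  })

  out <- purrr::map_dfr(per_file, "counts") |>
    dplyr::select("replicate", "fraction", "variant_id", "position",
                  "wt_aa", "mut_aa", "codon", "count")
  attr(out, "qc") <- purrr::map_dfr(per_file, "qc") |>
    dplyr::mutate(retained_fraction = ifelse(.data$n_pairs > 0L,
                                             .data$n_retained / .data$n_pairs,
                                             NA_real_))
  out
}

#' QC report of a counted table
#'
#' @param counts Output of [count_variants()].
#' @return The per-file QC tibble (pairs, retained reads and fraction,
#'   reject-reason tallies).
#' @export
count_qc <- function(counts) {
  qc <- attr(counts, "qc")
  if (is.null(qc)) stop("no QC attribute; was this table produced by count_variants()?")
  qc
}

#' Aggregate a codon-level count table to amino-acid level
#'
#' Codon variants translating to the same (position, mutant amino acid) are
#' summed; synonymous variants of the wild-type amino acid merge into the WT
#' class; stop codons aggregate to the `"*"` column per position. Total
#' retained reads are conserved.
#'
#' @param codon_table Codon-level count tibble.
#' @return Amino-acid-level count tibble: `replicate`, `fraction`,
#'   `variant_id`, `position`, `wt_aa`, `mut_aa`, `count`.
#' @export
aggregate_to_aa <- function(codon_table) {
  codon_table |>
    dplyr::mutate(
      is_wt = is.na(.data$position) | .data$mut_aa == .data$wt_aa,
      variant_id = dplyr::if_else(.data$is_wt, "WT",
                                  paste0(.data$wt_aa, .data$position,
                                         .data$mut_aa)),
      position = dplyr::if_else(.data$is_wt, NA_integer_, .data$position),
      wt_aa = dplyr::if_else(.data$is_wt, NA_character_, .data$wt_aa),
      mut_aa = dplyr::if_else(.data$is_wt, NA_character_, .data$mut_aa)
    ) |>
    dplyr::group_by(.data$replicate, .data$fraction, .data$variant_id,
                    .data$position, .data$wt_aa, .data$mut_aa) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$replicate, .data$fraction,
                   !is.na(.data$position), .data$position, .data$mut_aa)
}

#' Fraction of the mutant universe robustly detected
#'
#' Sums reads per non-WT variant over all fractions and replicates and
#' reports the percentage with strictly more than `min_reads` reads, the
#' library-coverage summary.
#'
#' @param table Count tibble (codon or aa level).
#' @param min_reads Detection threshold (strict `>`; default 10).
#' @param include_stop Count stop (`"*"`) variants in the universe
#'   (default `TRUE`).
#' @return A list with `percent_detected`, `n_detected`, `n_universe`, and
#'   `totals` (per-variant total-read tibble).
#' @export
detected_fraction <- function(table, min_reads = 10L, include_stop = TRUE) {
  if (min_reads < 0L) stop("min_reads must be non-negative")
  totals <- table |>
    dplyr::filter(.data$variant_id != "WT") |>
    {\(d) if (include_stop) d else dplyr::filter(d, .data$mut_aa != "*")}() |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("variant_id", "position", "wt_aa", "mut_aa", "codon")))) |>
    dplyr::summarise(total_reads = sum(.data$count), .groups = "drop")
  n_det <- sum(totals$total_reads > min_reads)
  list(percent_detected = 100 * n_det / nrow(totals),
       n_detected = n_det, n_universe = nrow(totals), totals = totals)
}
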