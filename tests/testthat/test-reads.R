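test_that("emit_fastq writes the designed read geometry", {
  d <- design_library("ATGGCTGAA")
  counts <- counts_template(d) |>
    dplyr::mutate(count = ifelse(variant_id == "WT", 1L, 0L))
  dir <- withr::local_tempdir()
  manifest <- emit_fastq(counts, d, dir, read_length = 6L,
                         overlap_length = 3L)
  r1 <- readLines(manifest$r1_path)
  r2 <- readLines(manifest$r2_path)
  expect_identical(r1[2L], "ATGGCT")
  expect_identical(r2[2L], revcomp("GCTGAA"))
  expect_identical(nchar(r1[4L]), 6L)

  expect_error(emit_fastq(counts, d, dir, read_length = 5L,
                          overlap_length = 3L), "cannot cover")
  expect_error(emit_fastq(counts, d, dir, read_length = 12L,
                          overlap_length = 3L), "exceeds")
})

test_that("empty count tables give empty but countable FASTQ files", {
  d <- design_library("ATGGCTGAA")
  counts <- counts_template(d)
  dir <- withr::local_tempdir()
  manifest <- emit_fastq(counts, d, dir, read_length = 6L,
                         overlap_length = 3L)
  expect_true(file.exists(manifest$r1_path))
  tab <- count_variants(manifest, d, min_overlap = 3L)
  expect_true(all(tab$count == 0L))
  qc <- count_qc(tab)
  expect_identical(qc$n_pairs, 0L)
  expect_true(is.na(qc$retained_fraction))
})

test_that("merge_pairs reconstructs the amplicon from its overlap", {
  q6 <- strrep("I", 6L)
  m <- merge_pairs("ATGGCT", q6, revcomp("GCTGAA"), q6, min_overlap = 3L)
  expect_identical(m$status, "merged")
  expect_identical(m$sequence, "ATGGCTGAA")
  expect_identical(m$n_overlap_mismatches, 0L)

  # full-overlap identity
  q9 <- strrep("I", 9L)
  full <- merge_pairs("ATGGCTGAA", q9, revcomp("ATGGCTGAA"), q9,
                      min_overlap = 3L)
  expect_identical(full$sequence, "ATGGCTGAA")

  # disjoint reads below the overlap floor
  no <- merge_pairs("AAAAAA", q6, "CCCCCC", q6, min_overlap = 10L)
  expect_identical(no$status, "reject")
  expect_identical(no$reject_reason, "NO_OVERLAP")
})

test_that("overlap consensus is Phred-weighted with ties to R1", {
  # R1 carries a low-quality error in the 3-base overlap
  r1 <- "ATGGAT"          # true prefix ATGGCT, error at position 5
  r2 <- revcomp("GCTGAA")
  q_r2 <- strrep("I", 6L)
  q_low <- paste0(strrep("I", 4L), "!", "I")   # Phred 0 at the error

  m <- merge_pairs(r1, q_low, r2, q_r2, min_overlap = 3L,
                   max_mismatch_frac = 0.34)
  expect_identical(m$sequence, "ATGGCTGAA")    # R2 base wins
  expect_identical(m$n_overlap_mismatches, 1L)

  tie <- merge_pairs(r1, strrep("I", 6L), r2, q_r2, min_overlap = 3L,
                     max_mismatch_frac = 0.34)
  expect_identical(tie$sequence, "ATGGATGAA")  # tie goes to R1

  # two equally scoring overlap lengths are ambiguous
  amb <- merge_pairs("ACAT", strrep("I", 4L), revcomp("ATAT"), strrep("I", 4L),
                     min_overlap = 2L, max_mismatch_frac = 0.25)
  expect_identical(amb$status, "reject")
  expect_identical(amb$reject_reason, "AMBIGUOUS_OVERLAP")
})

test_that("classify_read implements the exactly-one-codon library filter", {
  d <- design_library("ATGGCTGAA")

  syn <- classify_read("ATGGCCGAA", d)   # GCC: synonymous Ala, in NNB
  expect_identical(syn$class, "SINGLE_CODON")
  expect_identical(syn$position, 2L)
  expect_identical(syn$codon, "GCC")

  off <- classify_read("ATGGCAGAA", d)   # GCA ends in A: not in NNB
  expect_identical(off$class, "REJECT")
  expect_identical(off$reject_reason, "NOT_NNB")

  expect_identical(classify_read("ATGGCTGAA", d)$class, "WT")

  dbl <- classify_read("ATGGCCGAG", d)
  expect_identical(dbl$reject_reason, "MULTI_CODON")

  start <- classify_read("CTGGCTGAA", d)
  expect_identical(start$reject_reason, "NOT_MUTABLE")

  expect_error(classify_read("ATGGCT", d), "length")
})

test_that("error-free FASTQ round-trips exactly for every variant", {
  d <- design_library(toy_orf(6L, seed = 2L))
  counts <- counts_template(d) |>
    dplyr::mutate(count = 1L)   # one read pair per variant, WT included
  dir <- withr::local_tempdir()
  manifest <- emit_fastq(counts, d, dir, read_length = 12L,
                         overlap_length = 6L, error_rate = 0)
  tab <- count_variants(manifest, d, min_overlap = 5L)
  expect_identical(
    dplyr::arrange(tab, variant_id)$count,
    dplyr::arrange(counts, variant_id)$count
  )
  qc <- count_qc(tab)
  expect_identical(qc$n_retained, qc$n_pairs)
})

test_that("count_variants is invariant to read order and tallies rejects", {
  d <- design_library("ATGGCTGAA")
  counts <- counts_template(d) |>
    dplyr::mutate(count = ifelse(variant_id == "WT", 3L,
                                 ifelse(codon %in% c("TCC", "AAG"), 2L, 0L)))
  dir <- withr::local_tempdir()
  manifest <- emit_fastq(counts, d, dir, read_length = 6L,
                         overlap_length = 3L)
  tab <- count_variants(manifest, d, min_overlap = 3L)

  # shuffle the pairs (jointly in R1 and R2) and recount
  shuffle_fastq <- function(path, perm) {
    rec <- matrix(readLines(path), nrow = 4L)
    writeLines(as.vector(rec[, perm]), path)
  }
  set.seed(1)
  perm <- sample(sum(counts$count))
  shuffle_fastq(manifest$r1_path, perm)
  shuffle_fastq(manifest$r2_path, perm)
  tab2 <- count_variants(manifest, d, min_overlap = 3L)
  expect_identical(tab$count, tab2$count)

  # append a double-mutant pair: counted as a reject, table unchanged
  cat("@dm\nATGTCCAAG\n+\nIIIIIIIII\n",
      file = manifest$r1_path, append = TRUE)
  cat(sprintf("@dm\n%s\n+\nIIIIIIIII\n", revcomp("ATGTCCAAG")),
      file = manifest$r2_path, append = TRUE)
  tab3 <- count_variants(manifest, d, min_overlap = 3L)
  expect_identical(tab3$count, tab$count)
  expect_identical(count_qc(tab3)$MULTI_CODON, 1L)
})

test_that("aa aggregation follows the genetic code and conserves reads", {
  d <- design_library("ATGGCTGAA")
  counts <- counts_template(d) |>
    dplyr::mutate(count = dplyr::case_when(
      variant_id == "WT" ~ 10L,
      codon == "GCC" & position == 2L ~ 5L,   # synonymous Ala -> WT
      codon == "AAG" & position == 2L ~ 3L,   # Lys
      TRUE ~ 0L))
  aa <- aggregate_to_aa(counts)
  expect_identical(aa$count[aa$variant_id == "WT"], 15L)
  expect_identical(aa$count[aa$variant_id == "A2K"], 3L)
  expect_identical(sum(aa$count), sum(counts$count))

  empty <- counts[0, ]
  expect_identical(nrow(aggregate_to_aa(empty)), 0L)
})

test_that("detected_fraction counts strictly above the threshold", {
  tab <- tibble::tibble(
    replicate = 1L, fraction = "F1",
    variant_id = c("WT", "A", "B", "C", "D"),
    position = c(NA, 2L, 2L, 3L, 3L),
    wt_aa = c(NA, "G", "G", "K", "K"),
    mut_aa = c(NA, "A", "C", "D", "E"),
    count = c(999L, 11L, 10L, 200L, 0L))
  res <- detected_fraction(tab, min_reads = 10L)
  expect_equal(res$percent_detected, 50)
  expect_identical(res$n_universe, 4L)

  expect_equal(detected_fraction(tab, min_reads = 0L)$percent_detected, 75)
  expect_error(detected_fraction(tab, min_reads = -1L), "non-negative")

  # monotone non-increasing in min_reads
  pcts <- vapply(c(0L, 5L, 10L, 50L, 500L), function(m) {
    detected_fraction(tab, min_reads = m)$percent_detected
  }, numeric(1L))
  expect_true(all(diff(pcts) <= 0))
})
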