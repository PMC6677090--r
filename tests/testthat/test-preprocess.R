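ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("each cleaning rule claims its crafted read exactly once", {
  insert <- strrep("ACGT", 5)  # valid 20-mer
  seqs <- c(
    paste0(strrep("A", 22), ADAPTER3),        # homopolymer insert
    paste0(strrep("ACT", 5), ADAPTER3),       # 15 nt after trim -> length
    insert,                                   # no 3' adapter
    paste0("ACGTNACGTACGTACGTACGT", ADAPTER3),# contains N
    paste0(insert, "AC", ADAPTER3)            # valid 22-mer
  )
  fq <- write_fastq_fixture(seqs)
  res <- clean_reads(fq, adapter3 = ADAPTER3, adapter5 = ADAPTER5)
  rep <- res$report
  expect_equal(rep$raw_reads, 5L)
  expect_equal(rep$clean_reads, 1L)
  expect_equal(rep$removed_polyACGT, 1L)
  expect_equal(rep$removed_length, 1L)
  expect_equal(rep$removed_no3adapter, 1L)
  expect_equal(rep$removed_polyN, 1L)
  expect_equal(rep$removed_low_quality, 0L)
  expect_equal(rep$removed_5adapter, 0L)
  expect_equal(res$reads, paste0(insert, "AC"))
})

test_that("low-quality and 5'-adapter rules take precedence", {
  seqs <- c(paste0(strrep("A", 22), ADAPTER3),         # low qual AND homopolymer
            paste0(ADAPTER5, "ACGTACGTAC", ADAPTER3))  # starts with 5' adapter
  fq <- write_fastq_fixture(seqs, quals = c("#", "I"))  # '#' = Phred 2
  res <- clean_reads(fq, adapter3 = ADAPTER3, adapter5 = ADAPTER5)
  expect_equal(res$report$removed_low_quality, 1L)
  expect_equal(res$report$removed_5adapter, 1L)
  expect_equal(res$report$clean_reads, 0L)
})

test_that("empty FASTQ gives an all-zero report; all-valid input passes", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  res <- clean_reads(fq, adapter3 = ADAPTER3)
  expect_equal(res$report$raw_reads, 0L)
  expect_equal(res$report$clean_reads, 0L)

  seqs <- rep(paste0(strrep("ACGT", 5), "AC", ADAPTER3), 100)
  res <- clean_reads(write_fastq_fixture(seqs), adapter3 = ADAPTER3)
  expect_equal(res$report$clean_reads, 100L)
  expect_equal(res$report$raw_reads, 100L)
})

test_that("malformed FASTQ errors with the record index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), fq)
  expect_error(clean_reads(fq), "record 2")
})

test_that("cleaning report is a partition on random fixtures (property)", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(0:60, 1)
    seqs <- vapply(seq_len(max(n, 0)), function(j) {
      body <- paste(sample(c("A", "C", "G", "T", "N"),
                           sample(5:35, 1), replace = TRUE,
                           prob = c(0.3, 0.24, 0.24, 0.2, 0.02)),
                    collapse = "")
      if (runif(1) < 0.7) paste0(body, ADAPTER3) else body
    }, character(1))
    quals <- sample(c("#", "5", "I"), max(n, 0), replace = TRUE)
    fq <- write_fastq_fixture(seqs, quals)
    rep <- clean_reads(fq, adapter3 = ADAPTER3, adapter5 = ADAPTER5)$report
    removed <- rep$removed_low_quality + rep$removed_polyN +
      rep$removed_5adapter + rep$removed_no3adapter +
      rep$removed_polyACGT + rep$removed_length
    expect_identical(rep$raw_reads, removed + rep$clean_reads)
  }
})

test_that("collapse_tags merges duplicates and preserves totals", {
  ts <- collapse_tags(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                        "ACGTACGTACGTACGTAC", "TTGTACGTACGTACGTAC"), "L")
  expect_equal(nrow(ts), 2L)
  expect_equal(ts$count[ts$tag == "ACGTACGTACGTACGTAC"], 3L)
  expect_equal(total_reads(ts), 4L)

  empty <- collapse_tags(character(0))
  expect_equal(nrow(empty), 0L)
  expect_equal(total_reads(empty), 0L)

  distinct <- collapse_tags(paste0(strrep("A", 17), c("C","G","T","AA","CC",
                                                      "GG","TT","AC","AG","AT")))
  expect_equal(nrow(distinct), 10L)
  expect_true(all(distinct$count == 1L))
})

test_that("length distribution is read-weighted and sums to 1", {
  ts <- tag_set_of(c("ACGTACGTACGTACGTACGTAC" = 47,  # 22-mer
                     "ACGTACGTACGTACGTACGTA" = 53))  # 21-mer
  ld <- length_distribution(ts)
  expect_equal(ld$fraction[ld$length == 22], 0.47)
  expect_equal(sum(ld$fraction), 1)

  single <- tag_set_of(c("ACGTACGTACGTACGTAC" = 9))
  expect_equal(length_distribution(single)$fraction, 1)

  three <- tag_set_of(c("ACGTACGTACGTACGTAC" = 2, "ACGTACGTACGTACGTACG" = 3,
                        "ACGTACGTACGTACGTACGT" = 5))
  expect_equal(sum(length_distribution(three)$fraction), 1)
  expect_error(length_distribution(collapse_tags(character(0))), "empty")
})

test_that("compare_libraries partitions tags and reads (hand-enumerated)", {
  a <- tag_set_of(c(t1 = 5, t2 = 1))
  b <- tag_set_of(c(t2 = 2, t3 = 4))
  # rename tags to valid sequences is unnecessary: comparison is string-based
  cmp <- compare_libraries(a, b)
  expect_equal(cmp$common_unique, 1L)
  expect_equal(cmp$common_total, 3L)
  expect_equal(cmp$common_total_fraction, 3 / 12)
  expect_equal(cmp$a_specific_total, 5L)
  expect_equal(cmp$b_specific_total, 4L)
  expect_equal(cmp$common_total_fraction + cmp$a_specific_total_fraction +
                 cmp$b_specific_total_fraction, 1, tolerance = 1e-9)

  disj <- compare_libraries(tag_set_of(c(t1 = 2)), tag_set_of(c(t2 = 3)))
  expect_equal(disj$common_unique, 0L)
  expect_equal(disj$common_total, 0L)

  same <- compare_libraries(a, a)
  expect_equal(same$a_specific_total, 0L)
  expect_equal(same$common_total_fraction, 1)
})

test_that("compare_libraries is symmetric", {
  set.seed(11)
  mk <- function() {
    tags <- replicate(20, paste(sample(c("A","C","G","T"), 20, TRUE),
                                collapse = ""))
    counts <- sample(1:50, 20, TRUE)
    tag_set(data.frame(tag = unique(tags),
                       count = counts[seq_along(unique(tags))]), "x")
  }
  a <- mk(); b <- mk()
  ab <- compare_libraries(a, b)
  ba <- compare_libraries(b, a)
  expect_equal(ab$common_unique, ba$common_unique)
  expect_equal(ab$common_total, ba$common_total)
  expect_equal(ab$a_specific_total, ba$b_specific_total)
  expect_equal(ab$b_specific_unique, ba$a_specific_unique)
})

test_that("collapsed FASTA uses the t{serial}_x{count} header dialect", {
  ts <- tag_set_of(c("ACGTACGTACGTACGTACGTAC" = 12345, "TTTTACGTACGTACGTACGT" = 7))
  fa <- tempfile(fileext = ".fa")
  write_collapsed_fasta(ts, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], ">t1_x12345")
  expect_equal(lines[3], ">t2_x7")
})
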