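adapter <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming recovers constructed inserts", {
  set.seed(1)
  insert <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  r1 <- paste0(insert, substr(adapter, 1, 10))
  out <- trim_adapter(r1, adapter, min_overlap = 6)
  expect_true(out$trimmed)
  expect_equal(out$insert, insert)

  # no adapter anywhere: unchanged, flagged untrimmed
  r2 <- "ACACACACACACACACACAC"
  out2 <- trim_adapter(r2, adapter)
  expect_false(out2$trimmed)
  expect_equal(out2$insert, r2)

  # one mismatch within a 10-nt overlap at rate 0.1 still trims
  a10 <- substr(adapter, 1, 10)
  substr(a10, 5, 5) <- if (substr(a10, 5, 5) == "A") "C" else "A"
  out3 <- trim_adapter(paste0(insert, a10), adapter, min_overlap = 6,
                       max_mismatch_rate = 0.1)
  expect_true(out3$trimmed)
  expect_equal(out3$insert, insert)
})

test_that("trimming picks the longest match, leftmost on ties, and never lengthens", {
  # two full-adapter matches: the leftmost wins
  insert <- "AAAAA"
  read <- paste0(insert, adapter, adapter)
  out <- trim_adapter(read, adapter, min_overlap = 6)
  expect_equal(out$insert, insert)
  # an interrupted adapter start does not qualify, a clean later one does
  read2 <- paste0("ACGTACGTAC", substr(adapter, 1, 8), "TT",
                  substr(adapter, 1, 6))
  out2 <- trim_adapter(read2, adapter, min_overlap = 6)
  expect_equal(out2$insert, paste0("ACGTACGTAC", substr(adapter, 1, 8), "TT"))
  set.seed(2)
  reads <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(15:35, 1), TRUE),
          collapse = ""), "")
  out <- trim_adapter(reads, adapter)
  expect_true(all(nchar(out$insert) <= nchar(reads)))
})

test_that("trimming agrees with a brute-force offset scan", {
  set.seed(3)
  brute <- function(read, adapter, min_overlap, rate) {
    L <- nchar(read); alen <- nchar(adapter)
    best <- NULL
    for (s in seq_len(L)) {
      ov <- min(alen, L - s + 1)
      if (ov < min_overlap) next
      mm <- sum(strsplit(substr(read, s, s + ov - 1), "")[[1]] !=
                  strsplit(substr(adapter, 1, ov), "")[[1]])
      if (mm <= floor(rate * ov + 1e-9)) {
        if (is.null(best) || ov > best$ov) best <- list(s = s, ov = ov)
      }
    }
    if (is.null(best)) read else substr(read, 1, best$s - 1)
  }
  for (i in 1:100) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), TRUE),
                 collapse = "")
    keep <- sample(0:nchar(adapter), 1)
    read <- substr(paste0(ins, substr(adapter, 1, keep)), 1, 35)
    got <- trim_adapter(read, adapter)$insert
    expect_equal(got, brute(read, adapter, 6, 0.1), label = read)
  }
})

test_that("filter_and_collapse applies the 15-35 window and merges counts", {
  short <- strrep("A", 12)
  t22 <- paste(rep("ACGTACGTACGTACGTACGTAC", 3))
  fc <- filter_and_collapse(
    inserts_f3 = c(rep(short, 5), rep("ACGTACGTACGTACGTACGTAC", 3),
                   "GGGTTTCCCAAAGGGTTT"),
    inserts_f4 = c(rep("ACGTACGTACGTACGTACGTAC", 7), strrep("G", 36)))
  expect_equal(unname(fc$discarded["F3", "too_short"]), 5)
  expect_equal(unname(fc$discarded["F4", "too_long"]), 1)
  row <- fc$tags[fc$tags$sequence == "ACGTACGTACGTACGTACGTAC", ]
  expect_equal(row$count_f3, 3)
  expect_equal(row$count_f4, 7)
  expect_true(all(nchar(fc$tags$sequence) >= 15 &
                    nchar(fc$tags$sequence) <= 35))
  # conservation: retained totals equal kept insert counts
  expect_equal(sum(fc$tags$count_f3), 4)
  expect_equal(sum(fc$tags$count_f4), 7)
})

test_that("length distribution reports count-weighted fractions", {
  tags <- data.frame(sequence = c(strrep("A", 20), strrep("C", 22)),
                     count_f3 = c(10L, 30L), count_f4 = c(0L, 5L))
  ld <- summarize_length_distribution(tags)
  expect_equal(unname(ld$frac_21_24["F3"]), 0.75)
  expect_equal(unname(ld$frac_21_24["F4"]), 1.0)
  expect_equal(sum(ld$table$count_f3), 40)
  expect_equal(sum(ld$table$frac_f3), 1)
  # empty tag set: all-zero table
  ld0 <- summarize_length_distribution(tags[0, ])
  expect_true(all(ld0$table$count_f3 == 0))
})

test_that("preprocess_reads gates on mean quality and reports stats", {
  dir <- tempdir()
  f3 <- file.path(dir, "q3.fastq"); f4 <- file.path(dir, "q4.fastq")
  ins <- "ACGTACGTACGTACGTACGTAC"
  good <- paste0(ins, substr(adapter, 1, 13))
  writeLines(c("@r1", good, "+", strrep("I", nchar(good)),
               "@r2", good, "+", strrep("#", nchar(good))), f3)
  writeLines(c("@r1", good, "+", strrep("I", nchar(good))), f4)
  pp <- preprocess_reads(f3, f4, adapter)
  expect_equal(pp$stats$low_quality, c(1, 0))
  expect_equal(pp$tags$sequence, ins)
  expect_equal(pp$tags$count_f3, 1)
})
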