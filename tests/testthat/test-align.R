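test_that("locus strings round-trip and use 1-based inclusive arithmetic", {
  s <- "Chr4:104560738-104560800+"
  p <- parse_locus(s)
  expect_equal(p$end - p$start + 1, 63)
  expect_equal(locus_string(p$chrom, p$start, p$end, p$strand), s)
  expect_error(parse_locus("Chr1:10"), "malformed")
})

test_that("a verbatim planted tag yields a single exact hit", {
  g <- toy_genome()
  tag <- "ACGGTTCAGGTCCAGATCGGAT"
  g <- plant_seq(g, "Chr1", 501, tag)
  aln <- align_tags(data.frame(sequence = tag), as_dss(g))
  expect_equal(nrow(aln$hits), 1)
  expect_equal(aln$hits$start, 501)
  expect_equal(aln$hits$end, 522)
  expect_equal(aln$hits$strand, "+")
  expect_equal(aln$hits$n_mismatch, 0)
})

test_that("end mismatches are tolerated but interior mismatches are not", {
  g <- toy_genome(seed = 6)
  planted <- "ACGGTTCAGGTCCAGATCGGAT"
  g <- plant_seq(g, "Chr2", 1001, planted)
  flip <- function(s, i) {
    substr(s, i, i) <- if (substr(s, i, i) == "A") "G" else "A"
    s
  }
  # mismatch at read offset 0 (5'-most position)
  t1 <- flip(planted, 1)
  a1 <- align_tags(data.frame(sequence = t1), as_dss(g))
  h1 <- a1$hits[a1$hits$chrom == "Chr2" & a1$hits$start == 1001, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$mismatch_offsets, "0")
  # interior mismatch at offset 10 of a 22-mer: no qualifying locus
  t2 <- flip(planted, 11)
  a2 <- align_tags(data.frame(sequence = t2), as_dss(g))
  expect_false(any(a2$hits$chrom == "Chr2" & a2$hits$start == 1001))
  # three end mismatches exceed the budget
  t3 <- flip(flip(flip(planted, 1), 2), 22)
  a3 <- align_tags(data.frame(sequence = t3), as_dss(g))
  expect_false(any(a3$hits$chrom == "Chr2" & a3$hits$start == 1001))
})

test_that("alignment equals the brute-force scan on small genomes", {
  g <- toy_genome(seed = 7, len = 5000)
  set.seed(8)
  tags <- character(0)
  # planted tags with random end damage, plus fully random tags
  for (i in 1:12) {
    L <- sample(16:28, 1)
    pos <- sample(4000, 1)
    ch <- sample(names(g), 1)
    t <- substr(g[[ch]], pos, pos + L - 1)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      for (p in sample(c(1, 2, L - 1, L), nmut)) {
        substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(t, p, p)), 1)
      }
    }
    if (sample(c(TRUE, FALSE), 1)) t <- .oracle_revcomp(t)
    tags <- c(tags, t)
  }
  for (i in 1:8) {
    tags <- c(tags, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                          collapse = ""))
  }
  tags <- unique(tags)
  aln <- align_tags(data.frame(sequence = tags), as_dss(g))
  for (t in tags) {
    got <- aln$hits[aln$hits$sequence == t,
                    c("chrom", "start", "end", "strand", "n_mismatch",
                      "mismatch_offsets")]
    rownames(got) <- NULL
    want <- brute_align(t, g)
    rownames(want) <- NULL
    expect_equal(got, want, label = t)
  }
})

test_that("aligning the reverse complement swaps all hit strands", {
  g <- toy_genome(seed = 9)
  tag <- "TTGACCGGTACAGGTTCAGCAT"
  g <- plant_seq(g, "Chr1", 777, tag)
  a_f <- align_tags(data.frame(sequence = tag), as_dss(g))
  a_r <- align_tags(data.frame(sequence = .oracle_revcomp(tag)), as_dss(g))
  expect_equal(nrow(a_f$hits), nrow(a_r$hits))
  expect_equal(a_f$hits[, c("chrom", "start", "end")],
               a_r$hits[, c("chrom", "start", "end")])
  expect_true(all(a_f$hits$strand != a_r$hits$strand))
})

test_that("multi-copy tags are counted and repeat tags excluded", {
  g <- toy_genome(seed = 10, len = 30000)
  tag <- "GTACCGGATCAATGCCGTAGCA"
  for (p in c(1000, 5000, 9000)) g <- plant_seq(g, "Chr1", p, tag)
  rep_tag <- "CATTGGCCAATGGCCATTGGCA"
  for (p in seq(1000, 22000, by = 1000)) g <- plant_seq(g, "Chr2", p, rep_tag)
  aln <- align_tags(data.frame(sequence = c(tag, rep_tag)), as_dss(g),
                    max_loci = 20)
  cl <- count_loci(aln)
  expect_equal(cl$n_loci[cl$sequence == tag], 3)
  expect_true(cl$repeat_flag[cl$sequence == rep_tag])
  expect_gte(cl$n_loci[cl$sequence == rep_tag], 21)
  expect_false(rep_tag %in% aln$hits$sequence)
})
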