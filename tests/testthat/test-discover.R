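test_that("conservation classification applies the substitution budget", {
  ortho <- c("ACGGTTCAGGTCCAGATCGGAT", "TTGGCCAAGGTTCCAAGGTTCC")
  same <- ortho[1]
  two <- sub("^AC", "GT", ortho[1])
  three <- sub("^ACG", "GTA", ortho[1])
  expect_equal(classify_conservation(c(same, two, three), ortho),
               c("conserved_novel", "conserved_novel", "specific_novel"))
  # one-end extension counts toward the budget
  ext1 <- paste0(ortho[1], "A")
  ext3 <- paste0("TTT", ortho[1])
  expect_equal(classify_conservation(c(ext1, ext3), ortho),
               c("conserved_novel", "specific_novel"))
  # empty ortholog set: everything specific
  expect_equal(classify_conservation(same, character(0)), "specific_novel")
})

test_that("cluster chaining follows the strict 10 kb gap rule", {
  loci <- data.frame(chrom = "Chr1", start = c(1000, 5000),
                     end = c(1060, 5063))
  cl <- detect_clusters(loci)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n, 2)
  expect_equal(cl$clusters$max_gap, 3940)

  # the printed multi-locus example: gaps 869,041 and 151,522 -> no cluster
  p <- parse_locus(c("Chr4:104560738-104560800+",
                     "Chr4:105581425-105581487+",
                     "Chr4:105429841-105429903+"))
  cl2 <- detect_clusters(p)
  expect_equal(nrow(cl2$clusters), 0)
  expect_true(all(is.na(cl2$assignments$cluster_id)))

  # three loci chained by 9 kb gaps form one cluster of 3
  loci3 <- data.frame(chrom = "Chr2",
                      start = c(1000, 10060, 19120),
                      end = c(1060, 10120, 19180))
  cl3 <- detect_clusters(loci3)
  expect_equal(cl3$clusters$n, 3)
  expect_equal(cl3$clusters$max_gap, 9000)
  # a gap of exactly the window does not chain
  loci4 <- data.frame(chrom = "Chr2", start = c(1000, 11061),
                      end = c(1060, 11121))
  expect_equal(nrow(detect_clusters(loci4)$clusters), 0)
})

test_that("cluster detection equals brute-force all-pairs chaining", {
  set.seed(30)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    loci <- data.frame(
      chrom = sample(paste0("Chr", 1:3), n, TRUE),
      start = sort(sample(1e6, n)))
    loci$end <- loci$start + sample(50:90, n, TRUE)
    loci <- loci[order(loci$chrom, loci$start), ]
    cl <- detect_clusters(loci)
    bf <- brute_clusters(loci)
    expect_equal(!is.na(cl$assignments$cluster_id), bf$in_cluster)
    # members of one detected cluster share one brute-force component
    for (cid in unique(stats::na.omit(cl$assignments$cluster_id))) {
      comp <- bf$component[which(cl$assignments$cluster_id == cid)]
      expect_equal(length(unique(comp)), 1)
    }
  }
})

test_that("mirtron calls require both ends at splice boundaries", {
  introns <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(5000, 5056),
                                    strand = "+")
  exact <- data.frame(chrom = "Chr1", start = 5000, end = 5056, strand = "+")
  off5 <- data.frame(chrom = "Chr1", start = 5005, end = 5056, strand = "+")
  near <- data.frame(chrom = "Chr1", start = 4998, end = 5058, strand = "+")
  wrong_strand <- data.frame(chrom = "Chr1", start = 5000, end = 5056,
                             strand = "-")
  loci <- rbind(exact, off5, near, wrong_strand)
  expect_equal(detect_mirtrons(loci, introns, tolerance = 3),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_warning(f <- detect_mirtrons(exact, NULL), "no intron")
  expect_false(f)
})

test_that("genomic density is loci per Mb, 2 decimals", {
  loci <- data.frame(chrom = rep("Chr1", 12), start = 1:12 * 1000,
                     end = 1:12 * 1000 + 60)
  d <- genomic_density(loci, c(Chr1 = 60e6, Chr2 = 10e6))
  expect_equal(d$density$density, c(0.20, 0.00))
  expect_error(genomic_density(loci, c(Chr1 = 0)), "zero-length")
})

test_that("novel calling merges known overlaps and multi-locus matures", {
  run <- mini_run()
  sim <- run$sim; res <- run$res
  truth <- sim$truth$loci
  novel_truth <- truth[truth$status != "known", ]
  nv <- res$novel
  # no called novel gene overlaps a known precursor locus
  known <- truth[truth$status == "known", ]
  kg <- GenomicRanges::GRanges(known$chrom,
                               IRanges::IRanges(known$start, known$end))
  ng <- GenomicRanges::GRanges(nv$chrom,
                               IRanges::IRanges(nv$prec_start, nv$prec_end))
  expect_equal(length(GenomicRanges::findOverlaps(ng, kg,
                                                  ignore.strand = TRUE)), 0)
  # the multi-copy gene is one gene with both loci
  mc <- truth[truth$role == "multicopy", ]
  if (nrow(mc) && mc$status[1] != "known") {
    hit <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(mc$chrom, IRanges::IRanges(mc$start, mc$end)),
      ng, ignore.strand = TRUE)
    called <- unique(S4Vectors::subjectHits(hit))
    expect_equal(length(called), 1)
    expect_equal(nv$n_loci[called], 2)
  }
  # planted mirtrons are recovered exactly
  mt <- truth[truth$role == "mirtron", ]
  mirt_loci <- res$loci[res$loci$mirtron, ]
  expect_equal(nrow(mirt_loci), nrow(mt))
  # planted conserved-novel genes classify conserved
  planted_cons <- novel_truth[novel_truth$status == "conserved_novel", ]
  cg <- GenomicRanges::GRanges(planted_cons$chrom,
                               IRanges::IRanges(planted_cons$start,
                                                planted_cons$end))
  ov <- GenomicRanges::findOverlaps(ng, cg, ignore.strand = TRUE)
  expect_equal(sort(unique(nv$status[S4Vectors::queryHits(ov)])),
               "conserved_novel")
})

test_that("gene-set union identity holds", {
  m <- merge_library_gene_sets(paste0("g", 1:30), paste0("g", 21:45))
  expect_equal(m$n_union, m$n_f3 + m$n_f4 - m$n_common)
  expect_equal(m$n_union, 45)
  run <- mini_run()
  mm <- run$res$merge
  expect_equal(mm$n_union, mm$n_f3 + mm$n_f4 - mm$n_common)
})
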