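# Small hand-built annotation world: one tRNA overlapping an exon, one
# known miRNA duplex, on a toy genome.
.ann_world <- function() {
  g <- toy_genome(seed = 20, len = 6000)
  mature <- "ACGGTTCAGGTCCAGATCGGAT"
  star <- .oracle_revcomp(mature)
  hairpin <- paste0(mature, "ATTTATTTAA", star)
  g <- plant_seq(g, "Chr1", 2001, hairpin)
  trna_seq <- substr(g[["Chr1"]], 4001, 4075)
  ann <- GenomicRanges::GRanges(
    c("Chr1", "Chr1", "Chr1", "Chr1", "Chr1"),
    IRanges::IRanges(c(2001, 2001, 2033, 4001, 3990),
                     c(2054, 2022, 2054, 4075, 4400)),
    strand = c("+", "+", "+", "+", "+"))
  S4Vectors::mcols(ann)$type <- c("pre_miRNA", "miRNA", "miRNA_star",
                                  "tRNA", "exon")
  S4Vectors::mcols(ann)$ID <- c("mir-T1_pre", "mir-T1", "mir-T1*",
                                "trna1", "exon1")
  list(genome = g, ann = ann, mature = mature, star = star,
       trna_seq = trna_seq)
}

test_that("tags classify by the fixed priority with known miRNAs first", {
  w <- .ann_world()
  tags <- data.frame(
    sequence = c(w$mature,                        # known mature
                 substr(w$trna_seq, 10, 31),      # tRNA + exon overlap
                 "GGGTTTAAACCCGGGTTTAAAC"),       # nowhere in the genome
    count_f3 = c(5L, 3L, 2L), count_f4 = c(1L, 1L, 0L))
  aln <- align_tags(tags, as_dss(w$genome))
  cats <- classify_tags(tags, aln, w$ann)
  got <- setNames(cats$category, cats$sequence)
  expect_equal(unname(got[w$mature]), "known_mirna")
  expect_equal(unname(got[substr(w$trna_seq, 10, 31)]), "tRNA")
  expect_equal(unname(got["GGGTTTAAACCCGGGTTTAAAC"]), "unmapped")
  # partition: every tag gets exactly one category
  expect_equal(sort(cats$sequence), sort(tags$sequence))
})

test_that("assignment records 5'/3' offsets and the star arm", {
  w <- .ann_world()
  shifted <- substr(w$genome[["Chr1"]], 2002, 2024)  # +1 at 5', +2 at 3'
  tags <- data.frame(sequence = c(w$mature, shifted, w$star),
                     count_f3 = c(10L, 4L, 2L), count_f4 = c(0L, 1L, 1L))
  aln <- align_tags(tags, as_dss(w$genome))
  prods <- data.frame(product_id = c("mir-T1", "mir-T1*"),
                      type = c("mature", "star"),
                      chrom = "Chr1", start = c(2001, 2033),
                      end = c(2022, 2054), strand = "+")
  asg <- assign_products(tags, aln, prods)
  ref <- asg[asg$sequence == w$mature, ]
  expect_equal(ref$product_id, "mir-T1")
  expect_equal(c(ref$offset5, ref$offset3), c(0, 0))
  sh <- asg[asg$sequence == shifted, ]
  expect_equal(c(sh$offset5, sh$offset3), c(1, 2))
  st <- asg[asg$sequence == w$star, ]
  expect_equal(st$product_id, "mir-T1*")
})

test_that("non-templated 3' additions are split out of the 3' offset", {
  w <- .ann_world()
  gnext <- substr(w$genome[["Chr1"]], 2023, 2023)
  nta_base <- if (gnext == "A") "T" else "A"
  tagged <- paste0(w$mature, nta_base)
  tags <- data.frame(sequence = tagged, count_f3 = 3L, count_f4 = 0L)
  aln <- align_tags(tags, as_dss(w$genome))
  prods <- data.frame(product_id = "mir-T1", type = "mature", chrom = "Chr1",
                      start = 2001, end = 2022, strand = "+")
  asg <- assign_products(tags, aln, prods)
  expect_equal(asg$nta, nta_base)
  expect_equal(asg$offset3, 0)
})

test_that("the reference isomiR is the most abundant variant", {
  asg <- data.frame(
    sequence = c(strrep("A", 23), strrep("C", 22), strrep("G", 22)),
    product_id = c("p1", "p1", "p2"),
    offset5 = 0L, offset3 = c(1L, 0L, 0L), nta = "",
    count_f3 = c(4453L, 3477L, 7L), count_f4 = c(0L, 0L, 3L))
  cat <- catalog_isomirs(asg)
  p1 <- cat$products[cat$products$product_id == "p1", ]
  expect_equal(nchar(p1$ref_sequence), 23)
  expect_equal(p1$n_isomirs, 2)
  expect_equal(p1$total_f3, 4453 + 3477)
  # single variant: its own reference
  p2 <- cat$products[cat$products$product_id == "p2", ]
  expect_equal(p2$n_isomirs, 1)
  expect_equal(p2$ref_sequence, strrep("G", 22))
  # counts conserve per product
  expect_equal(sum(cat$isomirs$count_f3), sum(asg$count_f3))
})

test_that("reference ties break to the lexicographically smallest sequence", {
  asg <- data.frame(sequence = c("TTTTTTTTTTTTTTTT", "AAAAAAAAAAAAAAAA"),
                    product_id = "p1", offset5 = 0L, offset3 = 0L, nta = "",
                    count_f3 = c(5L, 5L), count_f4 = c(0L, 0L))
  cat <- catalog_isomirs(asg)
  expect_equal(cat$products$ref_sequence, strrep("A", 16))
})

test_that("star dominance is flagged when the star total exceeds the mature", {
  pt <- data.frame(product_id = c("g1_m", "g1_s", "g2_m", "g2_s"),
                   gene_id = c("g1", "g1", "g2", "g2"),
                   type = c("mature", "star", "mature", "star"),
                   total_f3 = c(3652L, 16200L, 100L, 5L),
                   total_f4 = c(0L, 0L, 0L, 0L))
  d <- flag_arm_dominance(pt)
  expect_equal(d$dominant_arm[d$gene_id == "g1"], "star")
  expect_equal(d$dominant_arm[d$gene_id == "g2"], "mature")
})

test_that("planted contaminant reads classify as their ncRNA source", {
  run <- mini_run()
  res <- run$res
  cats <- table(res$categories$category)
  expect_gt(sum(cats[names(cats) %in% c("rRNA", "tRNA")]), 0)
  # category totals partition the tag set
  expect_equal(sum(cats), nrow(res$tags))
})
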