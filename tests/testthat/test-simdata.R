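test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(n_mirna_loci = 5, n_known = 4,
                          n_conserved_novel = 3, n_clustered = 0,
                          n_mirtrons = 0, n_multicopy = 0),
               "exceeds n_mirna_loci")
  expect_error(sim_config(n_clustered = 1), "at least 2")
})

test_that("genome generation respects lengths and is deterministic", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 50000, seed = 99)
  g1 <- generate_genome(cfg)
  expect_equal(length(g1$genome), 2)
  expect_true(all(Biostrings::width(g1$genome) == 50000))
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(length(g1$annotation), length(g2$annotation))
  # gene models carry exons and introns; ncRNA features present
  types <- as.character(S4Vectors::mcols(g1$annotation)$type)
  expect_true(all(c("gene", "exon", "intron", "rRNA", "tRNA") %in% types))
})

test_that("planting honors cluster, mirtron and multi-copy constraints", {
  sim <- mini_sim()
  loci <- sim$truth$loci
  # multicopy: one mature at >= 2 identical loci on one chromosome
  mc <- loci[loci$role == "multicopy", ]
  expect_gte(nrow(mc), 2)
  expect_equal(length(unique(mc$chrom)), 1)
  expect_equal(length(unique(mc$precursor_seq)), 1)
  # clusters: pairwise adjacent gaps < 10 kb within each planted cluster
  for (cid in unique(stats::na.omit(loci$cluster_id))) {
    m <- loci[!is.na(loci$cluster_id) & loci$cluster_id == cid, ]
    expect_gte(nrow(m), 2)
    expect_equal(length(unique(m$chrom)), 1)
    m <- m[order(m$start), ]
    gaps <- m$start[-1] - m$end[-nrow(m)]
    expect_true(all(gaps < 10000))
  }
  # mirtrons coincide with an annotated intron on the same strand
  introns <- sim$annotation[
    as.character(S4Vectors::mcols(sim$annotation)$type) == "intron"]
  mt <- loci[loci$role == "mirtron", ]
  for (i in seq_len(nrow(mt))) {
    hit <- introns[as.character(GenomeInfoDb::seqnames(introns)) == mt$chrom[i] &
                     GenomicRanges::start(introns) == mt$start[i] &
                     GenomicRanges::end(introns) == mt$end[i] &
                     as.character(GenomicRanges::strand(introns)) == mt$strand[i]]
    expect_equal(length(hit), 1)
  }
  # genome sequence at each planted locus is the precursor
  for (i in seq_len(nrow(loci))) {
    s <- as.character(Biostrings::extractAt(
      sim$genome[[loci$chrom[i]]],
      IRanges::IRanges(loci$start[i], loci$end[i])))
    if (loci$strand[i] == "-") s <- .oracle_revcomp(s)
    expect_equal(s, loci$precursor_seq[i])
  }
})

test_that("known and ortholog exports mirror the planted truth", {
  sim <- mini_sim()
  loci <- sim$truth$loci
  kn <- loci[loci$status == "known" & !duplicated(loci$gene_id), ]
  expect_equal(length(sim$truth$known_mature), nrow(kn))
  expect_setequal(unname(sim$truth$known_mature), kn$mature_seq)
  cons <- loci[loci$status == "conserved_novel" & !duplicated(loci$gene_id), ]
  expect_equal(length(sim$truth$ortholog_mature), nrow(cons))
  # each ortholog is within 2 substitutions of its planted mature
  for (i in seq_len(nrow(cons))) {
    o <- unname(sim$truth$ortholog_mature[i])
    m <- cons$mature_seq[i]
    expect_equal(nchar(o), nchar(m))
    d <- sum(strsplit(o, "")[[1]] != strsplit(m, "")[[1]])
    expect_lte(d, 2)
  }
})

test_that("read realization follows the isomiR and conservation contracts", {
  sim <- mini_sim()
  v <- sim$libs$variants
  expect_true(all(abs(v$offset5) <= 2 & abs(v$offset3) <= 3))
  # conservation: emitted reads = realized product counts + contaminants
  expect_equal(length(sim$libs$reads$F3),
               sum(v$count_f3) + unname(sim$libs$n_contam["F3"]))
  expect_equal(length(sim$libs$reads$F4),
               sum(v$count_f4) + unname(sim$libs$n_contam["F4"]))
  # per-product counts decompose over variants
  tot <- tapply(v$count_f3 + v$count_f4, v$product_id, sum)
  expr <- sim$libs$expression
  for (p in names(tot)) {
    expect_equal(unname(tot[p]),
                 expr$count_f3[expr$product_id == p] +
                   expr$count_f4[expr$product_id == p])
  }
})

test_that("degenerate generator settings collapse as specified", {
  cfg0 <- sim_config(n_chromosomes = 1, chrom_length = 150000,
                     n_mirna_loci = 6, n_clustered = 0, n_mirtrons = 0,
                     n_multicopy = 0, n_known = 2, n_conserved_novel = 1,
                     n_decoys = 0, mean_depth = 3000, frac_de = 0,
                     isomir_decay = 0, nta_prob = 0, contam_frac = 0,
                     seed = 7)
  sim <- simulate_srna_experiment(cfg0)
  # frac_de = 0: no planted fold change anywhere
  expect_true(all(sim$truth$products$lfc == 0))
  # isomir_decay = 0 and nta_prob = 0: only reference isomiRs are emitted
  v <- sim$libs$variants
  expect_true(all(v$offset5 == 0 & v$offset3 == 0 & v$nta == ""))
  expect_equal(length(sim$libs$reads$F3), sum(v$count_f3))
})

test_that("realized counts approach planted means at high depth", {
  set.seed(1)
  means <- rep(10000, 50)
  k <- simulate_product_counts(means, lfc = 0)
  expect_true(all(abs(k[, "F3"] / means - 1) < 0.05))
  expect_true(all(abs(k[, "F4"] / means - 1) < 0.05))
  # planted fold change shifts the two libraries symmetrically
  k2 <- simulate_product_counts(rep(10000, 50), lfc = 2)
  expect_true(all(abs(k2[, "F3"] / k2[, "F4"] / 4 - 1) < 0.2))
})

test_that("identical configs give byte-identical generator outputs", {
  cfg <- mini_config()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_simdata(simulate_srna_experiment(cfg), d1)
  write_simdata(simulate_srna_experiment(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
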