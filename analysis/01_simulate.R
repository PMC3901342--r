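#!/usr/bin/env Rscript
# Step 1 — simulate the two-library small RNA experiment.
#
# Generates a ~2 Mb four-chromosome genome with gene models and ncRNA
# features, plants ~100 miRNA hairpin loci (clusters, mirtrons, multi-copy
# genes, known and conserved-novel subsets, plus non-hairpin decoys), and
# realizes ~200,000 reads across the castrated (F3) and intact (F4)
# libraries with isomiR spectra, non-templated additions, ncRNA
# contamination and planted fold changes under Poisson noise.

suppressMessages(library(srnaforge))

outdir <- "results/simdata"
cfg <- sim_config(seed = 1)
sim <- simulate_srna_experiment(cfg)
write_simdata(sim, outdir)

loci <- sim$truth$loci
cat("Planted", length(unique(loci$gene_id)), "miRNA genes at", nrow(loci),
    "loci:\n")
cat("  known:", sum(loci$status == "known" & !duplicated(loci$gene_id)),
    " conserved novel:",
    sum(loci$status == "conserved_novel" & !duplicated(loci$gene_id)),
    " specific novel:",
    sum(loci$status == "specific_novel" & !duplicated(loci$gene_id)), "\n")
cat("  clusters:", length(unique(stats::na.omit(loci$cluster_id))),
    " mirtrons:", sum(loci$role == "mirtron"),
    " multi-copy genes:",
    length(unique(loci$gene_id[loci$role == "multicopy"])), "\n")
cat("Realized reads: F3 =", length(sim$libs$reads$F3),
    " F4 =", length(sim$libs$reads$F4), "\n")
cat("Planted DE products:", sum(sim$truth$products$is_de), "of",
    nrow(sim$truth$products), "\n")
cat("Outputs in", outdir, "\n")
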