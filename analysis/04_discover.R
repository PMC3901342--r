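#!/usr/bin/env Rscript
# Step 4 — discover novel miRNA genes.
#
# Candidate tags (mapped, not attributable to any annotation) are grouped
# into candidate loci; 90-nt precursor windows around each representative
# mature are folded into single stem-loops, trimmed to the duplex, refolded
# and gated at -20 kcal/mol plus the hairpin-quality rules. Passing
# candidates become novel genes, classified conserved or species-specific
# against the ortholog mature set, and annotated for clusters, mirtrons and
# genomic density.

suppressMessages(library(srnaforge))

indir <- "results/simdata"
outdir <- "results/04_discover"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# the pipeline orchestrator runs preprocess -> align -> discover -> quantify;
# this driver re-runs it end to end and keeps the discovery tables
res <- suppressWarnings(run_pipeline(pipeline_config(
  genome = file.path(indir, "genome.fa"),
  annotation = file.path(indir, "annotation.gff3"),
  reads_f3 = file.path(indir, "reads_F3.fastq"),
  reads_f4 = file.path(indir, "reads_F4.fastq"),
  ortholog_mature = file.path(indir, "ortholog_mature.fa")), outdir))

nv <- res$novel
cat("Novel genes:", nrow(nv), "\n")
print(table(nv$status))
cat("Energy range of novel precursors: [",
    min(nv$delta_g), ",", max(nv$delta_g), "] kcal/mol\n")
cat("Clusters:", nrow(res$clusters), " mirtrons:", sum(res$loci$mirtron),
    "\n")
print(res$density)
cat(sprintf("Intergenic fraction of novel loci: %.1f%%\n",
            100 * res$intergenic_fraction))
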