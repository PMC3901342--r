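#!/usr/bin/env Rscript
# Step 6 — summary report.
#
# Gathers the per-library known / conserved-novel / specific-novel gene
# tallies, the two-library gene-set merge, differential-expression totals
# by direction with the percentage of the gene union, isomiR ranges, and
# cluster/mirtron counts into one table.

suppressMessages(library(srnaforge))

outdir <- "results/06_report"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

summary <- read.table("results/04_discover/summary.tsv", header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary, row.names = FALSE)

s <- setNames(summary$value, summary$metric)
cat(sprintf("\n%d unique miRNA genes (%d in F3, %d in F4, %d common).\n",
            s["genes_union"], s["genes_f3"], s["genes_f4"],
            s["genes_common"]))
cat(sprintf("%d products differentially expressed (%d up, %d down): %.1f%% of the union.\n",
            s["de_total"], s["de_up"], s["de_down"], s["de_pct_of_union"]))
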