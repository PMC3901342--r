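#!/usr/bin/env Rscript
# Step 5 — quantify expression and test differential expression.
#
# Product counts (mature and star arms separately, summed over isomiRs)
# are TMM-normalized; each product is tested between the two libraries
# with the conditional exact binomial test under Poisson technical noise,
# and called differential at strictly more than 2-fold with p < 0.001.

suppressMessages(library(srnaforge))

outdir <- "results/05_quantify"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# stage outputs from step 4 (the full pipeline run)
prods <- read.table("results/04_discover/products.tsv", header = TRUE,
                    sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
cm <- build_counts(prods)
factors <- tmm_factors(cm$counts)
de <- call_de(cm$counts, factors)
write.table(de, file.path(outdir, "de_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
scatter <- de[, c("product_id", "log2_norm_f3", "log2_norm_f4", "call")]
write.table(scatter, file.path(outdir, "scatter.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("TMM factors: F3 %.4f, F4 %.4f\n", factors[1], factors[2]))
cat("DE calls:\n")
print(table(de$call))
called <- de[de$call != "ns", ]
cat(sprintf("Minimum fold among calls: %.2f; maximum p: %.2e\n",
            min(2^abs(called$log2fc)), max(called$pvalue)))
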