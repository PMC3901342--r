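#!/usr/bin/env Rscript
# Step 3 — map tags to the genome and annotate them.
#
# Every genomic occurrence of each tag is located, allowing at most two
# mismatches confined to the two outermost positions of either read end.
# Tags are then classified against the annotation hierarchy (known miRNA
# first, then rRNA > tRNA > snoRNA > other ncRNA > mRNA exon), and tags
# over known mature/star loci are assigned to products with isomiR
# offsets.

suppressMessages(library(srnaforge))

indir <- "results/simdata"
outdir <- "results/03_align"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- Biostrings::readDNAStringSet(file.path(indir, "genome.fa"))
names(genome) <- sub("\\s.*", "", names(genome))
ann <- rtracklayer::import(file.path(indir, "annotation.gff3"))
tags <- read.table("results/02_preprocess/tags.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)

aln <- align_tags(tags, genome)
write.table(aln$hits, file.path(outdir, "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cats <- classify_tags(tags, aln, ann)
write.table(cats, file.path(outdir, "categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

lc <- count_loci(aln)
write.table(lc, file.path(outdir, "locus_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Hits:", nrow(aln$hits), " repeat-flagged tags:",
    length(aln$repeat_tags), "\n")
print(table(cats$category))
cat("Tags mapping to >= 2 loci:", sum(lc$n_loci >= 2 & !lc$repeat_flag),
    "\n")
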