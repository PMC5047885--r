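#!/usr/bin/env Rscript
# Step 2: collinear block detection. Reads the simulated genomes back
# from disk (exercising the GFF3/FASTA/hit-table readers), detects
# significant collinear blocks between outgroup and polyploid (gap <= 50
# gene ranks, permutation P < 0.05, >= 5 anchors), and writes the
# block-size census plus a gene-rank dot-plot.

source("analysis/00_common.R")

res <- pipeline_cached()

cen <- res$census
cat("block census (counts above each block-length threshold):\n")
print(cen)
cat(sprintf("largest block: %d anchor pairs on %s x %s\n",
            attr(cen, "largest_block_length"),
            attr(cen, "largest_block_chroms")[1],
            attr(cen, "largest_block_chroms")[2]))

panel_a <- read_annotations(file.path(SIM_DIR, "genome_A.gff3"), "A")
panel_b <- read_annotations(file.path(SIM_DIR, "genome_B.gff3"), "B")
hits <- read_hits(file.path(SIM_DIR, "hits.tsv"))
gp <- render_dotplot(hits, panel_a, panel_b)
ggplot2::ggsave("results/dotplot.pdf", gp, width = 7, height = 6)
cat("wrote results/run/blocks.tsv, results/run/census.tsv, results/dotplot.pdf\n")
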