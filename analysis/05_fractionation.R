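#!/usr/bin/env Rscript
# Step 5: fractionation census. For every outgroup gene, how many of
# the two expected duplicate copies survive in collinear position in
# the polyploid, and -- for genes absent from both expected locations --
# whether a protein-level hit elsewhere marks them as translocated
# rather than truly lost (bidirectional best hits flagged separately).

source("analysis/00_common.R")

res <- pipeline_cached()

s <- res$fractionation$summary
cat(sprintf("census over %d outgroup genes:\n", s$total))
for (cl in names(s$counts)) {
  cat(sprintf("  %-12s %4d (%.2f%%)\n", cl, s$counts[[cl]],
              100 * s$proportions[[cl]]))
}
tri <- res$fractionation$triage
cat(sprintf("absent-gene triage: %d with hits (translocated, %d of them BBH), %d without (candidate losses)\n",
            tri[["translocated_hit"]], tri[["translocated_bbh"]],
            tri[["no_hit"]]))
cat("wrote results/run/retention.tsv\n")
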