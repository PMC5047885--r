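# in-code fixtures shared across test files

# quick panel: chrom_sizes is a named integer vector; gene ids are
# <species>_<chrom>_g<i>, laid out 1000 bp apart
toy_panel <- function(species, chrom_sizes, cds = NULL) {
  rows <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    start <- (seq_len(n) - 1L) * 1000L + 1L
    data.frame(id = sprintf("%s_%s_g%d", species, ch, seq_len(n)),
               chrom = ch, start = start, end = start + 299L,
               strand = "+", stringsAsFactors = FALSE)
  })
  genome_panel(species, do.call(rbind, rows), cds = cds)
}

# hit rows in the 12-column dialect
toy_hits <- function(query, subject, evalue = 1e-50,
                     bitscore = 500, pident = 90) {
  n <- max(length(query), length(subject))
  data.frame(query = rep_len(query, n), subject = rep_len(subject, n),
             pident = rep_len(pident, n), length = rep_len(300L, n),
             mismatch = rep_len(0L, n), gapopen = rep_len(0L, n),
             qstart = rep_len(1L, n), qend = rep_len(300L, n),
             sstart = rep_len(1L, n), send = rep_len(300L, n),
             evalue = rep_len(evalue, n),
             bitscore = rep_len(bitscore, n), stringsAsFactors = FALSE)
}

# a bare collinear block without running detection
toy_block <- function(chrom_a, chrom_b, genes_a, genes_b,
                      orientation = "same", p_value = 0.001) {
  n <- length(genes_a)
  structure(list(chrom_a = chrom_a, chrom_b = chrom_b,
                 pairs = data.frame(gene_a = genes_a, gene_b = genes_b,
                                    order_a = seq_len(n) - 1L,
                                    order_b = seq_len(n) - 1L,
                                    stringsAsFactors = FALSE),
                 orientation = orientation, length = n,
                 p_value = p_value),
            class = "collinear_block")
}

toy_classification <- function(block, label, ks_median = 1.0) {
  structure(list(block = block, ks_median = ks_median, label = label,
                 evidence = "fixture"),
            class = "block_classification")
}

# correspondence map literal
toy_map <- function(...) {
  structure(list(...), class = "correspondence_map")
}
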