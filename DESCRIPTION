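Package: protochrom
Title: Proto-Chromosome Inference from Gene Collinearity Between a
    Polyploid Lineage and an Unduplicated Outgroup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics inference chain for resolving ancestral
    chromosome numbers across a whole-genome duplication: detection of
    statistically significant collinear gene blocks by sparse dynamic
    programming with a permutation null, Nei-Gojobori synonymous
    substitution (Ks) dating of anchor pairs, classification of blocks
    into orthologs and out-paralogs from block Ks medians and shared
    collinear genes, a formal fusion-versus-fission test on chromosome
    trios with ancestral karyotype inference, and a post-polyploidy
    fractionation census with a translocated-versus-lost triage. Includes
    a forward genome-evolution simulator (tetraploidization, end-end
    chromosome fusions, fissions, biased gene loss, translocation,
    inversion, clock-like synonymous divergence) that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    jsonlite,
    methods,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
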