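---
title: "Inferring proto-chromosomes across a tetraploidization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring proto-chromosomes across a tetraploidization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a lineage doubles its genome and the duplicated chromosomes are later
rearranged, the ancestral (basic) chromosome number can no longer be read
off the extant karyotype. Two histories can produce the same modern count:
an ancestral chromosome may have *split* (fission) or two ancestral
chromosomes may have *fused* after the duplication. The two histories are
distinguishable with an outgroup that never duplicated: under fission, the
two smaller chromosomes descend from one ancestral chromosome and therefore
share their outgroup correspondence; under fusion they descend from two
independent ancestral chromosomes and their outgroup correspondences are
disjoint.

`protochrom` implements that argument as a testable chain of inferences
between a polyploid genome ("subject", lineage B) and an unduplicated
outgroup ("query", lineage A):

1. **Collinear blocks** — runs of homologous gene pairs preserving gene
   order — are detected from an all-vs-all homology table.
2. Every anchor pair is dated by its **synonymous substitution rate (Ks)**
   using the Nei–Gojobori counting method.
3. Blocks are layered into **orthologs** (from the speciation) and
   **out-paralogs** (from older duplications) using block Ks medians, with
   a shared-collinear-gene tie-break for ambiguous cases.
4. Orthologous blocks build a **chromosome correspondence map**, on which
   the **fusion-vs-fission trio test** runs and the ancestral count is
   inferred.
5. A **fractionation census** classifies every query gene by how many of
   its expected duplicate copies survive in collinear position, and
   triages the absent ones into translocated versus lost using
   protein-level hits and reciprocal best hits.

Every stage is validated against a built-in forward simulator that carries
full ground truth.

## Collinearity model

Anchors are homology hits that survive the standard filter (E-value
≤ 1e-5, at most five subjects per query by bitscore; ties broken by
subject id, which the hit format leaves unspecified). Plotted in
gene-rank coordinates, collinear segments appear as monotone runs of
dots. A block is a maximal chain of dots, strictly monotone on both
genomes (increasing, or decreasing for inverted segments), in which
consecutive anchors skip at most `max_gap = 50` gene ranks on *each*
genome. Chains are found by sparse dynamic programming (quadratic in the
anchors of a chromosome pair, implemented in C++) and extracted greedily
by descending length, so each anchor belongs to at most one block —
overlapping chains lose their shared anchors to the longer chain.

Significance is a permutation test: the chromosome pair's anchor count is
re-placed uniformly at random on the two chromosomes' gene ranks and the
longest chain recorded, `permutations = 1000` times (seeded; the P-value
uses the `(hits + 1)/(N + 1)` smoothing). A block is kept when
`p < 0.05` and it has at least `min_len = 5` anchors. The permutation
null was chosen over an analytic model because it is assumption-light
and exactly reproducible; it also makes the honest point that a short
diagonal among few anchors on a large chromosome pair is weak evidence
(three random dots are monotone about a third of the time).

## Ks estimation

Anchor CDS pairs are aligned at the protein level (global alignment,
match +1, mismatch −1, linear gap −2 per residue — plain identity
scoring is adequate at the divergences involved) and back-translated to
codon columns; columns with a gap, an ambiguous base, or a stop codon
are excluded from counting.

The Nei–Gojobori estimator then counts, per codon, the expected
synonymous sites (the fraction of one-step changes at each position that
preserve the amino acid, with changes to stop codons excluded from the
denominator, so S + N = 3 × codons always) and, per differing codon
pair, the synonymous/nonsynonymous difference split averaged over all
minimal mutational pathways with equal weight; pathways through stop
codons are excluded (if every pathway is blocked, all are used).
Multiple hits are corrected with the Jukes–Cantor transform
`ks = −(3/4)·log(1 − (4/3)·pS)`; `pS ≥ 3/4` is reported as *saturated*
(`NA`) rather than an error. All 64 × 64 codon-pair counts are
precomputed once, so dating thousands of pairs is cheap. The counting
core is verified, term by term, against an independent brute-force
pathway enumerator in the test suite.

A block's date is the **median** Ks over its non-saturated anchor pairs
(even counts average the central two). Medians resist both saturation
censoring and the long upper tail that the Jukes–Cantor transform gives
individual pairs near saturation. Ks is computed for *all* anchor pairs
and saturated values are filtered afterwards, so the censoring is always
visible in the output.

## Orthology layering

Between an unduplicated outgroup and a once-doubled subject, each query
region has up to two orthologous subject copies and possibly deeper
out-paralogous copies from older events. Classification windows:

* orthologous: block Ks median in **[0.95, 1.20]** — the speciation-age
  window;
* out-paralogous: within **1.5 ± 0.15** — the older-event zone. The
  center is a property of the data being emulated; the half-width is
  this package's choice (no natural width exists) and is configurable;
* anything else: ambiguous.

When Ks medians cannot separate candidates (windows overlap within
noise), the tie-break is *shared collinear genes*: for candidate subject
chromosomes X and Y against one query chromosome, `share(X, Y)` is the
fraction of X's collinear query genes that also anchor to Y. WGD
co-orthologs cover the same ancestral segment and share heavily; an
out-paralog's collinear complement is sparse and largely disjoint
because old duplication layers are heavily fractionated. A candidate
pair sharing above `share_threshold = 0.20` in both directions is
declared co-orthologous; a candidate below it with all others is
out-paralogous. The default threshold sits far from both observed
regimes (tens of percent for co-orthologs, a few percent for
out-paralogs). Reported percentages are rounded half-up to one decimal.

The correspondence map then records, per subject chromosome, the query
chromosomes contributing at least `min_anchor = 10` orthologous anchors
— a floor that keeps scraps of noise out of the karyotype argument.

## The trio test

For a trio (merged chromosome P1; parts P2, P3), with `corr(c)` the set
of query chromosomes orthologously corresponding to subject chromosome
`c`:

* `jaccard_parts = |corr(P2) ∩ corr(P3)| / |corr(P2) ∪ corr(P3)|`
* `coverage` = fraction of `corr(P1)` covered by `corr(P2) ∪ corr(P3)`

Verdict **fusion** when the parts are independent
(`jaccard_parts ≤ 0.10`) and tile the merged chromosome
(`coverage ≥ 0.80`); **fission** when the parts overlap
(`jaccard > 0.10`) and correspond only to ancestral material also
carried by the merged chromosome; otherwise **undetermined**, with the
reason reported. The thresholds quantify what a dot-plot argument makes
qualitatively ("perfect independent correspondence"); both are
configurable and are printed with every verdict. Restricting the map to
blocks labeled orthologous is what shields the test from older
duplication layers in the outgroup.

Ancestral counts follow by event algebra: each fusion adds one
chromosome back, each fission removes one, and the post-duplication
count halves across the tetraploidization:
`x = (n_observed + fusions − fissions) / 2`. Twelve observed
chromosomes with two fusion verdicts give x = 7, hence 2n = 14 before
and 2n = 28 after the event. Undetermined trios propagate as an
interval, never silently as a point estimate.

For fusion verdicts, the junction is localized by ordering the merged
chromosome's orthologous anchors and finding the change point(s)
minimizing source-label mismatches; ties are all reported (an
interleaved merged chromosome is evidence against a single clean
end–end joining).

## Fractionation census

Per query gene, the census counts distinct subject copies anchored
through orthologous blocks: ≥ 2 → `both_copies`, 1 → `one_copy`,
0 → `absent`. "Expected location" is thus operationalized as membership
in an orthologous collinear block; a window-based relaxation was
considered and rejected as redundant given the gap tolerance already in
the chain definition. The denominator (all query genes considered) is
always printed with the proportions. Absent genes with any
protein-level hit at E ≤ 1e-10 are `translocated_hit`; those that are
reciprocal best hits (bitscore-ranked, ties by E-value then subject id)
are `translocated_bbh`; the rest are `no_hit` — the candidate true
losses. A missing hit table yields `untriaged`, never a spurious
`no_hit`.

## The simulator

`simulate_genomes()` builds a random ancestor (`x` chromosomes ×
`genes_per_chromosome` genes) and evolves two lineages: A unduplicated;
B optionally tetraploidized, then fissioned/fused (end–end joining
drops `cej_trim = 2` genes from each joined end — the "tiny part" a
telomeric crossover loses), thinned by per-copy gene loss (before or
after the subgenome merge, emulating allopolyploid versus
post-polyploid loss timing), translocated and inverted. The homology
table is emitted from true ancestry with bitscores decreasing in tree
distance, so hit ranking behaves like a search result without the cost
of one; optional decoy rows add noise.

Sequence divergence is a synonymous clock made *exactly* Jukes–Cantor
by construction: simulated CDS use only fourfold-degenerate codon
families ({GC, GG, CC, AC, GT, TC}-prefixed codons), synonymous events
hit third positions as a Poisson process calibrated so the expected
substitutions per synonymous site equal the configured `ks`, and
nonsynonymous events switch codon-family prefixes one step within the
set (always nonsynonymous, never creating stops or leaving the fourfold
set). Because every third position is a full synonymous site under the
estimator's site counting, the configured `ks_split` is the exact
Nei–Gojobori expectation — parameter-recovery tests measure estimator
behavior, not generator bias. Branch lengths place A–B ortholog pairs
at `ks_split` (default 1.05, the center of the orthology window),
subgenome pairs at `ks_wgd` (default 0.9), and ancient-duplicate pairs
at `ks_ancient` (default 1.5). The ancient layer is fractionated at
`ancient_loss_rate = 0.9`, which reproduces the few-percent
shared-collinear-gene signal that old duplication layers show against
recent co-orthologs.

Every random draw is recorded in an event log; `replay_log()` re-applies
the log deterministically and reproduces panels, CDS and hit table
exactly — the conservation and determinism invariants are tested.

What the generator deliberately does **not** emulate: intergenic
sequence and transposons, tandem arrays, codon-usage bias, rate
variation among genes and sites, gene conversion between subgenomes,
biased subgenome dominance, and alignment/annotation error (hits derive
from true ancestry). Passing tests therefore certify the inference
chain given correct homology input at realistic divergences, not
robustness to annotation noise; the `decoy_rate` knob probes only the
crudest form of spurious hits.

## Scenario presets and study sizes

`scenario_presets()` fixes the canonical configurations: `fission_A`
(one ancestral chromosome, one post-WGD copy splits), `fission_B` (as A
plus an independent outgroup fission at a different breakpoint),
`fusion_C` (two ancestral chromosomes, one duplicated set joins), and
`grass_like` (x = 7, WGD, two CEJ fusions taking 14 chromosomes to 12,
40% per-copy loss before the merge, 2% translocation, 0.2
inversions/chromosome). Preset sizes (60–140 genes per chromosome,
100-codon genes) keep every chromosome segment above ~30 orthologous
anchors after loss — enough that verdict recovery measures the method,
not sampling starvation — while a full recovery study (40 replicates
per scenario) runs on a single CPU in minutes. The acceptance script
uses 20 replicates per scenario and the test suite 40; both sizes are
the package's own choice of study design.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive bp in files, 0-based gene ranks
  internally; all gaps and junctions are measured in gene ranks.
* Anchor ranking key (bitscore, then subject id) and BBH tie-breaks
  (bitscore, E-value, subject id) are fixed so outputs are
  deterministic; reruns with the same seed are byte-identical, and the
  run manifest records every parameter.
* Empty inputs produce empty, well-formed outputs (empty hit table →
  zero blocks, all-absent census, empty map), not errors.
* A block whose anchor pairs are all Ks-saturated is classified
  ambiguous with the reason recorded.
* `infer_ancestral_count()` warns when the event algebra yields a
  non-integer basic number — a sign the verdicts are inconsistent with
  a single tetraploidization.
* Within-genome runs drop self-hits and mirrored duplicate anchors
  (keeping one side of the diagonal); within-tandem hit removal exists
  behind a flag and is off by default.
* The homology table is standardized on gene-vs-gene hits throughout
  (dot-plot and collinearity stages share one input), rather than mixing
  gene-vs-genome and gene-vs-gene searches.

## Known limitations

* The trio test needs its trios named; it does not search chromosome
  triples exhaustively.
* Correspondence is set-valued per chromosome; segment-level ancestral
  reconstruction (contiguous ancestral regions) is out of scope.
* The Ks windows are calibrated for a speciation near Ks ≈ 1; much
  younger or older splits need re-centered windows (all are arguments).
* The Nei–Gojobori estimator is the counting method by design; no
  maximum-likelihood (GY94-style) alternative is provided.
* With loss timed *after* the merge, junction gene-rank truth shifts
  relative to the fusion-time record; junction assessments in the tests
  use before-merge loss.
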