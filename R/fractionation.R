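## Post-polyploidy fractionation census: for every gene of the
## unduplicated query genome, how many of the two expected duplicate
## copies survive in collinear (orthologous-block) position in the
## polyploid subject genome, and, for genes absent from both expected
## locations, whether a protein-level hit elsewhere marks them as
## translocated rather than lost.

#' Duplicate-retention census of the query genome
#'
#' A query gene is `both_copies` if it anchors orthologous collinear
#' blocks to at least `expected_depth` distinct subject copies of its
#' region, `one_copy` if to exactly one, `absent` otherwise ("expected
#' location" is operationalized as membership in an orthologous
#' collinear block). Genes on unplaced scaffolds (chromosome name
#' matching `unplaced_pattern`) stay in the denominator but are flagged.
#'
#' @param query_panel Query-side `genome_panel`.
#' @param classifications List of `block_classification`; only
#'   orthologous blocks count.
#' @param expected_depth Expected duplicate copies (default 2).
#' @param query_side Which block side is the query genome.
#' @param unplaced_pattern Regex flagging unplaced sequences.
#' @return Object of class `fractionation_census`: `records` (data frame
#'   `gene`, `depth`, `class`, `unplaced`) and `summary` (totals and
#'   proportions; proportions sum to 1).
#' @export
retention_census <- function(query_panel, classifications,
                             expected_depth = 2L,
                             query_side = c("a", "b"),
                             unplaced_pattern = "^(scaffold|ctg|un)") {
  query_side <- match.arg(query_side)
  dc <- depth_check(classifications, query_panel,
                    expected_depth = expected_depth,
                    query_side = query_side)
  depth <- dc$depth
  cls <- ifelse(depth >= expected_depth, "both_copies",
                ifelse(depth == 1L, "one_copy", "absent"))
  records <- data.frame(
    gene = names(depth), depth = as.integer(depth), class = cls,
    subclass = NA_character_,
    unplaced = grepl(unplaced_pattern, query_panel$genes$chrom,
                     ignore.case = TRUE)[match(names(depth),
                                               query_panel$genes$id)],
    stringsAsFactors = FALSE)
  total <- nrow(records)
  counts <- c(both_copies = sum(cls == "both_copies"),
              one_copy = sum(cls == "one_copy"),
              absent = sum(cls == "absent"))
  props <- if (total > 0L) counts / total else counts * NA_real_
  structure(list(records = records,
                 summary = list(total = total, counts = counts,
                                proportions = props,
                                denominator = total)),
            class = "fractionation_census")
}

#' @export
print.fractionation_census <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<fractionation_census> %d query genes: both %.2f%%, one %.2f%%, absent %.2f%%\n",
              s$total, 100 * s$proportions[["both_copies"]],
              100 * s$proportions[["one_copy"]],
              100 * s$proportions[["absent"]]))
  invisible(x)
}

# best subject per query by bitscore desc, ties by evalue asc then
# subject id
best_hit <- function(hits, from = "query", to = "subject") {
  if (!nrow(hits)) return(setNames(character(), character()))
  ord <- order(hits[[from]], -hits$bitscore, hits$evalue, hits[[to]])
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h[[from]])
  setNames(h[[to]][first], h[[from]][first])
}

#' Triage absent query genes into translocated versus lost
#'
#' Absent genes with any subject-genome hit at
#' `evalue <= evalue_max` are `translocated_hit`; among those, reciprocal
#' (bidirectional) best hits are upgraded to `translocated_bbh`;
#' the remainder are `no_hit`, the candidate true losses. Best hits are
#' ranked by bitscore with ties broken by evalue then subject id. When
#' no hit table is supplied, absent genes are reported `untriaged`.
#'
#' @param census A `fractionation_census` ([retention_census()]).
#' @param protein_hits Protein-level hit table in the 12-column dialect
#'   (query-genome genes as queries), or `NULL`. Hits in both directions
#'   may be included; reciprocity is evaluated on the table itself.
#' @param evalue_max E-value cutoff (default `1e-10`).
#' @return The census with `records$subclass` filled for absent genes
#'   and a `triage` element: counts of `translocated_hit` (including
#'   BBH), `translocated_bbh`, `no_hit`, `untriaged`.
#' @export
absent_gene_triage <- function(census, protein_hits, evalue_max = 1e-10) {
  stopifnot(inherits(census, "fractionation_census"))
  rec <- census$records
  absent <- rec$gene[rec$class == "absent"]
  if (is.null(protein_hits)) {
    rec$subclass[rec$class == "absent"] <- "untriaged"
    census$records <- rec
    census$triage <- c(translocated_hit = 0L, translocated_bbh = 0L,
                       no_hit = 0L, untriaged = length(absent))
    return(census)
  }
  h <- protein_hits[protein_hits$evalue <= evalue_max &
                      protein_hits$query != protein_hits$subject, ,
                    drop = FALSE]
  fwd <- best_hit(h, "query", "subject")
  rev <- best_hit(h, "subject", "query")
  has_hit <- absent %in% h$query
  bbh <- vapply(absent, function(g) {
    b <- fwd[g]
    !is.na(b) && !is.na(rev[b]) && rev[b] == g
  }, logical(1))
  sub <- ifelse(bbh, "translocated_bbh",
                ifelse(has_hit, "translocated_hit", "no_hit"))
  rec$subclass[match(absent, rec$gene)] <- sub
  census$records <- rec
  census$triage <- c(
    translocated_hit = sum(has_hit),
    translocated_bbh = sum(bbh),
    no_hit = sum(!has_hit),
    untriaged = 0L)
  census
}
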