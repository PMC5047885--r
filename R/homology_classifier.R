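## Separating orthologous from out-paralogous collinear blocks. Between an
## unduplicated outgroup and a lineage that underwent one tetraploidization
## after the split, every outgroup region has up to two orthologous copies
## (the WGD subgenomes, Ks near the speciation value) and possibly deeper
## out-paralogous copies from more ancient events (larger Ks). Block Ks
## medians do most of the work; near-ties are resolved by how many
## collinear genes competing subject chromosomes share on the query
## chromosome: WGD co-orthologs cover the same ancestral segment and so
## share many query genes, out-paralogs share few.

# round half-up to one decimal, for reported percentages
pct1 <- function(x) floor(x * 1000 + 0.5) / 10

#' Classify a block by its Ks median
#'
#' Blocks whose median falls inside the orthology window are orthologous;
#' within `margin` of the out-paralogy center they are out-paralogous;
#' anything else is ambiguous.
#'
#' @param block A `collinear_block`.
#' @param ks_median Finite block Ks median ([block_ks_median()]).
#' @param ortho_window Ks window for speciation-age orthologs
#'   (default `c(0.95, 1.20)`).
#' @param outpara_center,margin Out-paralogy zone `center +/- margin`
#'   (defaults 1.5 and 0.15).
#' @return Object of class `block_classification`: `block`, `ks_median`,
#'   `label` (`"orthologous"`, `"outparalogous"`, `"ambiguous"`) and an
#'   `evidence` string naming the rule that fired.
#' @export
classify_by_ks <- function(block, ks_median, ortho_window = c(0.95, 1.20),
                           outpara_center = 1.5, margin = 0.15) {
  if (length(ortho_window) != 2L || ortho_window[1] > ortho_window[2]) {
    stop("ortho_window must be an increasing interval")
  }
  if (!is.finite(ks_median)) stop("ks_median must be finite")
  if (ks_median >= ortho_window[1] && ks_median <= ortho_window[2]) {
    label <- "orthologous"
    evidence <- sprintf("ks_median %.3f in orthology window [%.2f, %.2f]",
                        ks_median, ortho_window[1], ortho_window[2])
  } else if (abs(ks_median - outpara_center) <= margin) {
    label <- "outparalogous"
    evidence <- sprintf("ks_median %.3f within %.2f of out-paralogy center %.2f",
                        ks_median, margin, outpara_center)
  } else {
    label <- "ambiguous"
    evidence <- sprintf("ks_median %.3f outside both zones", ks_median)
  }
  structure(list(block = block, ks_median = ks_median, label = label,
                 evidence = evidence),
            class = "block_classification")
}

#' @export
print.block_classification <- function(x, ...) {
  cat(sprintf("<block_classification> %s x %s: %s (ks_median %.3f)\n",
              x$block$chrom_a, x$block$chrom_b, x$label, x$ks_median))
  invisible(x)
}

# query-gene anchor sets per candidate subject chromosome, from blocks
# touching the query chromosome
anchor_sets <- function(query_chrom, candidates, blocks,
                        query_side = c("a", "b")) {
  query_side <- match.arg(query_side)
  qc <- if (query_side == "a") "chrom_a" else "chrom_b"
  sc <- if (query_side == "a") "chrom_b" else "chrom_a"
  qg <- if (query_side == "a") "gene_a" else "gene_b"
  sets <- lapply(candidates, function(cand) {
    genes <- unlist(lapply(blocks, function(b) {
      if (b[[qc]] == query_chrom && b[[sc]] == cand) b$pairs[[qg]]
      else character()
    }))
    unique(genes)
  })
  names(sets) <- candidates
  sets
}

#' Resolve competing subject chromosomes by shared collinear genes
#'
#' When two or more subject chromosomes have similar Ks medians against
#' one query chromosome, the WGD co-ortholog pair is recognized by mutual
#' sharing: for candidates X and Y, `share(X, Y)` is the fraction of X's
#' collinear query genes that also anchor to Y. A candidate pair whose
#' sharing exceeds `share_threshold` in both directions are co-orthologs
#' (WGD duplicates covering the same ancestral segment); a candidate
#' sharing below the threshold with every other is out-paralogous.
#'
#' @param query_chrom Query chromosome name.
#' @param candidates Two or more subject chromosome names.
#' @param blocks List of `collinear_block` (any labels).
#' @param share_threshold Mutual-sharing cutoff (default 0.20).
#' @param query_side Which block side carries the query chromosome.
#' @return Data frame ranked by anchor count: `chrom`, `n_anchors`,
#'   `label`, `best_partner`, `best_share_pct` (half-up, one decimal).
#'   The pairwise share matrix is attached as attribute `"share"`.
#' @export
resolve_by_sharing <- function(query_chrom, candidates, blocks,
                               share_threshold = 0.20,
                               query_side = c("a", "b")) {
  query_side <- match.arg(query_side)
  if (length(candidates) < 2L) stop("need at least two candidates")
  sets <- anchor_sets(query_chrom, candidates, blocks, query_side)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    warning("candidate(s) with zero anchors excluded: ",
            paste(empty, collapse = ", "))
    sets <- sets[lengths(sets) > 0L]
  }
  cand <- names(sets)
  k <- length(cand)
  share <- matrix(NA_real_, k, k, dimnames = list(cand, cand))
  for (x in cand) for (y in cand) {
    if (x != y) share[x, y] <- length(intersect(sets[[x]], sets[[y]])) /
        length(sets[[x]])
  }
  mutual <- share >= share_threshold & t(share) >= share_threshold
  mutual[is.na(mutual)] <- FALSE
  label <- setNames(rep("outparalogous", k), cand)
  label[rowSums(mutual) > 0L] <- "orthologous"
  best_partner <- vapply(cand, function(x) {
    others <- setdiff(cand, x)
    if (!length(others)) return(NA_character_)
    others[which.max(share[x, others])]
  }, character(1))
  best_share <- vapply(cand, function(x) {
    if (is.na(best_partner[[x]])) return(NA_real_)
    share[x, best_partner[[x]]]
  }, numeric(1))
  out <- data.frame(chrom = cand,
                    n_anchors = lengths(sets)[cand],
                    label = label[cand],
                    best_partner = best_partner[cand],
                    best_share_pct = pct1(best_share[cand]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_anchors), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "share") <- share
  out
}

#' Build a chromosome correspondence map from classified blocks
#'
#' Per subject chromosome, the set of query chromosomes contributing at
#' least `min_anchor` orthologous anchor pairs (summed over blocks).
#'
#' @param classifications List of `block_classification`.
#' @param min_anchor Minimum summed orthologous anchors (default 10).
#' @param subject_side Which block side is the subject genome
#'   (default `"b"`).
#' @return Object of class `correspondence_map`: a named list mapping
#'   each subject chromosome to a named integer vector of anchor counts
#'   per corresponding query chromosome.
#' @export
build_correspondence <- function(classifications, min_anchor = 10L,
                                 subject_side = c("b", "a")) {
  subject_side <- match.arg(subject_side)
  sc <- if (subject_side == "b") "chrom_b" else "chrom_a"
  qc <- if (subject_side == "b") "chrom_a" else "chrom_b"
  ortho <- Filter(function(cl) cl$label == "orthologous", classifications)
  counts <- list()
  for (cl in ortho) {
    s <- cl$block[[sc]]; q <- cl$block[[qc]]
    if (is.null(counts[[s]])) counts[[s]] <- integer()
    counts[[s]][q] <- (if (is.na(counts[[s]][q])) 0L
                       else counts[[s]][q]) + cl$block$length
  }
  if (!length(counts)) {
    return(structure(list(), class = "correspondence_map"))
  }
  map <- lapply(counts, function(v) {
    v <- v[v >= min_anchor]
    v[order(names(v))]
  })
  map <- map[order(names(map))]
  map <- Filter(length, map)
  structure(map, class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  if (!length(x)) { cat("<correspondence_map> empty\n"); return(invisible(x)) }
  for (s in names(x)) {
    cat(sprintf("%s -> %s\n", s,
                paste(sprintf("%s(%d)", names(x[[s]]), x[[s]]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Orthology depth per query gene
#'
#' Counts, for every query gene, the number of distinct subject copies it
#' anchors through orthologous blocks, and compares the depth histogram
#' with the expected orthology ratio (here 1 query : `expected_depth`
#' subject copies). Depths above the expectation are flagged.
#'
#' @param classifications List of `block_classification` (only
#'   orthologous blocks are used).
#' @param query_panel Query-side `genome_panel`.
#' @param expected_depth Expected subject copies per query gene
#'   (default 2, the post-tetraploidization ratio).
#' @param query_side Which block side is the query genome.
#' @return List with `depth` (named integer per query gene), `histogram`
#'   (counts at depth 0, 1, ..., `>expected`), and `over_expected`
#'   (gene ids exceeding the expectation).
#' @export
depth_check <- function(classifications, query_panel, expected_depth = 2L,
                        query_side = c("a", "b")) {
  query_side <- match.arg(query_side)
  qg <- if (query_side == "a") "gene_a" else "gene_b"
  sg <- if (query_side == "a") "gene_b" else "gene_a"
  ortho <- Filter(function(cl) cl$label == "orthologous", classifications)
  pairs <- do.call(rbind, lapply(ortho, function(cl) {
    data.frame(q = cl$block$pairs[[qg]], s = cl$block$pairs[[sg]],
               stringsAsFactors = FALSE)
  }))
  depth <- setNames(integer(nrow(query_panel$genes)), query_panel$genes$id)
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[!duplicated(paste(pairs$q, pairs$s, sep = "\r")), ,
                   drop = FALSE]
    tab <- table(pairs$q)
    depth[names(tab)] <- as.integer(tab)
  }
  levels <- c(as.character(0:expected_depth),
              paste0(">", expected_depth))
  hist <- setNames(integer(length(levels)), levels)
  capped <- ifelse(depth > expected_depth, paste0(">", expected_depth),
                   as.character(depth))
  tab <- table(capped)
  hist[names(tab)] <- as.integer(tab)
  list(depth = depth, histogram = hist,
       over_expected = names(depth)[depth > expected_depth])
}
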