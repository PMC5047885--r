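## ColinearScan-style collinear block detection: anchors (homologous gene
## pairs) are dots on a gene-rank dot-plot; blocks are maximal monotone
## chains found by sparse dynamic programming, with both order-index gaps
## bounded by max_gap, extracted greedily by descending chain length, and
## tested against a seeded permutation null.

# Map a hit table onto gene-rank anchor dots per chromosome pair. For a
# within-genome run (panel_a identical to panel_b) self pairs are dropped
# and unordered pairs are kept once (order_a < order_b side of the
# diagonal), which also removes the trivial self-diagonal.
anchor_dots <- function(hits, panel_a, panel_b) {
  ga <- panel_a$genes; gb <- panel_b$genes
  ia <- match(hits$query, ga$id)
  ib <- match(hits$subject, gb$id)
  ok <- !is.na(ia) & !is.na(ib)
  dots <- data.frame(gene_a = hits$query[ok], gene_b = hits$subject[ok],
                     chrom_a = ga$chrom[ia[ok]], chrom_b = gb$chrom[ib[ok]],
                     order_a = ga$order_index[ia[ok]],
                     order_b = gb$order_index[ib[ok]],
                     stringsAsFactors = FALSE)
  same_genome <- identical(panel_a$species, panel_b$species)
  if (same_genome) {
    dots <- dots[dots$gene_a != dots$gene_b, , drop = FALSE]
    flip <- (dots$chrom_a > dots$chrom_b) |
      (dots$chrom_a == dots$chrom_b & dots$order_a > dots$order_b)
    dots[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                 "order_a", "order_b")] <-
      dots[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a",
                   "order_b", "order_a")]
  }
  dots <- dots[!duplicated(paste(dots$gene_a, dots$gene_b, sep = "\r")), ,
               drop = FALSE]
  rownames(dots) <- NULL
  dots
}

best_chain <- function(oa, ob, max_gap) {
  ord <- order(oa, ob)
  res_s <- chain_dp_cpp(oa[ord], ob[ord], max_gap, FALSE)
  res_i <- chain_dp_cpp(oa[ord], ob[ord], max_gap, TRUE)
  pick <- function(res, inverted) {
    i <- which.max(res$score)
    chain <- integer()
    while (i > 0L) { chain <- c(i, chain); i <- res$prev[i] }
    list(idx = ord[chain], len = length(chain), inverted = inverted)
  }
  s <- pick(res_s, FALSE); v <- pick(res_i, TRUE)
  if (v$len > s$len) v else s
}

#' Detect collinear gene blocks between two panels
#'
#' For each chromosome pair with anchors, maximal-length monotone chains
#' (same or inverted orientation, both gene-rank gaps `<= max_gap`) are
#' extracted greedily by descending chain length; each anchor belongs to
#' at most one block. Block significance is a permutation P-value (see
#' [block_significance()]) computed from a shared null per chromosome
#' pair; blocks with `p_value >= p_threshold` or fewer than `min_len`
#' anchor pairs are discarded. Within-genome runs (same panel twice)
#' exclude the trivial self-diagonal.
#'
#' @param hits Filtered hit table ([read_hits()]/[filter_hits()]).
#' @param panel_a,panel_b Genome panels (query and subject side).
#' @param max_gap Maximum intervening gene ranks between consecutive
#'   anchors, enforced on both genomes (default 50).
#' @param p_threshold Significance cutoff (default 0.05).
#' @param min_len Minimum anchor pairs per block (default 5).
#' @param permutations Permutations for the null (default 1000).
#' @param seed Optional integer seed for the permutation null.
#' @return List of `collinear_block` objects: `chrom_a`, `chrom_b`,
#'   `pairs` (anchor data frame ordered along genome A), `orientation`
#'   (`"same"`/`"inverted"`), `length`, `p_value`.
#' @export
detect_blocks <- function(hits, panel_a, panel_b, max_gap = 50L,
                          p_threshold = 0.05, min_len = 5L,
                          permutations = 1000L, seed = NULL) {
  if (max_gap < 1L) stop("max_gap must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dots <- anchor_dots(hits, panel_a, panel_b)
  if (nrow(dots) == 0L) return(list())
  len_a <- chromosome_lengths(panel_a)
  len_b <- chromosome_lengths(panel_b)
  blocks <- list()
  for (key in unique(paste(dots$chrom_a, dots$chrom_b, sep = "\r"))) {
    d <- dots[paste(dots$chrom_a, dots$chrom_b, sep = "\r") == key, ,
              drop = FALSE]
    n_pair_anchors <- nrow(d)
    chrom_a <- d$chrom_a[1]; chrom_b <- d$chrom_b[1]
    null_max <- NULL
    repeat {
      if (nrow(d) < min_len) break
      ch <- best_chain(d$order_a, d$order_b, max_gap)
      if (ch$len < min_len) break
      if (is.null(null_max)) {
        null_max <- chain_null_cpp(n_pair_anchors, len_a[[chrom_a]],
                                   len_b[[chrom_b]], permutations, max_gap)
      }
      pairs <- d[ch$idx, , drop = FALSE]
      pairs <- pairs[order(pairs$order_a), , drop = FALSE]
      rownames(pairs) <- NULL
      p <- (sum(null_max >= ch$len) + 1) / (length(null_max) + 1)
      blocks[[length(blocks) + 1L]] <- structure(
        list(chrom_a = chrom_a, chrom_b = chrom_b,
             pairs = pairs[, c("gene_a", "gene_b", "order_a", "order_b")],
             orientation = if (ch$inverted) "inverted" else "same",
             length = ch$len, p_value = p),
        class = "collinear_block")
      d <- d[-ch$idx, , drop = FALSE]
    }
  }
  keep <- vapply(blocks, function(b) b$p_value < p_threshold, logical(1))
  blocks[keep]
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("<collinear_block> %s x %s: %d pairs, %s, p=%.4g\n",
              x$chrom_a, x$chrom_b, x$length, x$orientation, x$p_value))
  invisible(x)
}

#' Permutation P-value of a collinear block
#'
#' Places the chromosome pair's anchor count uniformly at random on the
#' two chromosomes' gene ranks and records the longest max-gap-bounded
#' monotone chain; the P-value is the smoothed fraction
#' `(hits + 1) / (permutations + 1)` of permutations whose longest chain
#' reaches the observed block length. Deterministic given `seed`.
#'
#' @param block A `collinear_block` (or its length as an integer).
#' @param n_anchors Anchor count on the chromosome pair.
#' @param chrom_len_a,chrom_len_b Chromosome lengths in genes.
#' @param permutations Number of permutations (default 1000; fewer than
#'   100 triggers a warning, fewer than 1 an error).
#' @param max_gap Gap bound used for the chains.
#' @param seed Optional integer seed.
#' @return P-value in (0, 1].
#' @export
block_significance <- function(block, n_anchors, chrom_len_a, chrom_len_b,
                               permutations = 1000L, max_gap = 50L,
                               seed = NULL) {
  if (permutations < 1L) stop("permutations must be >= 1")
  if (permutations < 100L) {
    warning("fewer than 100 permutations gives a coarse P-value")
  }
  obs <- if (inherits(block, "collinear_block")) block$length
         else as.integer(block)
  if (!is.null(seed)) set.seed(seed)
  null_max <- chain_null_cpp(n_anchors, chrom_len_a, chrom_len_b,
                             permutations, max_gap)
  (sum(null_max >= obs) + 1) / (permutations + 1)
}

#' Census of collinear blocks at size thresholds
#'
#' For each threshold `t`, counts blocks with more than `t` anchor pairs,
#' the collinear gene pairs inside them, and the distinct genes involved
#' on each genome; also reports the largest block and its chromosome
#' pair.
#'
#' @param blocks List of `collinear_block`.
#' @param thresholds Block-size thresholds (default `c(4, 10, 20, 50)`).
#' @return Data frame with one row per threshold and attributes
#'   `largest_block_length`, `largest_block_chroms`.
#' @export
block_census <- function(blocks, thresholds = c(4L, 10L, 20L, 50L)) {
  lens <- vapply(blocks, function(b) b$length, integer(1))
  rows <- lapply(thresholds, function(t) {
    sel <- blocks[lens > t]
    genes_a <- unique(unlist(lapply(sel, function(b) b$pairs$gene_a)))
    genes_b <- unique(unlist(lapply(sel, function(b) b$pairs$gene_b)))
    data.frame(threshold = t,
               block_count = length(sel),
               gene_pairs = sum(vapply(sel, function(b) b$length,
                                       integer(1))),
               genes_a = length(genes_a),
               genes_b = length(genes_b))
  })
  out <- do.call(rbind, rows)
  if (length(blocks)) {
    i <- which.max(lens)
    attr(out, "largest_block_length") <- lens[i]
    attr(out, "largest_block_chroms") <- c(blocks[[i]]$chrom_a,
                                           blocks[[i]]$chrom_b)
  } else {
    attr(out, "largest_block_length") <- 0L
    attr(out, "largest_block_chroms") <- c(NA_character_, NA_character_)
  }
  out
}

#' Write blocks as a tab-separated report
#'
#' One header line per block (chromosomes, length, orientation, P-value)
#' followed by one line per anchor pair.
#'
#' @param blocks List of `collinear_block`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    cat(sprintf("#block\t%d\t%s\t%s\t%d\t%s\t%g\n", i, b$chrom_a,
                b$chrom_b, b$length, b$orientation, b$p_value), file = con)
    for (j in seq_len(nrow(b$pairs))) {
      cat(sprintf("%s\t%s\t%d\t%d\n", b$pairs$gene_a[j], b$pairs$gene_b[j],
                  b$pairs$order_a[j], b$pairs$order_b[j]), file = con)
    }
  }
  invisible(path)
}
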