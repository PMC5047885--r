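## End-to-end orchestration: collinearity -> Ks -> classification ->
## correspondence -> trio tests -> fractionation, plus the gene-rank
## dot-plot. All stage parameters travel in one list and are written
## into the run manifest, so a manifest (plus the inputs and seed)
## reproduces a run exactly.

#' Default pipeline parameters
#'
#' @return Named list: `max_gap` (50 gene ranks), `p_threshold` (0.05),
#'   `min_len` (5 anchors), `permutations` (1000), `ortho_window`
#'   (Ks 0.95-1.20), `outpara_center` (1.5), `outpara_margin` (0.15),
#'   `share_threshold` (0.20), `min_anchor` (10), `disjoint_max` (0.10),
#'   `coverage_min` (0.80), `expected_depth` (2), `triage_evalue`
#'   (1e-10).
#' @export
pipeline_params <- function() {
  list(max_gap = 50L, p_threshold = 0.05, min_len = 5L,
       permutations = 1000L, ortho_window = c(0.95, 1.20),
       outpara_center = 1.5, outpara_margin = 0.15,
       share_threshold = 0.20, min_anchor = 10L, disjoint_max = 0.10,
       coverage_min = 0.80, expected_depth = 2L, triage_evalue = 1e-10)
}

classification_table <- function(classifications) {
  if (!length(classifications)) {
    return(data.frame(block = integer(), chrom_a = character(),
                      chrom_b = character(), length = integer(),
                      orientation = character(), p_value = numeric(),
                      ks_median = numeric(), label = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(classifications), function(i) {
    cl <- classifications[[i]]
    data.frame(block = i, chrom_a = cl$block$chrom_a,
               chrom_b = cl$block$chrom_b, length = cl$block$length,
               orientation = cl$block$orientation,
               p_value = cl$block$p_value, ks_median = cl$ks_median,
               label = cl$label, evidence = cl$evidence,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full inference pipeline
#'
#' Executes block detection between the query (unduplicated, panel A)
#' and subject (polyploid, panel B) genomes, Ks estimation on every
#' anchor pair, Ks-median classification with the shared-collinear-gene
#' tie-break for ambiguous cases, correspondence-map construction, the
#' fusion/fission trio tests with ancestral-count inference, the
#' fractionation census with translocation triage, and the block-size
#' census. All randomness (the permutation null) is governed by `seed`.
#'
#' @param panel_a Query-side `genome_panel` with CDS.
#' @param panel_b Subject-side `genome_panel` with CDS.
#' @param hits Hit table (filtered or raw; it is re-filtered).
#' @param trios Optional list of [trio_spec()] to test.
#' @param params Parameter list, see [pipeline_params()]; entries given
#'   here override the defaults.
#' @param seed Integer seed (default 1).
#' @param out_dir Optional directory; when given, all tables plus a
#'   run manifest are written there (deterministically: identical
#'   seed/config give byte-identical files).
#' @return Object of class `pipeline_result`: `blocks`, `ks_table`,
#'   `classifications` (+ `classification_table`), `map`, `verdicts`,
#'   `ancestral`, `census`, `fractionation`, `params`, `seed`.
#' @export
run_pipeline <- function(panel_a, panel_b, hits, trios = NULL,
                         params = list(), seed = 1L, out_dir = NULL) {
  p <- utils::modifyList(pipeline_params(), params)
  hits <- filter_hits(hits)
  blocks <- detect_blocks(hits, panel_a, panel_b, max_gap = p$max_gap,
                          p_threshold = p$p_threshold,
                          min_len = p$min_len,
                          permutations = p$permutations, seed = seed)
  pairs <- if (length(blocks)) {
    do.call(rbind, lapply(blocks, function(b) {
      data.frame(gene_a = b$pairs$gene_a, gene_b = b$pairs$gene_b,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(gene_a = character(), gene_b = character())
  ks_table <- if (nrow(pairs)) {
    ks_for_pairs(pairs, panel_a$cds, panel_b$cds)
  } else cbind(pairs, S = numeric(0), N = numeric(0), sd = numeric(0),
               nd = numeric(0), pS = numeric(0), ks = numeric(0),
               ka = numeric(0))
  classifications <- lapply(blocks, function(b) {
    m <- block_ks_median(b, ks_table)
    if (is.finite(m)) {
      classify_by_ks(b, m, ortho_window = p$ortho_window,
                     outpara_center = p$outpara_center,
                     margin = p$outpara_margin)
    } else {
      structure(list(block = b, ks_median = NA_real_,
                     label = "ambiguous",
                     evidence = "all anchor pairs Ks-saturated"),
                class = "block_classification")
    }
  })
  # tie-break ambiguous blocks via shared collinear genes: for each
  # query chromosome with several subject candidates, co-ortholog pairs
  # rescue their ambiguous blocks, resolved out-paralogs get demoted
  amb_q <- unique(vapply(Filter(function(cl) cl$label == "ambiguous",
                                classifications),
                         function(cl) cl$block$chrom_a, character(1)))
  for (q in amb_q) {
    touching <- Filter(function(cl) cl$block$chrom_a == q, classifications)
    cands <- unique(vapply(touching, function(cl) cl$block$chrom_b,
                           character(1)))
    if (length(cands) < 2L) next
    res <- tryCatch(
      resolve_by_sharing(q, cands, lapply(touching, `[[`, "block"),
                         share_threshold = p$share_threshold,
                         query_side = "a"),
      warning = function(w) suppressWarnings(
        resolve_by_sharing(q, cands, lapply(touching, `[[`, "block"),
                           share_threshold = p$share_threshold,
                           query_side = "a")))
    for (i in seq_along(classifications)) {
      cl <- classifications[[i]]
      if (cl$label != "ambiguous" || cl$block$chrom_a != q) next
      hit <- res$label[match(cl$block$chrom_b, res$chrom)]
      if (!is.na(hit)) {
        classifications[[i]]$label <- hit
        classifications[[i]]$evidence <- paste0(
          cl$evidence, "; resolved by shared collinear genes (",
          hit, ")")
      }
    }
  }
  map <- build_correspondence(classifications, min_anchor = p$min_anchor,
                              subject_side = "b")
  verdicts <- lapply(trios %||% list(), function(tr) {
    test_trio(tr, map, disjoint_max = p$disjoint_max,
              coverage_min = p$coverage_min)
  })
  ancestral <- if (length(verdicts)) {
    infer_ancestral_count(length(panel_b$chromosomes), verdicts)
  } else NULL
  census <- block_census(blocks)
  fr <- retention_census(panel_a, classifications,
                         expected_depth = p$expected_depth,
                         query_side = "a")
  fr <- absent_gene_triage(fr, hits, evalue_max = p$triage_evalue)
  result <- structure(
    list(blocks = blocks, ks_table = ks_table,
         classifications = classifications,
         classification_table = classification_table(classifications),
         map = map, verdicts = verdicts, ancestral = ancestral,
         census = census, fractionation = fr, params = p, seed = seed),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d blocks, %d classified",
              length(x$blocks), length(x$classifications)))
  if (!is.null(x$ancestral) && !is.na(x$ancestral$x)) {
    cat(sprintf("; inferred x = %g (2n pre-WGD %g, post %g)",
                x$ancestral$x, x$ancestral$n_pre_wgd[1],
                x$ancestral$n_post_wgd[1]))
  }
  cat("\n")
  invisible(x)
}

#' Write pipeline outputs and manifest to a directory
#'
#' Outputs are deterministic (no timestamps): the manifest records the
#' parameters, seed and package version, and suffices to reproduce the
#' run from the same inputs.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_blocks(result$blocks, file.path(out_dir, "blocks.tsv"))
  tsv(result$ks_table, "ks_pairs.tsv")
  tsv(result$classification_table, "classifications.tsv")
  tsv(result$census, "census.tsv")
  tsv(result$fractionation$records, "retention.tsv")
  verd <- if (length(result$verdicts)) {
    do.call(rbind, lapply(result$verdicts, function(v) {
      data.frame(merged = v$spec$merged, part_a = v$spec$parts[1],
                 part_b = v$spec$parts[2],
                 jaccard_parts = v$jaccard_parts, coverage = v$coverage,
                 verdict = v$verdict, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(merged = character(), part_a = character(),
               part_b = character(), jaccard_parts = numeric(),
               coverage = numeric(), verdict = character())
  }
  tsv(verd, "trio_verdicts.tsv")
  jsonlite::write_json(
    lapply(unclass(result$map), as.list),
    file.path(out_dir, "correspondence.json"), auto_unbox = TRUE)
  manifest <- list(
    package = "protochrom",
    version = as.character(utils::packageVersion("protochrom")),
    seed = result$seed,
    params = result$params,
    ancestral = result$ancestral,
    fractionation_summary = result$fractionation$summary,
    triage = as.list(result$fractionation$triage))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Gene-rank dot-plot of homology hits
#'
#' Axes are gene-order ranks with chromosomes laid end to end (the
#' convention matching the gap-in-genes chaining); dots are colored by
#' per-query match rank (best, second, other) by bitscore.
#'
#' @param hits Hit table.
#' @param panel_a,panel_b Panels for the x (query) and y (subject) axes.
#' @param highlight Subset of rank classes to draw
#'   (default all of best/second/other).
#' @return A ggplot object; the underlying dot data frame (columns
#'   `x`, `y`, `rank_class`, chromosomes and gene ids) is attached as
#'   attribute `"dots"`.
#' @export
render_dotplot <- function(hits, panel_a, panel_b,
                           highlight = c("best", "second", "other")) {
  highlight <- match.arg(highlight, several.ok = TRUE)
  dots <- anchor_dots(hits, panel_a, panel_b)
  offsets <- function(panel) {
    len <- chromosome_lengths(panel)
    off <- cumsum(c(0L, unname(len)[-length(len)]))
    setNames(off, names(len))
  }
  off_a <- offsets(panel_a); off_b <- offsets(panel_b)
  if (nrow(dots)) {
    rk <- hits[match(paste(dots$gene_a, dots$gene_b),
                     paste(hits$query, hits$subject)), "bitscore"]
    ord <- order(dots$gene_a, -rk)
    pos <- unlist(lapply(split(seq_along(ord), dots$gene_a[ord]),
                         seq_along), use.names = FALSE)
    rank_class <- character(nrow(dots))
    rank_class[ord] <- ifelse(pos == 1L, "best",
                              ifelse(pos == 2L, "second", "other"))
    dots$rank_class <- rank_class
    dots$x <- off_a[dots$chrom_a] + dots$order_a
    dots$y <- off_b[dots$chrom_b] + dots$order_b
    dots <- dots[dots$rank_class %in% highlight, , drop = FALSE]
  } else {
    warning("no dots to plot")
    dots$rank_class <- character(0)
    dots$x <- numeric(0); dots$y <- numeric(0)
  }
  gp <- ggplot2::ggplot(dots, ggplot2::aes(x = x, y = y,
                                           colour = rank_class)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(xintercept = unname(off_a)[-1], linewidth = 0.2,
                        colour = "grey70") +
    ggplot2::geom_hline(yintercept = unname(off_b)[-1], linewidth = 0.2,
                        colour = "grey70") +
    ggplot2::scale_colour_manual(values = c(best = "red",
                                            second = "orange",
                                            other = "blue"),
                                 name = "match rank") +
    ggplot2::labs(x = sprintf("%s gene rank", panel_a$species),
                  y = sprintf("%s gene rank", panel_b$species)) +
    ggplot2::theme_minimal()
  attr(gp, "dots") <- dots
  gp
}
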