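#' @useDynLib protochrom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rpois runif setNames
#' @importFrom utils head read.delim write.table
NULL

utils::globalVariables(c("x", "y", "rank_class"))

VALID_STRANDS <- c("+", "-")

#' Construct a genome panel
#'
#' A genome panel holds the ordered genes of one species together with
#' their coding sequences. Gene coordinates are 1-based inclusive base
#' pairs as in GFF3; the gene-order rank (`order_index`) used by all
#' collinearity machinery is 0-based and assigned per chromosome by start
#' coordinate, with ties broken by gene id.
#'
#' @param species Species label.
#' @param genes Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param cds Optional named character vector of coding sequences, names
#'   matching gene ids. Sequences are uppercased; genes whose CDS length
#'   is not a multiple of 3 are flagged frame-broken rather than dropped.
#' @return An object of class `genome_panel` with elements `species`,
#'   `chromosomes`, `genes` (with `order_index`), `cds`, `frame_broken`,
#'   `ambiguous` (gene ids whose CDS contains non-ACGT characters).
#' @export
genome_panel <- function(species, genes, cds = NULL) {
  stopifnot(is.character(species), length(species) == 1L)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  need <- c("id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  genes <- genes[, need]
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  dup <- genes$id[duplicated(genes$id)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(genes$strand), VALID_STRANDS)
  if (length(bad)) {
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    stop("gene start greater than end for: ",
         paste(genes$id[genes$start > genes$end], collapse = ", "))
  }
  # rank by start within chromosome, ties by id; 0-based order_index
  genes <- genes[order(genes$chrom, genes$start, genes$id), , drop = FALSE]
  genes$order_index <- unlist(lapply(split(seq_len(nrow(genes)),
                                           genes$chrom)[unique(genes$chrom)],
                                     function(ix) seq_along(ix) - 1L),
                              use.names = FALSE)
  rownames(genes) <- NULL
  frame_broken <- character()
  ambiguous <- character()
  if (!is.null(cds)) {
    cds <- setNames(toupper(as.character(cds)), names(cds))
    missing_panel <- setdiff(names(cds), genes$id)
    if (length(missing_panel)) {
      warning("CDS id(s) absent from panel: ",
              paste(missing_panel, collapse = ", "))
    }
    frame_broken <- names(cds)[nchar(cds) %% 3L != 0L]
    ambiguous <- names(cds)[grepl("[^ACGT]", cds)]
  }
  structure(list(species = species,
                 chromosomes = unique(genes$chrom),
                 genes = genes,
                 cds = cds,
                 frame_broken = frame_broken,
                 ambiguous = ambiguous),
            class = "genome_panel")
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("<genome_panel> %s: %d genes on %d chromosomes%s\n",
              x$species, nrow(x$genes), length(x$chromosomes),
              if (is.null(x$cds)) "" else sprintf(", %d CDS", length(x$cds))))
  invisible(x)
}

#' Number of genes per chromosome of a panel
#' @param panel A `genome_panel`.
#' @return Named integer vector, one entry per chromosome.
#' @export
chromosome_lengths <- function(panel) {
  if (nrow(panel$genes) == 0L) return(setNames(integer(), character()))
  tab <- table(panel$genes$chrom)
  setNames(as.integer(tab), names(tab))[panel$chromosomes]
}

#' Read gene annotations into a genome panel
#'
#' Accepts GFF3 (gene features; the `ID` attribute is the gene id) or a
#' 5-column BED-like TSV (`chrom`, `start`, `end`, `strand`, `id`,
#' 1-based inclusive coordinates, no header).
#'
#' @param path Annotation file.
#' @param species Species label for the panel.
#' @param format `"auto"` (by extension), `"gff3"`, or `"bed"`.
#' @return A [genome_panel()] (without CDS; see [read_cds()]).
#' @export
read_annotations <- function(path, species,
                             format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    genes <- data.frame(
      id = as.character(gr$ID),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    if (nrow(genes) && anyNA(genes$id)) {
      stop("GFF3 gene feature(s) without an ID attribute in ", path)
    }
  } else {
    if (file.size(path) == 0L) {
      genes <- NULL
    } else {
      tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(tab) < 5L) stop("BED-like gene list needs 5 columns")
      genes <- data.frame(id = as.character(tab[[5]]),
                          chrom = as.character(tab[[1]]),
                          start = as.integer(tab[[2]]),
                          end = as.integer(tab[[3]]),
                          strand = as.character(tab[[4]]),
                          stringsAsFactors = FALSE)
    }
  }
  genome_panel(species, genes)
}

#' Write a panel's gene annotations as GFF3
#'
#' Inverse of [read_annotations()]: `read_annotations(write_annotations(p))`
#' reproduces `p`'s gene table exactly (ids, coordinates, strands, order).
#'
#' @param panel A `genome_panel`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(panel, path) {
  g <- panel$genes
  if (nrow(g) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  gr$type <- "gene"
  gr$source <- "protochrom"
  gr$ID <- g$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' Record names (first whitespace-separated token) are taken as gene ids.
#' Sequences are uppercased; non-ACGT characters are preserved and the
#' affected ids are returned in the `"ambiguous"` attribute.
#'
#' @param path FASTA file.
#' @param panel Optional `genome_panel`; ids absent from the panel trigger
#'   a warning listing them (they are still returned).
#' @return Named character vector of sequences.
#' @export
read_cds <- function(path, panel = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (!is.null(panel)) {
    extra <- setdiff(names(seqs), panel$genes$id)
    if (length(extra)) {
      warning("CDS id(s) absent from panel: ", paste(extra, collapse = ", "))
    }
  }
  attr(seqs, "ambiguous") <- names(seqs)[grepl("[^ACGT]", seqs)]
  seqs
}

#' Write coding sequences as FASTA
#' @param cds Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

HIT_COLUMNS <- c("query", "subject", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read an all-vs-all homology hit table
#'
#' Parses the 12-column tab-separated dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) and
#' applies the standard anchor filter: drop self-hits and hits with
#' E-value above `max_evalue`, then keep at most `top_n` subjects per
#' query, ranked by bitscore (descending, ties broken by subject id).
#'
#' @param path Tab-separated hit table.
#' @param max_evalue Maximum E-value retained (default `1e-5`).
#' @param top_n Matches kept per query gene (default 5).
#' @return Data frame with columns `r paste(HIT_COLUMNS, collapse = ", ")`.
#' @export
read_hits <- function(path, max_evalue = 1e-5, top_n = 5L) {
  if (file.size(path) == 0L) {
    tab <- as.data.frame(setNames(rep(list(character(0)), 12), HIT_COLUMNS))
  } else {
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 12L)
    if (length(bad)) {
      stop(sprintf("malformed hit row at line %d of %s (%d fields, 12 needed)",
                   bad[1], path, nf[bad[1]]))
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:12))
    tab <- data.frame(m, stringsAsFactors = FALSE)
    names(tab) <- HIT_COLUMNS
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore")
    for (cc in num) {
      v <- suppressWarnings(as.numeric(tab[[cc]]))
      if (anyNA(v)) {
        stop(sprintf("malformed hit row at line %d of %s (non-numeric %s)",
                     which(is.na(v))[1], path, cc))
      }
      tab[[cc]] <- v
    }
  }
  filter_hits(tab, max_evalue = max_evalue, top_n = top_n)
}

#' Filter a homology hit table
#'
#' Idempotent: filtering an already-filtered table changes nothing.
#'
#' @param hits Data frame in the layout returned by [read_hits()].
#' @param max_evalue,top_n As in [read_hits()].
#' @param remove_tandem Drop within-genome hits between genes adjacent in
#'   gene order on the same chromosome (requires `panel`). Off by default.
#' @param panel `genome_panel` used for the tandem test.
#' @return Filtered data frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, top_n = 5L,
                        remove_tandem = FALSE, panel = NULL) {
  stopifnot(is.data.frame(hits))
  hits <- hits[hits$query != hits$subject & hits$evalue <= max_evalue, ,
               drop = FALSE]
  if (remove_tandem) {
    if (is.null(panel)) stop("remove_tandem requires a panel")
    g <- panel$genes
    oi <- setNames(g$order_index, g$id)
    ch <- setNames(g$chrom, g$id)
    both <- hits$query %in% g$id & hits$subject %in% g$id
    tandem <- both &
      ch[hits$query] == ch[hits$subject] &
      abs(oi[hits$query] - oi[hits$subject]) == 1L
    tandem[is.na(tandem)] <- FALSE
    hits <- hits[!tandem, , drop = FALSE]
  }
  if (nrow(hits)) {
    ord <- order(hits$query, -hits$bitscore, hits$subject)
    hits <- hits[ord, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query),
                          function(ix) head(ix, top_n)), use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Write a hit table in the 12-column tabular dialect
#' @param hits Data frame as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
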