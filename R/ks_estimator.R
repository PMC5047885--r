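## Nei-Gojobori (1986) counting estimator of synonymous (Ks) and
## nonsynonymous (Ka) substitution rates, with Jukes-Cantor multiple-hit
## correction. Synonymous site fractions per codon position exclude
## changes to stop codons from the denominator (the original convention),
## so S + N = 3 * n_codon_pairs always holds. Multi-position codon
## differences are averaged over all minimal mutational pathways with
## equal weight; pathways through stop codons are excluded (if every
## pathway is blocked, all are used as a fallback).

.ks_env <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  if (is.null(.ks_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .ks_env$code <- setNames(as.character(gc), names(gc))
  }
  .ks_env$code
}

translate_codon <- function(codon) {
  code <- genetic_code()
  aa <- code[codon]
  ifelse(is.na(aa), "X", aa)
}

# Synonymous site count of one codon: sum over positions of the fraction
# of non-stop single-base changes that preserve the amino acid.
syn_sites_codon <- function(codon) {
  key <- paste0("S:", codon)
  hit <- .ks_env[[key]]
  if (!is.null(hit)) return(hit)
  code <- genetic_code()
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(DNA_BASES, substr(codon, pos, pos))
    syn <- 0L; considered <- 0L
    for (b in alts) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (code[[alt]] == "*") next
      considered <- considered + 1L
      if (code[[alt]] == aa) syn <- syn + 1L
    }
    if (considered > 0L) s <- s + syn / considered
  }
  .ks_env[[key]] <- s
  s
}

all_orders <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orders(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Average synonymous/nonsynonymous difference counts between two codons
# over all minimal mutational pathways (stop-free pathways only, unless
# every pathway passes through a stop).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("D:", c1, "|", c2)
  hit <- .ks_env[[key]]
  if (!is.null(hit)) return(hit)
  code <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- all_orders(pos)
  tally <- function(order) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- vapply(paths, tally, numeric(3))
  ok <- res[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  out <- c(sd = mean(res[1, ok]), nd = mean(res[2, ok]))
  .ks_env[[key]] <- out
  out
}

# full lookup tables over all 64 codons: synonymous site counts and
# pathway-averaged difference counts for every codon pair; built once
ensure_ks_tables <- function() {
  if (!is.null(.ks_env$syn_tab)) return(invisible())
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                  collapse = "")
  syn <- vapply(codons, syn_sites_codon, numeric(1))
  n <- length(codons)
  sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- codon_pair_diffs(codons[i], codons[j])
      sd_mat[i, j] <- d[["sd"]]
      nd_mat[i, j] <- d[["nd"]]
    }
  }
  .ks_env$syn_tab <- syn
  .ks_env$sd_mat <- sd_mat
  .ks_env$nd_mat <- nd_mat
  invisible()
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

identity_matrix <- function(extra = character(), match = 1,
                            mismatch = -1) {
  alphabet <- unique(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                       "*", "X", extra))
  mat <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- match
  mat
}

# global protein alignment, vectorized over pairs: match +1, mismatch
# -1, linear gap -2 per residue
protein_align_many <- function(aa_a, aa_b, match = 1, mismatch = -1,
                               gap = -2) {
  mat <- identity_matrix(c(unlist(strsplit(aa_a, "")),
                           unlist(strsplit(aa_b, ""))), match, mismatch)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(aa_a), Biostrings::AAStringSet(aa_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap))
  list(pattern = as.character(Biostrings::pattern(al)),
       subject = as.character(Biostrings::subject(al)),
       score = Biostrings::score(al))
}

protein_align <- function(aa_a, aa_b, match = 1, mismatch = -1, gap = -2) {
  m <- protein_align_many(aa_a, aa_b, match, mismatch, gap)
  list(pattern = m$pattern[1], subject = m$subject[1], score = m$score[1])
}

# back-translate one aligned protein pair to retained codon columns
collapse_columns <- function(pattern, subject, ca, cb) {
  pa <- strsplit(pattern, "")[[1]]
  pb <- strsplit(subject, "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  gap <- pa == "-" | pb == "-"
  cod_a <- ifelse(gap, NA_character_, ca[ia])
  cod_b <- ifelse(gap, NA_character_, cb[ib])
  ambig <- !gap & (grepl("[^ACGT]", cod_a) | grepl("[^ACGT]", cod_b))
  stops <- !gap & !ambig & (pa == "*" | pb == "*")
  keep <- !gap & !ambig & !stops
  list(codons_a = cod_a[keep], codons_b = cod_b[keep],
       n_gap = sum(gap), n_ambig = sum(ambig), n_stop = sum(stops))
}

# Nei-Gojobori counts and rates from retained codon pairs
ng_core <- function(codons_a, codons_b) {
  ensure_ks_tables()
  n <- length(codons_a)
  S <- (sum(.ks_env$syn_tab[codons_a]) + sum(.ks_env$syn_tab[codons_b])) / 2
  N <- 3 * n - S
  idx <- cbind(match(codons_a, names(.ks_env$syn_tab)),
               match(codons_b, names(.ks_env$syn_tab)))
  sd <- sum(.ks_env$sd_mat[idx]); nd <- sum(.ks_env$nd_mat[idx])
  pS <- if (S > 0) sd / S else NA_real_
  pN <- if (N > 0) nd / N else NA_real_
  list(S = S, N = N, sd = sd, nd = nd, pS = pS, pN = pN,
       ks = jc_correct(pS), ka = jc_correct(pN))
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both sequences (incomplete terminal codons are trimmed,
#' internal stops are flagged), globally aligns the proteins (match +1,
#' mismatch -1, linear gap -2 per residue), and back-translates to codon
#' columns. Columns containing a gap, an ambiguous (non-ACGT) base, or a
#' stop codon are excluded from the retained codon pairs.
#'
#' @param cds_a,cds_b Coding sequences (DNA strings).
#' @return Object of class `codon_alignment`: retained `codons_a`,
#'   `codons_b`, `n_codon_pairs`, exclusion counts, alignment `score`,
#'   and `internal_stop` flags.
#' @export
align_codons <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  if (length(ca) == 0L || length(cb) == 0L) {
    stop("translated length 0: a CDS has no complete codon")
  }
  aa_a <- paste(translate_codon(ca), collapse = "")
  aa_b <- paste(translate_codon(cb), collapse = "")
  internal_stop <- c(a = grepl("\\*.", aa_a), b = grepl("\\*.", aa_b))
  al <- protein_align(aa_a, aa_b)
  cc <- collapse_columns(al$pattern, al$subject, ca, cb)
  structure(list(codons_a = cc$codons_a, codons_b = cc$codons_b,
                 n_codon_pairs = length(cc$codons_a),
                 n_gap_cols = cc$n_gap, n_ambiguous_cols = cc$n_ambig,
                 n_stop_cols = cc$n_stop, score = al$score,
                 internal_stop = internal_stop),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d codon pairs (%d gap, %d ambiguous, %d stop columns excluded), score %.1f\n",
              x$n_codon_pairs, x$n_gap_cols, x$n_ambiguous_cols,
              x$n_stop_cols, x$score))
  invisible(x)
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori Ks/Ka estimate for a codon alignment
#'
#' Counting estimator: expected synonymous (S) and nonsynonymous (N)
#' sites from per-position one-step change fractions averaged over the
#' two sequences; observed synonymous (sd) and nonsynonymous (nd)
#' differences averaged over all minimal mutational pathways with equal
#' weight (stop-free pathways only); Jukes-Cantor correction
#' `ks = -(3/4) log(1 - (4/3) pS)` and likewise for ka. `pS >= 3/4`
#' yields a saturated (undefined, `NA`) ks rather than an error.
#'
#' @param alignment A [align_codons()] result.
#' @return Object of class `ks_estimate` with fields `S`, `N`, `sd`,
#'   `nd`, `pS`, `pN`, `ks`, `ka`, `n_codon_pairs`, `saturated`.
#' @export
nei_gojobori <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  n <- alignment$n_codon_pairs
  if (n < 1L) stop("alignment has no retained codon pairs")
  cc <- ng_core(alignment$codons_a, alignment$codons_b)
  structure(c(cc, list(n_codon_pairs = n,
                       saturated = is.na(cc$ks) && !is.na(cc$pS) &&
                         cc$pS >= 3 / 4)),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("<ks_estimate> S=%.2f N=%.2f sd=%.2f nd=%.2f pS=%.4f ks=%s ka=%s\n",
              x$S, x$N, x$sd, x$nd, x$pS,
              if (is.na(x$ks)) "saturated" else sprintf("%.4f", x$ks),
              if (is.na(x$ka)) "saturated" else sprintf("%.4f", x$ka)))
  invisible(x)
}

#' Ks estimates for a table of gene pairs
#'
#' Convenience wrapper: aligns and estimates every pair once (pairs are
#' cached within the call).
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param cds_a,cds_b Named CDS vectors for the two genomes.
#' @return Data frame `gene_a`, `gene_b`, `S`, `N`, `sd`, `nd`, `pS`,
#'   `ks`, `ka` (`NA` ks marks saturation or missing CDS).
#' @export
ks_for_pairs <- function(pairs, cds_a, cds_b) {
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  ui <- which(!duplicated(key))
  ga <- pairs$gene_a[ui]; gb <- pairs$gene_b[ui]
  sa <- unname(cds_a[ga]); sb <- unname(cds_b[gb])
  ok <- !is.na(sa) & !is.na(sb) & nchar(sa) >= 3L & nchar(sb) >= 3L
  mat <- matrix(NA_real_, length(ui), 7,
                dimnames = list(NULL, c("S", "N", "sd", "nd", "pS",
                                        "ks", "ka")))
  if (any(ok)) {
    codons <- lapply(c(sa[ok], sb[ok]), function(s) split_codons(toupper(s)))
    prots <- vapply(codons, function(cd) paste(translate_codon(cd),
                                               collapse = ""),
                    character(1))
    n <- sum(ok)
    al <- protein_align_many(prots[seq_len(n)], prots[n + seq_len(n)])
    est <- lapply(seq_len(n), function(j) {
      cc <- collapse_columns(al$pattern[j], al$subject[j],
                             codons[[j]], codons[[n + j]])
      if (!length(cc$codons_a)) return(rep(NA_real_, 7))
      e <- ng_core(cc$codons_a, cc$codons_b)
      c(e$S, e$N, e$sd, e$nd, e$pS, e$ks, e$ka)
    })
    mat[ok, ] <- do.call(rbind, est)
  }
  out <- cbind(pairs[, c("gene_a", "gene_b")],
               as.data.frame(mat[match(key, key[ui]), , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Block Ks median
#'
#' Median over the finite (non-saturated) Ks values of a block's anchor
#' pairs; an even count averages the central two. If every pair is
#' saturated the median is `NA` and the block is flagged.
#'
#' @param block A `collinear_block` (see [detect_blocks()]).
#' @param ks_table Data frame from [ks_for_pairs()] covering the block's
#'   pairs.
#' @return Numeric median (possibly `NA`) with attribute `n_finite`.
#' @export
block_ks_median <- function(block, ks_table) {
  key <- paste(ks_table$gene_a, ks_table$gene_b, sep = "\r")
  want <- paste(block$pairs$gene_a, block$pairs$gene_b, sep = "\r")
  ks <- ks_table$ks[match(want, key)]
  finite <- ks[is.finite(ks)]
  out <- if (length(finite)) median(finite) else NA_real_
  attr(out, "n_finite") <- length(finite)
  out
}
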