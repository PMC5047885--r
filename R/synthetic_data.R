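## Forward simulator of two genomes descending from a common ancestor.
## Lineage A stays unduplicated (the outgroup); lineage B may undergo a
## tetraploidization followed by end-end chromosome fusions (CEJ),
## fissions, per-copy gene loss, translocations and inversions. Coding
## sequences diverge under a synonymous clock: substitution events are
## Poisson in expected substitutions per synonymous site, placed at
## third positions of fourfold-degenerate codons, so the synonymous
## process is exactly Jukes-Cantor and the configured ks is the
## Nei-Gojobori expectation. Every random draw is recorded in an event
## log whose replay reproduces the genomes exactly.

# fourfold-degenerate codon families used for simulated CDS; all third
# positions are fully synonymous, all one-step prefix changes within the
# set are nonsynonymous and stop-free
FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "TC")

prefix_neighbors <- function() {
  nb <- list()
  for (p in FOURFOLD_PREFIXES) {
    others <- setdiff(FOURFOLD_PREFIXES, p)
    one_step <- others[substr(others, 1, 1) == substr(p, 1, 1) |
                         substr(others, 2, 2) == substr(p, 2, 2)]
    nb[[p]] <- one_step
  }
  nb
}

#' Simulation configuration
#'
#' Defines one two-lineage genome history. Defaults describe the
#' grass-like study design: an outgroup split at synonymous divergence
#' `ks_split`, a tetraploidization in lineage B whose subgenomes sit at
#' `ks_wgd`, and optional chromosome fusions/fissions, per-copy gene
#' loss, translocations and inversions in lineage B.
#'
#' @param seed Integer seed; the whole simulation is deterministic
#'   given it.
#' @param x Ancestral (basic) chromosome number.
#' @param genes_per_chromosome Genes on each ancestral chromosome.
#' @param codons_per_gene CDS length in codons.
#' @param wgd_in_lineage_b Tetraploidize lineage B?
#' @param fusion_events List of two-element character vectors naming
#'   lineage-B chromosomes to join end-to-end (after the WGD these are
#'   `"B1_i"`/`"B2_i"`, else `"B_i"`).
#' @param fission_events List of `list(chrom =, rank =)` splits in
#'   lineage B (first part keeps ranks `1..rank`).
#' @param fission_events_a Same, for lineage A chromosomes (`"A_i"`).
#' @param per_copy_loss_rate Probability each lineage-B gene copy is
#'   lost.
#' @param loss_timing `"before_merge"` (losses in the parental
#'   subgenomes before any fusion, the allopolyploid scenario) or
#'   `"after_merge"`.
#' @param translocation_rate Probability a lineage-B gene moves to a
#'   random position on another chromosome.
#' @param inversion_rate Expected inversions per lineage-B chromosome.
#' @param ks_split Expected synonymous divergence between A-B ortholog
#'   pairs.
#' @param ks_wgd Expected synonymous divergence between the two B
#'   subgenomes (must be at most `2 * ks_split`).
#' @param nonsyn_fraction Nonsynonymous events per synonymous event.
#' @param cej_trim Genes lost from each joined end in a fusion (the
#'   "tiny part" removed by end-end joining).
#' @param ancient_dup Plant a pre-split duplicate of the first ancestral
#'   chromosome (an out-paralogy layer).
#' @param ks_ancient Synonymous divergence of out-paralog pairs across
#'   the genomes (must exceed `ks_split`).
#' @param ancient_loss_rate Per-copy loss applied to descendants of the
#'   ancient duplicate in both lineages (old duplication layers are
#'   heavily fractionated, which is what makes out-paralogous
#'   collinearity sparse; default 0.9).
#' @param decoy_rate Fraction of spurious hit rows added to the
#'   homology table.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, x = 7L, genes_per_chromosome = 60L,
                       codons_per_gene = 120L, wgd_in_lineage_b = TRUE,
                       fusion_events = list(), fission_events = list(),
                       fission_events_a = list(),
                       per_copy_loss_rate = 0, loss_timing = "before_merge",
                       translocation_rate = 0, inversion_rate = 0,
                       ks_split = 1.05, ks_wgd = 0.9,
                       nonsyn_fraction = 0.1, cej_trim = 2L,
                       ancient_dup = FALSE, ks_ancient = 1.5,
                       ancient_loss_rate = 0.9, decoy_rate = 0) {
  cfg <- list(seed = as.integer(seed), x = as.integer(x),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              codons_per_gene = as.integer(codons_per_gene),
              wgd_in_lineage_b = isTRUE(wgd_in_lineage_b),
              fusion_events = fusion_events,
              fission_events = fission_events,
              fission_events_a = fission_events_a,
              per_copy_loss_rate = per_copy_loss_rate,
              loss_timing = match.arg(loss_timing,
                                      c("before_merge", "after_merge")),
              translocation_rate = translocation_rate,
              inversion_rate = inversion_rate,
              ks_split = ks_split, ks_wgd = ks_wgd,
              nonsyn_fraction = nonsyn_fraction,
              cej_trim = as.integer(cej_trim),
              ancient_dup = isTRUE(ancient_dup), ks_ancient = ks_ancient,
              ancient_loss_rate = ancient_loss_rate,
              decoy_rate = decoy_rate)
  rates <- c(cfg$per_copy_loss_rate, cfg$translocation_rate,
             cfg$decoy_rate, cfg$ancient_loss_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$inversion_rate < 0) stop("inversion_rate must be >= 0")
  if (cfg$ks_split < 0 || cfg$ks_wgd < 0) stop("ks values must be >= 0")
  if (cfg$wgd_in_lineage_b && cfg$ks_wgd > 2 * cfg$ks_split) {
    stop("ks_wgd cannot exceed 2 * ks_split on a clock-like tree")
  }
  if (cfg$ancient_dup && cfg$ks_ancient <= cfg$ks_split) {
    stop("ks_ancient must exceed ks_split")
  }
  if (cfg$x < 1L || cfg$genes_per_chromosome < 1L ||
      cfg$codons_per_gene < 1L) {
    stop("x, genes_per_chromosome and codons_per_gene must be positive")
  }
  structure(cfg, class = "sim_config")
}

random_cds <- function(n_codons) {
  pref <- sample(FOURFOLD_PREFIXES, n_codons, replace = TRUE)
  third <- sample(DNA_BASES, n_codons, replace = TRUE)
  paste0(pref, third, collapse = "")
}

# draw a substitution-event table for one branch. Synonymous events hit
# third positions of fourfold codons; each event sets the base uniformly
# over all four (a self-change is a no-op), which is exactly the
# Jukes-Cantor chain when events arrive at rate (4/3) k per codon --
# expected realized substitutions per synonymous site = k, multiple hits
# included. Nonsynonymous events are one-step prefix switches within the
# fourfold set at rate k * nonsyn_fraction.
draw_mutations <- function(gene_ids, n_codons, k, nonsyn_fraction) {
  if (k <= 0 || !length(gene_ids)) {
    return(data.frame(gene = character(), codon = integer(),
                      kind = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  n_syn <- rpois(length(gene_ids), n_codons * k * 4 / 3)
  n_non <- rpois(length(gene_ids), n_codons * k * nonsyn_fraction)
  syn <- data.frame(
    gene = rep(gene_ids, n_syn),
    codon = unlist(lapply(n_syn, function(m) sample.int(n_codons, m,
                                                        replace = TRUE))),
    kind = "syn",
    value = sample(DNA_BASES, sum(n_syn), replace = TRUE),
    stringsAsFactors = FALSE)
  non <- data.frame(
    gene = rep(gene_ids, n_non),
    codon = unlist(lapply(n_non, function(m) sample.int(n_codons, m,
                                                        replace = TRUE))),
    kind = "non",
    value = as.character(sample.int(5L, sum(n_non), replace = TRUE)),
    stringsAsFactors = FALSE)
  out <- rbind(syn, non)
  out[sample.int(nrow(out)), , drop = FALSE]
}

# apply a mutation table to a CDS vector; "syn" events set the third
# position of the codon to `value` (skipped when equal, so each applied
# event picks one of the three alternatives uniformly via redraw-free
# thinning is NOT used: value is uniform over 4, a self-change is a
# silent no-op which thins the rate equally for all codons)
apply_mutations <- function(cds, muts, neighbors) {
  if (!nrow(muts)) return(cds)
  for (g in unique(muts$gene)) {
    seq <- cds[[g]]
    rows <- which(muts$gene == g)
    codons <- split_codons(seq)
    for (r in rows) {
      j <- muts$codon[r]
      cod <- codons[j]
      if (muts$kind[r] == "syn") {
        codons[j] <- paste0(substr(cod, 1, 2), muts$value[r])
      } else {
        nb <- neighbors[[substr(cod, 1, 2)]]
        pick <- nb[(as.integer(muts$value[r]) - 1L) %% length(nb) + 1L]
        codons[j] <- paste0(pick, substr(cod, 3, 3))
      }
    }
    cds[[g]] <- paste0(codons, collapse = "")
  }
  cds
}

new_sim_genome <- function(chroms, cds) {
  list(chroms = chroms, cds = cds,
       strand = setNames(rep("+", length(cds)), names(cds)))
}

## ---- event application (shared by simulate and replay) ----

apply_sim_event <- function(state, ev, neighbors) {
  g <- ev$lineage
  switch(ev$type,
    derive = {
      src <- state$ancestor
      chroms <- lapply(src$chroms, function(v) paste0(ev$prefix, v))
      names(chroms) <- ev$chrom_names
      cds <- setNames(src$cds, paste0(ev$prefix, names(src$cds)))
      state[[g]] <- new_sim_genome(chroms, cds)
    },
    wgd = {
      gen <- state[[g]]
      c1 <- lapply(gen$chroms, function(v) paste0("s1_", sub("^B_", "",
                                                             v)))
      c2 <- lapply(gen$chroms, function(v) paste0("s2_", sub("^B_", "",
                                                             v)))
      names(c1) <- ev$names_s1; names(c2) <- ev$names_s2
      base <- sub("^B_", "", names(gen$cds))
      cds <- c(setNames(gen$cds, paste0("s1_", base)),
               setNames(gen$cds, paste0("s2_", base)))
      state[[g]] <- new_sim_genome(c(c1, c2), cds)
    },
    mutate = {
      gen <- state[[g]]
      gen$cds <- apply_mutations(gen$cds, ev$mutations, neighbors)
      state[[g]] <- gen
    },
    loss = {
      gen <- state[[g]]
      gen$chroms <- lapply(gen$chroms, function(v) setdiff(v, ev$genes))
      gen$cds <- gen$cds[setdiff(names(gen$cds), ev$genes)]
      gen$strand <- gen$strand[setdiff(names(gen$strand), ev$genes)]
      state[[g]] <- gen
    },
    fission = {
      gen <- state[[g]]
      v <- gen$chroms[[ev$chrom]]
      if (is.null(v)) stop("fission target not found: ", ev$chrom)
      if (ev$rank < 1L || ev$rank >= length(v)) {
        stop("fission breakpoint outside chromosome ", ev$chrom)
      }
      keep <- setdiff(names(gen$chroms), ev$chrom)
      gen$chroms <- c(gen$chroms[keep],
                      setNames(list(v[seq_len(ev$rank)],
                                    v[(ev$rank + 1L):length(v)]),
                               paste0(ev$chrom, c("a", "b"))))
      state[[g]] <- gen
    },
    fusion = {
      gen <- state[[g]]
      vi <- gen$chroms[[ev$chrom_i]]; vj <- gen$chroms[[ev$chrom_j]]
      if (is.null(vi) || is.null(vj)) {
        stop("fusion target not found: ", ev$chrom_i, " / ", ev$chrom_j)
      }
      trim <- ev$trim
      keep_i <- if (trim > 0L && length(vi) > trim)
        vi[seq_len(length(vi) - trim)] else vi
      keep_j <- if (trim > 0L && length(vj) > trim)
        vj[-seq_len(trim)] else vj
      dropped <- c(setdiff(vi, keep_i), setdiff(vj, keep_j))
      merged <- c(keep_i, keep_j)
      keep <- setdiff(names(gen$chroms), c(ev$chrom_i, ev$chrom_j))
      gen$chroms <- c(gen$chroms[keep],
                      setNames(list(merged),
                               paste0(ev$chrom_i, "x", ev$chrom_j)))
      gen$cds <- gen$cds[setdiff(names(gen$cds), dropped)]
      gen$strand <- gen$strand[setdiff(names(gen$strand), dropped)]
      state[[g]] <- gen
    },
    inversion = {
      gen <- state[[g]]
      v <- gen$chroms[[ev$chrom]]
      span <- ev$from:ev$to
      gen$chroms[[ev$chrom]][span] <- rev(v[span])
      flip <- v[span]
      gen$strand[flip] <- ifelse(gen$strand[flip] == "+", "-", "+")
      state[[g]] <- gen
    },
    translocation = {
      gen <- state[[g]]
      from <- ev$from_chrom
      gen$chroms[[from]] <- setdiff(gen$chroms[[from]], ev$gene)
      tv <- gen$chroms[[ev$to_chrom]]
      at <- min(ev$at, length(tv) + 1L)
      gen$chroms[[ev$to_chrom]] <- append(tv, ev$gene, after = at - 1L)
      state[[g]] <- gen
    },
    decoys = {
      state$decoys <- ev$rows
      state
    },
    stop("unknown event type: ", ev$type)
  )
  state
}

## ---- panels, ancestry, hits ----

sim_genome_to_panel <- function(gen, species, codons_per_gene) {
  if (is.null(gen)) return(genome_panel(species, NULL))
  chroms <- gen$chroms[order(names(gen$chroms))]
  rows <- lapply(names(chroms), function(ch) {
    ids <- chroms[[ch]]
    if (!length(ids)) return(NULL)
    start <- (seq_along(ids) - 1L) * 1500L + 1L
    data.frame(id = ids, chrom = ch, start = start,
               end = start + 3L * codons_per_gene - 1L,
               strand = unname(gen$strand[ids]), stringsAsFactors = FALSE)
  })
  genome_panel(species, do.call(rbind, rows), cds = gen$cds)
}

strip_prefix <- function(ids) sub("^(A_|s1_|s2_|B_)", "", ids)

sim_ancestry <- function(state) {
  rows <- lapply(c("A", "B"), function(g) {
    gen <- state[[g]]
    if (is.null(gen)) return(NULL)
    ids <- names(gen$cds)
    anc <- strip_prefix(ids)
    data.frame(gene = ids, genome = g,
               ancestral_gene = anc,
               family = sub("d$", "", anc),
               subgenome = sub("_.*$", "", ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# nominal synonymous tree distance between two extant genes of the same
# family, from the branch lengths the simulation used: paths meet either
# at the speciation/WGD (sum of the two terminal branches) or, for
# ancient-duplicate pairs, additionally traverse the duplicate's stem
# branch of length ks_ancient - ks_split
pair_distance <- function(sub1, sub2, dup1, dup2, cfg) {
  k_a <- cfg$ks_split - if (cfg$wgd_in_lineage_b) cfg$ks_wgd / 2 else 0
  branch <- function(sub) {
    if (sub == "A") k_a
    else if (sub %in% c("s1", "s2")) cfg$ks_wgd / 2
    else cfg$ks_split - k_a   # unduplicated B
  }
  d <- if (sub1 == sub2) 0 else branch(sub1) + branch(sub2)
  if (dup1 != dup2) {
    d <- d + (cfg$ks_ancient - cfg$ks_split)
    # same-subgenome pairs exist only through the ancient duplication;
    # both copies then carry the full terminal branch independently
    if (sub1 == sub2) d <- d + 2 * branch(sub1)
  }
  d
}

empty_hits <- function() {
  as.data.frame(setNames(c(rep(list(character(0)), 2),
                           rep(list(numeric(0)), 10)), HIT_COLUMNS))
}

sim_hits <- function(state, cfg) {
  anc <- sim_ancestry(state)
  if (is.null(anc) || !nrow(anc)) return(empty_hits())
  qlen <- 3L * cfg$codons_per_gene
  fams <- split(anc, anc$family)
  rows <- lapply(fams, function(f) {
    n <- nrow(f)
    if (n < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    d <- mapply(function(a, b) {
      pair_distance(f$subgenome[a], f$subgenome[b],
                    grepl("d$", f$ancestral_gene[a]),
                    grepl("d$", f$ancestral_gene[b]), cfg)
    }, i, j)
    data.frame(query = c(f$gene[i], f$gene[j]),
               subject = c(f$gene[j], f$gene[i]),
               pident = round(100 * exp(-rep(d, 2) / 2), 2),
               length = qlen, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = qlen, sstart = 1L, send = qlen,
               evalue = signif(10^-(pmax(10, 200 * exp(-rep(d, 2)))), 3),
               bitscore = round(800 * exp(-rep(d, 2)), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(state$decoys)))
  rownames(out) <- NULL
  out
}

## ---- the simulator ----

#' Simulate two genomes across a tetraploidization
#'
#' Builds a random ancestor, evolves an unduplicated lineage A and a
#' lineage B that may undergo a whole-genome duplication, fusions,
#' fissions, gene loss, translocations and inversions per `config`, and
#' emits gene panels, CDS, a homology hit table derived from true
#' ancestry, and a ground-truth event log. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: `panel_a`, `panel_b`
#'   (panels with CDS attached), `hits`, `log` (class `event_log`,
#'   containing the ancestor, the applied events, the ancestry map,
#'   losses and fusion junctions).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  neighbors <- prefix_neighbors()
  L <- cfg$codons_per_gene
  # ancestor (plus optional pre-split duplicate of chromosome 1)
  chroms <- lapply(seq_len(cfg$x), function(c) {
    sprintf("anc%d_g%03d", c, seq_len(cfg$genes_per_chromosome))
  })
  names(chroms) <- paste0("anc", seq_len(cfg$x))
  ids <- unlist(chroms, use.names = FALSE)
  cds <- setNames(vapply(ids, function(i) random_cds(L), character(1)), ids)
  if (cfg$ancient_dup) {
    dup_ids <- paste0(chroms[[1]], "d")
    dup_cds <- setNames(cds[chroms[[1]]], dup_ids)
    dup_muts <- draw_mutations(dup_ids, L, cfg$ks_ancient - cfg$ks_split,
                               cfg$nonsyn_fraction)
    dup_cds <- apply_mutations(dup_cds, dup_muts, neighbors)
    chroms[[paste0("anc", cfg$x + 1L)]] <- dup_ids
    cds <- c(cds, dup_cds)
  }
  ancestor <- new_sim_genome(chroms, cds)
  state <- list(ancestor = ancestor, A = NULL, B = NULL, decoys = NULL)
  events <- list()
  push <- function(ev) {
    events[[length(events) + 1L]] <<- ev
    state <<- apply_sim_event(state, ev, neighbors)
  }
  anc_names <- names(ancestor$chroms)
  # lineage A
  push(list(type = "derive", lineage = "A", prefix = "A_",
            chrom_names = paste0("A_", seq_along(anc_names))))
  k_a <- cfg$ks_split - if (cfg$wgd_in_lineage_b) cfg$ks_wgd / 2 else 0
  push(list(type = "mutate", lineage = "A",
            mutations = draw_mutations(names(state$A$cds), L, k_a,
                                       cfg$nonsyn_fraction)))
  for (fe in cfg$fission_events_a) {
    push(list(type = "fission", lineage = "A", chrom = fe$chrom,
              rank = as.integer(fe$rank)))
  }
  # lineage B
  push(list(type = "derive", lineage = "B", prefix = "B_",
            chrom_names = paste0("B_", seq_along(anc_names))))
  if (cfg$wgd_in_lineage_b) {
    push(list(type = "wgd", lineage = "B",
              names_s1 = paste0("B1_", seq_along(anc_names)),
              names_s2 = paste0("B2_", seq_along(anc_names))))
    for (sub in c("s1_", "s2_")) {
      tgt <- names(state$B$cds)[startsWith(names(state$B$cds), sub)]
      push(list(type = "mutate", lineage = "B",
                mutations = draw_mutations(tgt, L, cfg$ks_wgd / 2,
                                           cfg$nonsyn_fraction)))
    }
  } else if (cfg$ks_split - k_a > 0) {
    push(list(type = "mutate", lineage = "B",
              mutations = draw_mutations(names(state$B$cds), L,
                                         cfg$ks_split - k_a,
                                         cfg$nonsyn_fraction)))
  }
  # ancient-layer fractionation: descendants of the pre-split duplicate
  # are thinned in both lineages (the sparse collinearity an old
  # duplication leaves behind)
  if (cfg$ancient_dup && cfg$ancient_loss_rate > 0) {
    for (g in c("A", "B")) {
      ids <- names(state[[g]]$cds)
      dups <- ids[grepl("d$", strip_prefix(ids))]
      lost <- dups[runif(length(dups)) < cfg$ancient_loss_rate]
      if (length(lost)) push(list(type = "loss", lineage = g,
                                  genes = lost))
    }
  }
  do_loss <- function() {
    if (cfg$per_copy_loss_rate <= 0) return()
    ids <- names(state$B$cds)
    ids <- ids[!grepl("d$", strip_prefix(ids))]  # ancient layer handled
    lost <- ids[runif(length(ids)) < cfg$per_copy_loss_rate]
    if (length(lost)) push(list(type = "loss", lineage = "B",
                                genes = lost))
  }
  if (cfg$loss_timing == "before_merge") do_loss()
  for (fe in cfg$fission_events) {
    push(list(type = "fission", lineage = "B", chrom = fe$chrom,
              rank = as.integer(fe$rank)))
  }
  for (fu in cfg$fusion_events) {
    vi <- state$B$chroms[[fu[1]]]; vj <- state$B$chroms[[fu[2]]]
    if (is.null(vi) || is.null(vj)) {
      stop("fusion target not found: ", fu[1], " / ", fu[2])
    }
    trim <- min(cfg$cej_trim, length(vi) - 1L, length(vj) - 1L)
    push(list(type = "fusion", lineage = "B", chrom_i = fu[1],
              chrom_j = fu[2], trim = trim,
              trimmed = c(if (trim > 0L) vi[(length(vi) - trim + 1L):
                                              length(vi)],
                          if (trim > 0L) vj[seq_len(trim)]),
              junction_rank = length(vi) - trim))
  }
  if (cfg$loss_timing == "after_merge") do_loss()
  if (cfg$inversion_rate > 0) {
    for (ch in names(state$B$chroms)) {
      n_inv <- rpois(1, cfg$inversion_rate)
      for (k in seq_len(n_inv)) {
        len <- length(state$B$chroms[[ch]])
        if (len < 4L) next
        from <- sample.int(len - 1L, 1L)
        to <- min(len, from + sample.int(max(len %/% 4L, 2L), 1L))
        push(list(type = "inversion", lineage = "B", chrom = ch,
                  from = from, to = to))
      }
    }
  }
  if (cfg$translocation_rate > 0 && length(state$B$chroms) > 1L) {
    for (ch in names(state$B$chroms)) {
      for (gene in state$B$chroms[[ch]]) {
        if (runif(1) >= cfg$translocation_rate) next
        to <- sample(setdiff(names(state$B$chroms), ch), 1L)
        at <- sample.int(length(state$B$chroms[[to]]) + 1L, 1L)
        push(list(type = "translocation", lineage = "B", gene = gene,
                  from_chrom = ch, to_chrom = to, at = at))
      }
    }
  }
  if (cfg$decoy_rate > 0) {
    anc_map <- sim_ancestry(state)
    n_decoy <- round(cfg$decoy_rate * nrow(anc_map))
    if (n_decoy > 0L) {
      qa <- sample(anc_map$gene[anc_map$genome == "A"], n_decoy,
                   replace = TRUE)
      sb <- sample(anc_map$gene[anc_map$genome == "B"], n_decoy,
                   replace = TRUE)
      qlen <- 3L * L
      push(list(type = "decoys", lineage = "B", rows = data.frame(
        query = qa, subject = sb, pident = 30, length = qlen,
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = qlen,
        sstart = 1L, send = qlen, evalue = 1e-6, bitscore = 40,
        stringsAsFactors = FALSE)))
    }
  }
  finish_sim(state, events, cfg)
}

finish_sim <- function(state, events, cfg) {
  panel_a <- sim_genome_to_panel(state$A, "A", cfg$codons_per_gene)
  panel_b <- sim_genome_to_panel(state$B, "B", cfg$codons_per_gene)
  hits <- sim_hits(state, cfg)
  losses <- unlist(lapply(events, function(e) {
    if (e$type == "loss") e$genes else character()
  }))
  trimmed <- unlist(lapply(events, function(e) {
    if (e$type == "fusion") e$trimmed else character()
  }))
  junc <- lapply(Filter(function(e) e$type == "fusion", events),
                 function(e) data.frame(
                   chrom = paste0(e$chrom_i, "x", e$chrom_j),
                   junction_rank = e$junction_rank,
                   left_chrom = e$chrom_i, right_chrom = e$chrom_j,
                   stringsAsFactors = FALSE))
  log <- structure(list(config = cfg, ancestor = state$ancestor,
                        events = events, n_events = length(events),
                        ancestry = sim_ancestry(state),
                        losses = losses, trimmed = trimmed,
                        junctions = if (length(junc))
                          do.call(rbind, junc) else NULL,
                        complete = TRUE),
                   class = "event_log")
  structure(list(panel_a = panel_a, panel_b = panel_b, hits = hits,
                 log = log),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> A: %d genes / %d chromosomes; B: %d genes / %d chromosomes; %d hit rows; %d events\n",
              nrow(x$panel_a$genes), length(x$panel_a$chromosomes),
              nrow(x$panel_b$genes), length(x$panel_b$chromosomes),
              nrow(x$hits), x$log$n_events))
  invisible(x)
}

#' Replay an event log on an ancestor
#'
#' Re-applies the recorded events deterministically (no randomness is
#' drawn) and rebuilds panels and hit table; the result is identical to
#' the original [simulate_genomes()] output.
#'
#' @param log An `event_log`.
#' @param ancestor Ancestor genome; defaults to the one stored in the
#'   log.
#' @return A `sim_result`.
#' @export
replay_log <- function(log, ancestor = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (!isTRUE(log$complete) || length(log$events) != log$n_events) {
    stop("event log is incomplete: cannot replay")
  }
  if (is.null(ancestor)) ancestor <- log$ancestor
  if (!identical(sort(names(ancestor$cds)),
                 sort(unlist(lapply(ancestor$chroms, identity),
                             use.names = FALSE)))) {
    stop("ancestor does not match the event log")
  }
  neighbors <- prefix_neighbors()
  state <- list(ancestor = ancestor, A = NULL, B = NULL, decoys = NULL)
  for (ev in log$events) {
    state <- apply_sim_event(state, ev, neighbors)
  }
  finish_sim(state, log$events, log$config)
}

#' Named scenario presets
#'
#' Ready-made configurations for the canonical rearrangement scenarios:
#' `fission_A` (one ancestral chromosome; after the WGD one duplicate
#' copy splits in two), `fission_B` (as A, plus an independent fission
#' in the outgroup lineage), `fusion_C` (two ancestral chromosomes; after
#' the WGD one duplicated set joins end-to-end), and `grass_like`
#' (x = 7, WGD, two CEJ fusions taking 14 chromosomes to 12, 40%
#' per-copy loss before the merge, light translocation and inversion).
#'
#' @param seed Seed stored into each preset config.
#' @return Named list; each element has `config` (a [sim_config()]),
#'   `trios` (list of [trio_spec()] to test) and `expected_verdict`.
#' @export
scenario_presets <- function(seed = 1L) {
  list(
    fission_A = list(
      config = sim_config(seed = seed, x = 1L, genes_per_chromosome = 140L,
                          codons_per_gene = 100L,
                          fission_events = list(list(chrom = "B2_1",
                                                     rank = 70L)),
                          per_copy_loss_rate = 0.3),
      trios = list(trio_spec("B1_1", c("B2_1a", "B2_1b"))),
      expected_verdict = "fission"),
    fission_B = list(
      config = sim_config(seed = seed, x = 1L, genes_per_chromosome = 140L,
                          codons_per_gene = 100L,
                          fission_events = list(list(chrom = "B2_1",
                                                     rank = 70L)),
                          fission_events_a = list(list(chrom = "A_1",
                                                       rank = 45L)),
                          per_copy_loss_rate = 0.3),
      trios = list(trio_spec("B1_1", c("B2_1a", "B2_1b"))),
      expected_verdict = "fission"),
    fusion_C = list(
      config = sim_config(seed = seed, x = 2L, genes_per_chromosome = 100L,
                          codons_per_gene = 100L,
                          fusion_events = list(c("B2_1", "B2_2")),
                          per_copy_loss_rate = 0.3),
      trios = list(trio_spec("B2_1xB2_2", c("B1_1", "B1_2"))),
      expected_verdict = "fusion"),
    grass_like = list(
      config = sim_config(seed = seed, x = 7L, genes_per_chromosome = 60L,
                          codons_per_gene = 100L,
                          fusion_events = list(c("B2_1", "B2_2"),
                                               c("B2_3", "B2_4")),
                          per_copy_loss_rate = 0.4,
                          loss_timing = "before_merge",
                          translocation_rate = 0.02,
                          inversion_rate = 0.2),
      trios = list(trio_spec("B2_1xB2_2", c("B1_1", "B1_2")),
                   trio_spec("B2_3xB2_4", c("B1_3", "B1_4"))),
      expected_verdict = "fusion")
  )
}

#' Write a simulation to files
#'
#' Emits GFF3 + FASTA per genome, the hit table, and the event log as
#' JSON.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gff_a = file.path(dir, "genome_A.gff3"),
    cds_a = file.path(dir, "genome_A.cds.fa"),
    gff_b = file.path(dir, "genome_B.gff3"),
    cds_b = file.path(dir, "genome_B.cds.fa"),
    hits = file.path(dir, "hits.tsv"),
    log = file.path(dir, "event_log.json"))
  write_annotations(sim$panel_a, paths[["gff_a"]])
  write_cds(sim$panel_a$cds, paths[["cds_a"]])
  write_annotations(sim$panel_b, paths[["gff_b"]])
  write_cds(sim$panel_b$cds, paths[["cds_b"]])
  write_hits(sim$hits, paths[["hits"]])
  jsonlite::write_json(
    list(config = unclass(sim$log$config),
         n_events = sim$log$n_events,
         events = lapply(sim$log$events, function(e) {
           e$mutations <- NULL  # bulky; kept in the in-memory log only
           e
         }),
         losses = sim$log$losses,
         ancestry = sim$log$ancestry),
    paths[["log"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
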