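# Independent oracles, deliberately implemented differently from the
# package internals: a memoized depth-first longest-chain search over the
# anchor DAG, a plain matrix Needleman-Wunsch, and a permutation-based
# Nei-Gojobori pathway enumerator.

# longest max-gap-bounded monotone chain (both orientations) by top-down
# DFS with memoization over successors
oracle_longest_chain <- function(oa, ob, max_gap) {
  one_orientation <- function(ob) {
    n <- length(oa)
    if (n == 0L) return(0L)
    memo <- rep(NA_integer_, n)
    succ <- function(i) {
      which(oa > oa[i] & oa - oa[i] - 1L <= max_gap &
              ob > ob[i] & ob - ob[i] - 1L <= max_gap)
    }
    best_from <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      s <- succ(i)
      val <- if (length(s)) 1L + max(vapply(s, best_from, integer(1)))
             else 1L
      memo[i] <<- val
      val
    }
    max(vapply(seq_len(n), best_from, integer(1)))
  }
  max(one_orientation(ob), one_orientation(-ob))
}

# full Needleman-Wunsch score matrix, linear gaps
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n); f[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      f[i + 1, j + 1] <- max(f[i, j] + s, f[i, j + 1] + gap,
                             f[i + 1, j] + gap)
    }
  }
  f[n + 1, m + 1]
}

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

# synonymous sites of one codon, counting each position's synonymous
# fraction among non-stop single-base changes
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (pos in 1:3) {
    syn <- 0L; ok <- 0L
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon; substr(alt, pos, pos) <- b
      if (oracle_code[[alt]] == "*") next
      ok <- ok + 1L
      if (oracle_code[[alt]] == oracle_code[[codon]]) syn <- syn + 1L
    }
    if (ok > 0L) total <- total + syn / ok
  }
  total
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(oracle_perms(v[-i]), function(r) c(v[i], r))
  }), recursive = FALSE)
}

# pathway-averaged synonymous / nonsynonymous differences for one codon
# pair (stop-free pathways; all pathways if none is stop-free)
oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walks <- lapply(oracle_perms(pos), function(ord) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (oracle_code[[cur]] == oracle_code[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  m <- do.call(rbind, walks)
  use <- m[, 3] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(mean(m[use, 1]), mean(m[use, 2]))
}

# full Nei-Gojobori counts for paired codon vectors
oracle_ng_counts <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  d <- mapply(function(x, y) oracle_pair_diffs(x, y), codons_a, codons_b)
  list(S = S, N = 3 * length(codons_a) - S,
       sd = sum(d[1, ]), nd = sum(d[2, ]))
}

random_codon <- function(n, include_stop_free = TRUE) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!include_stop_free || oracle_code[[cod]] != "*") break
    }
    out[i] <- cod
  }
  out
}
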