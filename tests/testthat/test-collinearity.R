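two_panels <- function(n = 60L) {
  list(a = toy_panel("A", c(c1 = n)), b = toy_panel("B", c(c1 = n)))
}

# hits putting anchor dots at the given 1-based rank coordinates
dot_hits <- function(p, ra, rb) {
  ia <- p$a$genes$id[match(ra - 1L, p$a$genes$order_index)]
  ib <- p$b$genes$id[match(rb - 1L, p$b$genes$order_index)]
  toy_hits(ia, ib)
}

test_that("a perfect diagonal yields one same-orientation block", {
  p <- two_panels()
  blocks <- detect_blocks(dot_hits(p, 1:3, 1:3), p$a, p$b,
                          min_len = 3L, p_threshold = 1,
                          permutations = 200L, seed = 1)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$length, 3L)
  expect_equal(blocks[[1]]$orientation, "same")
})

test_that("an anti-diagonal yields one inverted block", {
  p <- two_panels()
  blocks <- detect_blocks(dot_hits(p, c(1, 2, 3), c(10, 8, 6)), p$a, p$b,
                          min_len = 3L, p_threshold = 1,
                          permutations = 200L, seed = 1)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$length, 3L)
  expect_equal(blocks[[1]]$orientation, "inverted")
})

test_that("max_gap below 1 is a parameter error", {
  p <- two_panels()
  expect_error(detect_blocks(dot_hits(p, 1:3, 1:3), p$a, p$b,
                             max_gap = 0L), "max_gap")
})

test_that("DP block length equals exhaustive longest-chain search on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    oa <- sample.int(80L, n, replace = TRUE)
    ob <- sample.int(80L, n, replace = TRUE)
    gap <- sample(c(3L, 10L, 50L), 1)
    expect_equal(longest_chain_cpp(oa, ob, gap),
                 oracle_longest_chain(oa, ob, gap),
                 info = sprintf("replicate %d, gap %d", rep, gap))
  }
})

test_that("emitted blocks satisfy monotonicity and gap bounds", {
  set.seed(7)
  p <- two_panels(100L)
  for (rep in 1:10) {
    n <- 60L
    hits <- dot_hits(p, sample.int(100L, n, replace = TRUE),
                     sample.int(100L, n, replace = TRUE))
    gap <- sample(c(5L, 20L, 50L), 1)
    blocks <- detect_blocks(hits, p$a, p$b, max_gap = gap, min_len = 3L,
                            p_threshold = 1, permutations = 100L,
                            seed = rep)
    seen <- character()
    for (b in blocks) {
      da <- diff(b$pairs$order_a)
      expect_true(all(da > 0) && all(da - 1 <= gap))
      db <- diff(b$pairs$order_b)
      if (b$orientation == "same") {
        expect_true(all(db > 0) && all(db - 1 <= gap))
      } else {
        expect_true(all(db < 0) && all(-db - 1 <= gap))
      }
      key <- paste(b$pairs$gene_a, b$pairs$gene_b)
      expect_length(intersect(seen, key), 0L)  # anchors used once
      seen <- c(seen, key)
    }
  }
})

test_that("within-genome runs skip self pairs and mirrored duplicates", {
  p <- toy_panel("A", c(c1 = 20L))
  ids <- p$genes$id
  hits <- rbind(toy_hits(ids[1:5], ids[1:5]),          # self-diagonal
                toy_hits(ids[1:5], ids[11:15]),
                toy_hits(ids[11:15], ids[1:5]))        # mirror
  dots <- protochrom:::anchor_dots(filter_hits(hits), p, p)
  expect_equal(nrow(dots), 5L)
  expect_true(all(dots$order_a < dots$order_b))
})

test_that("a long block among few anchors is significant, a trivial chain is not", {
  # 20 of 30 anchors in one chain on 1000-gene chromosomes
  p_long <- block_significance(20L, 30L, 1000L, 1000L,
                               permutations = 300L, seed = 1)
  expect_lt(p_long, 0.05)
  # a length-2 chain is expected by chance among 30 anchors
  p_triv <- block_significance(2L, 30L, 1000L, 1000L,
                               permutations = 300L, seed = 1)
  expect_gt(p_triv, 0.5)
  expect_error(block_significance(5L, 10L, 100L, 100L,
                                  permutations = 0L), "permutations")
  expect_warning(block_significance(5L, 10L, 100L, 100L,
                                    permutations = 50L, seed = 1),
                 "100 permutations")
})

test_that("permutation P-values are deterministic given a seed", {
  p1 <- block_significance(10L, 40L, 500L, 500L, permutations = 200L,
                           seed = 99)
  p2 <- block_significance(10L, 40L, 500L, 500L, permutations = 200L,
                           seed = 99)
  expect_identical(p1, p2)
})

test_that("block census counts blocks and pairs above each threshold", {
  mk <- function(len) toy_block("c1", "c2",
                                sprintf("a%d", seq_len(len) + 1000),
                                sprintf("b%d", seq_len(len) + 2000))
  blocks <- lapply(c(3L, 12L, 60L), mk)
  cen <- block_census(blocks)
  expect_equal(cen$block_count, c(2L, 2L, 1L, 1L))
  expect_equal(cen$gene_pairs, c(72L, 72L, 60L, 60L))
  expect_equal(attr(cen, "largest_block_length"), 60L)
  # monotone non-increasing in threshold
  expect_true(all(diff(cen$block_count) <= 0))
  expect_true(all(diff(cen$gene_pairs) <= 0))
  empty <- block_census(list())
  expect_true(all(empty$block_count == 0L) && all(empty$gene_pairs == 0L))
})

test_that("census matches planted truth on a simulated genome pair", {
  pr <- scenario_presets(seed = 5)$fusion_C
  sim <- simulate_genomes(pr$config)
  blocks <- detect_blocks(filter_hits(sim$hits), sim$panel_a, sim$panel_b,
                          permutations = 300L, seed = 5)
  cen <- block_census(blocks)
  # 2 ancestral chromosomes x 2 subgenome copies = 4 planted blocks, all
  # longer than 50 anchors at 30% loss of 100-gene chromosomes
  expect_equal(cen$block_count[cen$threshold == 50], 4L)
  expect_equal(cen$block_count[cen$threshold == 4], 4L)
})
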