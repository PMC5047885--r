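# the Ac19 worked example: one end of the query chromosome Ac19 shows
# collinearity with three subject chromosomes (107, 51 and 135 collinear
# genes); Os02 shares 45 of its 107 query genes with Os06 but only 5
# with Os04
ac19_blocks <- function() {
  q <- sprintf("q%03d", 1:400)
  os02 <- q[1:107]
  os06 <- c(q[1:45], q[200:289])          # 45 shared with Os02, 135 total
  os04 <- c(q[50:54], q[300:345])         # 5 shared with Os02, 51 total
  mk <- function(sub, genes) toy_block("Ac19", sub, genes,
                                       sprintf("%s_g%d", sub,
                                               seq_along(genes)))
  list(mk("Os02", os02), mk("Os06", os06), mk("Os04", os04))
}

test_that("Ks medians classify blocks into the documented zones", {
  blk <- toy_block("c1", "c2", c("a1", "a2"), c("b1", "b2"))
  expect_equal(classify_by_ks(blk, 1.05)$label, "orthologous")
  expect_equal(classify_by_ks(blk, 1.5)$label, "outparalogous")
  expect_equal(classify_by_ks(blk, 1.30)$label, "ambiguous")
  expect_error(classify_by_ks(blk, 1.0, ortho_window = c(1.2, 0.9)),
               "increasing interval")
  expect_error(classify_by_ks(blk, NA_real_), "finite")
})

test_that("raising the Ks median never promotes out-paralogous to orthologous", {
  blk <- toy_block("c1", "c2", "a1", "b1")
  grid <- seq(0.5, 2.0, by = 0.01)
  labels <- vapply(grid, function(m) classify_by_ks(blk, m)$label,
                   character(1))
  expect_lt(max(grid[labels == "orthologous"]),
            min(grid[labels == "outparalogous"]))
})

test_that("shared collinear genes separate co-orthologs from the out-paralog", {
  res <- resolve_by_sharing("Ac19", c("Os02", "Os04", "Os06"),
                            ac19_blocks())
  lab <- setNames(res$label, res$chrom)
  expect_equal(lab[["Os02"]], "orthologous")
  expect_equal(lab[["Os06"]], "orthologous")
  expect_equal(lab[["Os04"]], "outparalogous")
  expect_equal(res$n_anchors[res$chrom == "Os02"], 107L)
  share <- attr(res, "share")
  expect_equal(share["Os02", "Os04"], 5 / 107)
  # reported percentage, half-up to one decimal: 5/107 prints as 4.7
  expect_equal(protochrom:::pct1(share["Os02", "Os04"]), 4.7)
  expect_equal(protochrom:::pct1(share["Os02", "Os06"]), 42.1)  # 45/107
})

test_that("sharing resolution is invariant to candidate order and handles edge cases", {
  blocks <- ac19_blocks()
  r1 <- resolve_by_sharing("Ac19", c("Os02", "Os04", "Os06"), blocks)
  r2 <- resolve_by_sharing("Ac19", c("Os06", "Os02", "Os04"), blocks)
  expect_equal(r1$label[order(r1$chrom)], r2$label[order(r2$chrom)])
  # full mutual sharing: both co-orthologs
  twin <- list(toy_block("q", "s1", sprintf("g%d", 1:30),
                         sprintf("x%d", 1:30)),
               toy_block("q", "s2", sprintf("g%d", 1:30),
                         sprintf("y%d", 1:30)))
  rt <- resolve_by_sharing("q", c("s1", "s2"), twin)
  expect_true(all(rt$label == "orthologous"))
  expect_warning(resolve_by_sharing("q", c("s1", "s2", "s3"), twin),
                 "zero anchors.*s3")
  expect_error(resolve_by_sharing("q", "s1", twin), "two candidates")
})

test_that("sharing resolution recovers planted WGD pairs against an older duplicate", {
  hitsn <- 0L
  for (seed in 1:40) {
    cfg <- sim_config(seed = seed, x = 1L, genes_per_chromosome = 80L,
                      codons_per_gene = 30L, per_copy_loss_rate = 0.3,
                      ancient_dup = TRUE, ks_ancient = 1.5)
    sim <- simulate_genomes(cfg)
    blocks <- detect_blocks(filter_hits(sim$hits), sim$panel_a,
                            sim$panel_b, permutations = 100L, seed = seed)
    res <- suppressWarnings(
      resolve_by_sharing("A_1", c("B1_1", "B2_1", "B1_2"), blocks))
    lab <- setNames(res$label, res$chrom)
    ok <- identical(unname(lab[c("B1_1", "B2_1")]),
                    c("orthologous", "orthologous")) &&
      (!"B1_2" %in% names(lab) || lab[["B1_2"]] == "outparalogous")
    hitsn <- hitsn + ok
  }
  expect_gte(hitsn, 38L)  # >= 95% of replicates
})

test_that("correspondence maps honor the anchor threshold", {
  cls <- list(
    toy_classification(toy_block("Ac08", "Os10", sprintf("a%d", 1:30),
                                 sprintf("b%d", 1:30)), "orthologous"),
    toy_classification(toy_block("Ac15", "Os10", sprintf("c%d", 1:25),
                                 sprintf("d%d", 1:25)), "orthologous"),
    toy_classification(toy_block("Ac01", "Os10", sprintf("e%d", 1:3),
                                 sprintf("f%d", 1:3)), "orthologous"),
    toy_classification(toy_block("Ac09", "Os10", sprintf("g%d", 1:40),
                                 sprintf("h%d", 1:40)), "outparalogous"))
  map <- build_correspondence(cls, min_anchor = 10L)
  expect_named(map, "Os10")
  expect_setequal(names(map$Os10), c("Ac08", "Ac15"))
  expect_equal(map$Os10[["Ac08"]], 30L)
  expect_length(build_correspondence(list()), 0L)
})

test_that("correspondence on simulated genomes equals planted segment ancestry", {
  pr <- scenario_presets(seed = 21)$grass_like
  sim <- simulate_genomes(pr$config)
  res <- run_pipeline(sim$panel_a, sim$panel_b, sim$hits,
                      trios = pr$trios, seed = 21,
                      params = list(permutations = 200L))
  map <- res$map
  expect_setequal(names(map$B1_5), "A_5")
  expect_setequal(names(map$B2_1xB2_2), c("A_1", "A_2"))
  expect_setequal(names(map$B2_3xB2_4), c("A_3", "A_4"))
})

test_that("orthology depth histograms behave at the extremes and in between", {
  panel <- toy_panel("A", c(c1 = 50L))
  dc <- depth_check(list(), panel)
  expect_equal(sum(dc$histogram), 50L)
  expect_equal(unname(dc$histogram[["0"]]), 50L)   # empty map: all depth 0
  # without gene loss every retained gene sits at depth 2
  cfg <- sim_config(seed = 3, x = 2L, genes_per_chromosome = 60L,
                    codons_per_gene = 40L)
  sim <- simulate_genomes(cfg)
  res <- run_pipeline(sim$panel_a, sim$panel_b, sim$hits, seed = 3,
                      params = list(permutations = 200L))
  dc2 <- depth_check(res$classifications, sim$panel_a)
  expect_equal(unname(dc2$histogram[["2"]]), 120L)
  # per-copy loss 0.4: depth ~ Binomial(2, 0.6) within 3 s.e.
  cfg3 <- sim_config(seed = 8, x = 2L, genes_per_chromosome = 100L,
                     codons_per_gene = 40L, per_copy_loss_rate = 0.4)
  sim3 <- simulate_genomes(cfg3)
  res3 <- run_pipeline(sim3$panel_a, sim3$panel_b, sim3$hits, seed = 8,
                       params = list(permutations = 200L))
  dc3 <- depth_check(res3$classifications, sim3$panel_a)
  n <- 200
  for (d in 0:2) {
    expe <- choose(2, d) * 0.6^d * 0.4^(2 - d)
    se <- sqrt(expe * (1 - expe) / n)
    expect_lt(abs(dc3$histogram[[as.character(d)]] / n - expe), 3 * se,
              label = sprintf("depth %d", d))
  }
})
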