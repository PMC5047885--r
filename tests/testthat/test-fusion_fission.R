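# correspondence sets for the two canonical fusion trios (Os02 from
# Os04 + Os06, Os03 from Os07 + Os10)
rice_like_map <- function() {
  cnt <- function(ch) setNames(rep(30L, length(ch)), ch)
  toy_map(
    Os02 = cnt(c("Ac03", "Ac05", "Ac06", "Ac19", "Ac20", "Ac21", "Ac22")),
    Os04 = cnt(c("Ac03", "Ac20", "Ac21")),
    Os06 = cnt(c("Ac05", "Ac06", "Ac19", "Ac22")),
    Os03 = cnt(c("Ac01", "Ac07", "Ac08", "Ac09", "Ac15", "Ac18")),
    Os07 = cnt(c("Ac01", "Ac09", "Ac18")),
    Os10 = cnt(c("Ac08", "Ac15")))
}

test_that("trio specs validate their members", {
  expect_error(trio_spec("c1", c("c2", "c2")), "distinct")
  expect_error(trio_spec("c1", c("c1", "c2")), "cannot be one of the parts")
})

test_that("disjoint part correspondences covering the merged chromosome read as fusion", {
  map <- rice_like_map()
  v1 <- test_trio(trio_spec("Os02", c("Os04", "Os06")), map)
  expect_equal(v1$verdict, "fusion")
  expect_equal(v1$jaccard_parts, 0)
  expect_equal(v1$coverage, 1)
  v2 <- test_trio(trio_spec("Os03", c("Os07", "Os10")), map)
  expect_equal(v2$verdict, "fusion")
  expect_equal(v2$jaccard_parts, 0)
})

test_that("the trio test is symmetric in the two parts", {
  map <- rice_like_map()
  v1 <- test_trio(trio_spec("Os02", c("Os04", "Os06")), map)
  v2 <- test_trio(trio_spec("Os02", c("Os06", "Os04")), map)
  expect_equal(v1$verdict, v2$verdict)
  expect_equal(v1$jaccard_parts, v2$jaccard_parts)
  expect_equal(v1$coverage, v2$coverage)
})

test_that("shared part correspondences within the merged set read as fission", {
  map <- toy_map(P1 = c(S1 = 40L), P2 = c(S1 = 25L), P3 = c(S1 = 30L))
  v <- test_trio(trio_spec("P1", c("P2", "P3")), map)
  expect_equal(v$verdict, "fission")
  expect_equal(v$jaccard_parts, 1)
})

test_that("missing correspondence gives an undetermined verdict with a reason", {
  map <- toy_map(P1 = c(S1 = 40L), P2 = c(S1 = 25L))
  v <- test_trio(trio_spec("P1", c("P2", "P3")), map)
  expect_equal(v$verdict, "undetermined")
  expect_match(v$reason, "empty correspondence")
})

test_that("ancestral chromosome counts follow the event algebra", {
  fus <- function() structure(list(verdict = "fusion"),
                              class = "trio_verdict")
  fis <- function() structure(list(verdict = "fission"),
                              class = "trio_verdict")
  und <- function() structure(list(verdict = "undetermined"),
                              class = "trio_verdict")
  # 12 observed chromosomes, two fusions: x = 7, 2n = 14 before the
  # tetraploidization and 28 after
  r <- infer_ancestral_count(12L, list(fus(), fus()))
  expect_equal(r$x, 7)
  expect_equal(r$n_pre_wgd, 14)
  expect_equal(r$n_post_wgd, 28)
  # planted x = 5 with two fissions observed as 12 chromosomes
  r2 <- infer_ancestral_count(12L, list(fis(), fis()))
  expect_equal(r2$x, 5)
  # no events, no WGD: x equals the observed count
  r3 <- infer_ancestral_count(12L, list(), wgd = FALSE)
  expect_equal(r3$x, 12)
  # undetermined trios widen to an interval
  r4 <- infer_ancestral_count(12L, list(fus(), und()))
  expect_true(is.na(r4$x))
  expect_equal(r4$x_interval, c(6, 7))
})

test_that("label-independent partitions give x = 7 whenever two disjoint pairs merge", {
  fus <- function() structure(list(verdict = "fusion"),
                              class = "trio_verdict")
  for (labels in list(c("u", "v"), c("chrA", "chrB"))) {
    r <- infer_ancestral_count(12L, list(fus(), fus()))
    expect_equal(r$x, 7)
  }
})

test_that("simulated fission and fusion scenarios are recovered end to end", {
  for (nm in c("fission_A", "fission_B", "fusion_C")) {
    pr <- scenario_presets(seed = 33)[[nm]]
    sim <- simulate_genomes(pr$config)
    res <- run_pipeline(sim$panel_a, sim$panel_b, sim$hits,
                        trios = pr$trios, seed = 33,
                        params = list(permutations = 200L))
    expect_equal(res$verdicts[[1]]$verdict, pr$expected_verdict,
                 info = nm)
  }
})

test_that("CEJ fusion junctions are located within five genes of the truth", {
  pr <- scenario_presets(seed = 19)$fusion_C
  sim <- simulate_genomes(pr$config)
  res <- run_pipeline(sim$panel_a, sim$panel_b, sim$hits,
                      trios = pr$trios, seed = 19,
                      params = list(permutations = 200L))
  v <- res$verdicts[[1]]
  expect_equal(v$verdict, "fusion")
  tr <- fusion_mechanism_trace(v, res$classifications, res$map)
  expect_null(tr$error)
  expect_lte(nrow(tr$junctions), 3L)   # a clean CEJ has few candidates
  true_rank <- sim$log$junctions$junction_rank[1]   # genes left of joint
  # trace reports 0-based order indices flanking the junction
  expect_lte(min(abs(tr$junctions$after_rank - (true_rank - 1L))), 5L)
})

test_that("a single-source merged chromosome has no junction to trace", {
  map <- toy_map(M = c(S1 = 40L), P2 = c(S1 = 40L), P3 = c(S2 = 40L))
  spec <- trio_spec("M", c("P2", "P3"))
  v <- structure(list(spec = spec, corr_merged = "S1", corr_p2 = "S1",
                      corr_p3 = "S2", jaccard_parts = 0, coverage = 1,
                      verdict = "fusion", reason = ""),
                 class = "trio_verdict")
  cls <- list(toy_classification(
    toy_block("S1", "M", sprintf("q%d", 1:20), sprintf("m%d", 1:20)),
    "orthologous"))
  tr <- fusion_mechanism_trace(v, cls, map)
  expect_match(tr$error, "single part")
  expect_error(fusion_mechanism_trace(
    structure(list(verdict = "fission"), class = "trio_verdict"),
    cls, map), "fusion verdict")
})

test_that("a double fusion yields junctions on both merged chromosomes", {
  cfg <- sim_config(seed = 27, x = 4L, genes_per_chromosome = 60L,
                    codons_per_gene = 60L,
                    fusion_events = list(c("B2_1", "B2_2"),
                                         c("B2_3", "B2_4")),
                    per_copy_loss_rate = 0.2)
  sim <- simulate_genomes(cfg)
  trios <- list(trio_spec("B2_1xB2_2", c("B1_1", "B1_2")),
                trio_spec("B2_3xB2_4", c("B1_3", "B1_4")))
  res <- run_pipeline(sim$panel_a, sim$panel_b, sim$hits, trios = trios,
                      seed = 27, params = list(permutations = 200L))
  for (i in 1:2) {
    expect_equal(res$verdicts[[i]]$verdict, "fusion")
    tr <- fusion_mechanism_trace(res$verdicts[[i]], res$classifications,
                                 res$map)
    expect_lte(nrow(tr$junctions), 3L)
    true_rank <- sim$log$junctions$junction_rank[i]
    expect_lte(min(abs(tr$junctions$after_rank - (true_rank - 1L))), 5L)
  }
})
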