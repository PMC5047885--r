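test_that("configs validate rates, ks values and targets", {
  expect_error(sim_config(per_copy_loss_rate = 1.2), "rates")
  expect_error(sim_config(ks_split = -1), "ks values")
  expect_error(sim_config(ks_split = 0.3, ks_wgd = 0.9), "2 \\* ks_split")
  expect_error(sim_config(x = 0), "positive")
  expect_error(simulate_genomes(
    sim_config(seed = 1, x = 1L, genes_per_chromosome = 20L,
               codons_per_gene = 10L,
               fission_events = list(list(chrom = "B2_1", rank = 50L)))),
    "breakpoint outside")
  expect_error(simulate_genomes(
    sim_config(seed = 1, x = 1L, genes_per_chromosome = 20L,
               codons_per_gene = 10L,
               fusion_events = list(c("B2_1", "B2_9")))),
    "fusion target")
})

test_that("identical seeds give identical genomes, logs and files", {
  cfg <- sim_config(seed = 101, x = 2L, genes_per_chromosome = 40L,
                    codons_per_gene = 30L, per_copy_loss_rate = 0.3,
                    translocation_rate = 0.05, inversion_rate = 0.5)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$panel_a$genes, s2$panel_a$genes)
  expect_identical(s1$panel_b$cds, s2$panel_b$cds)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$log$events, s2$log$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1); p2 <- write_simulation(s2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("all-zero rates without WGD leave the two lineages in the same order", {
  cfg <- sim_config(seed = 5, x = 3L, genes_per_chromosome = 25L,
                    codons_per_gene = 10L, wgd_in_lineage_b = FALSE,
                    ks_split = 0)
  sim <- simulate_genomes(cfg)
  ga <- sim$panel_a$genes; gb <- sim$panel_b$genes
  expect_equal(nrow(ga), nrow(gb))
  expect_equal(sub("^A_", "", ga$id[order(ga$chrom, ga$order_index)]),
               sub("^B_", "", gb$id[order(gb$chrom, gb$order_index)]))
  expect_identical(unname(sim$panel_a$cds[order(names(sim$panel_a$cds))]),
                   unname(sim$panel_b$cds[order(names(sim$panel_b$cds))]))
})

test_that("WGD plus two CEJ fusions turns 14 chromosomes into 12", {
  pr <- scenario_presets(seed = 2)$grass_like
  sim <- simulate_genomes(pr$config)
  expect_length(sim$panel_b$chromosomes, 12L)
  expect_length(sim$panel_a$chromosomes, 7L)
})

test_that("gene counts are conserved up to recorded losses and CEJ trims", {
  cfg <- sim_config(seed = 55, x = 3L, genes_per_chromosome = 50L,
                    codons_per_gene = 20L, per_copy_loss_rate = 0.4,
                    fusion_events = list(c("B2_1", "B2_2")),
                    translocation_rate = 0.05)
  sim <- simulate_genomes(cfg)
  n_anc <- 150L
  expect_equal(nrow(sim$panel_b$genes),
               2L * n_anc - length(sim$log$losses) -
                 length(sim$log$trimmed))
  expect_equal(nrow(sim$panel_a$genes), n_anc)
})

test_that("replaying the event log reproduces the simulation exactly", {
  cfg <- sim_config(seed = 77, x = 2L, genes_per_chromosome = 30L,
                    codons_per_gene = 20L, per_copy_loss_rate = 0.3,
                    fusion_events = list(c("B2_1", "B2_2")),
                    inversion_rate = 0.5, translocation_rate = 0.05,
                    decoy_rate = 0.02)
  sim <- simulate_genomes(cfg)
  rep1 <- replay_log(sim$log)
  expect_identical(rep1$panel_a, sim$panel_a)
  expect_identical(rep1$panel_b, sim$panel_b)
  expect_identical(rep1$hits, sim$hits)
  # explicit ancestor argument
  rep2 <- replay_log(sim$log, ancestor = sim$log$ancestor)
  expect_identical(rep2$panel_b$cds, sim$panel_b$cds)
})

test_that("an empty event list leaves the ancestor untouched and truncation errors", {
  cfg <- sim_config(seed = 9, x = 1L, genes_per_chromosome = 10L,
                    codons_per_gene = 10L)
  sim <- simulate_genomes(cfg)
  empty <- sim$log
  empty$events <- list(); empty$n_events <- 0L
  out <- replay_log(empty)
  expect_equal(nrow(out$panel_a$genes), 0L)  # no derive events ran
  truncated <- sim$log
  truncated$events <- truncated$events[-length(truncated$events)]
  expect_error(replay_log(truncated), "incomplete")
  mismatched <- sim$log
  mismatched$ancestor$cds <- mismatched$ancestor$cds[-1]
  expect_error(replay_log(mismatched), "does not match")
})

test_that("presets encode their namesake scenarios", {
  pre <- scenario_presets(seed = 4)
  expect_setequal(names(pre), c("fission_A", "fission_B", "fusion_C",
                                "grass_like"))
  simA <- simulate_genomes(pre$fission_A$config)
  fis <- Filter(function(e) e$type == "fission", simA$log$events)
  expect_length(fis, 1L)
  expect_length(Filter(function(e) e$type == "fusion", simA$log$events),
                0L)
  gl <- pre$grass_like$config
  expect_equal(gl$x, 7L)
  expect_true(gl$wgd_in_lineage_b)
  expect_length(gl$fusion_events, 2L)
  expect_equal(gl$per_copy_loss_rate, 0.4)
  expect_equal(gl$loss_timing, "before_merge")
})

test_that("hit tables reflect true homology with orthologs outscoring out-paralogs", {
  cfg <- sim_config(seed = 13, x = 1L, genes_per_chromosome = 30L,
                    codons_per_gene = 20L, ancient_dup = TRUE,
                    ancient_loss_rate = 0)
  sim <- simulate_genomes(cfg)
  h <- sim$hits
  expect_true(all(h$evalue <= 1e-10))
  one <- h[h$query == "A_anc1_g001", ]
  orth <- one$bitscore[one$subject %in% c("s1_anc1_g001", "s2_anc1_g001")]
  outp <- one$bitscore[one$subject %in% c("s1_anc1_g001d",
                                          "s2_anc1_g001d")]
  expect_length(orth, 2L)
  expect_length(outp, 2L)
  expect_true(min(orth) > max(outp))
})

test_that("loss timing scenarios both reach the configured loss fraction", {
  for (timing in c("before_merge", "after_merge")) {
    cfg <- sim_config(seed = 61, x = 2L, genes_per_chromosome = 100L,
                      codons_per_gene = 10L, per_copy_loss_rate = 0.4,
                      fusion_events = list(c("B2_1", "B2_2")),
                      loss_timing = timing)
    sim <- simulate_genomes(cfg)
    frac <- length(sim$log$losses) / 400
    expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 400), label = timing)
  }
})
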