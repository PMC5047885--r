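# shared settings for the analysis drivers: one seeded grass-like study
# (x = 7 ancestor, tetraploidization, two CEJ fusions, 40% per-copy
# loss) analysed end to end. Source this from the numbered scripts.

library(protochrom)

SEED <- 42L
SIM_DIR <- "results/simulated"
RUN_DIR <- "results/run"
CACHE <- "results/pipeline_cache.rds"

preset <- scenario_presets(seed = SEED)$grass_like

# the full pipeline result, computed once and reused by later drivers
pipeline_cached <- function() {
  if (file.exists(CACHE)) return(readRDS(CACHE))
  panel_a <- read_annotations(file.path(SIM_DIR, "genome_A.gff3"), "A")
  panel_a$cds <- read_cds(file.path(SIM_DIR, "genome_A.cds.fa"), panel_a)
  panel_b <- read_annotations(file.path(SIM_DIR, "genome_B.gff3"), "B")
  panel_b$cds <- read_cds(file.path(SIM_DIR, "genome_B.cds.fa"), panel_b)
  hits <- read_hits(file.path(SIM_DIR, "hits.tsv"))
  res <- run_pipeline(panel_a, panel_b, hits, trios = preset$trios,
                      seed = SEED, out_dir = RUN_DIR)
  saveRDS(res, CACHE)
  res
}
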