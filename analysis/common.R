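## Shared setup for the analysis drivers: one master seed, the demo study
## conditions, and lazy builders for the simulated tracks each stage needs.
## Every driver regenerates its inputs deterministically from the seed, so
## the scripts can be run independently and in any order.

suppressMessages(library(smcreg))

MASTER_SEED <- as.integer(Sys.getenv("SMCREG_SEED", "1"))
CONFIG <- default_config(seed = MASTER_SEED)
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

LAYOUT <- make_genome(CONFIG$genome)

sim_track_for <- function(factor) {
  i <- match(factor, CONFIG$chip$factors)
  reads <- simulate_chip_reads(LAYOUT, factor, depth = CONFIG$chip$depth,
                               read_len = CONFIG$chip$read_len,
                               seed = smcreg:::derive_seed(MASTER_SEED,
                                                           10L + i))
  build_track(reads, bin_size = CONFIG$chip$bin_size,
              extend_len = CONFIG$chip$extend_len)
}

occupancy_for <- function(factor, control_track) {
  call_occupied_regions(sim_track_for(factor), control_track,
                        factor = factor,
                        p_cutoff = CONFIG$calling$p_cutoff,
                        min_width = CONFIG$calling$min_width,
                        merge_gap = CONFIG$calling$merge_gap)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
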