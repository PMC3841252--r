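#!/usr/bin/env Rscript

## Stage 1 -- build the synthetic study: a 20 Mb genome carrying 20
## super-enhancer constituent clusters, 300 typical enhancer
## constituents, genes with promoters, and heterochromatin domains, plus
## the knockdown RNA-seq experiment.  Writes the planted truth so later
## stages can be audited against it.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "common.R"))

validate_layout(LAYOUT)
message(sprintf(
  "genome: %s; %d SE clusters, %d typical constituents, %d genes, %d heterochromatin domains",
  paste(sprintf("%s=%.0fMb", names(LAYOUT$chrom_sizes),
                LAYOUT$chrom_sizes / 1e6), collapse = ", "),
  length(LAYOUT$se_clusters), length(LAYOUT$typical_constituents),
  nrow(LAYOUT$genes), length(LAYOUT$heterochromatin)))

expr <- simulate_knockdown_expression(
  LAYOUT, effects = CONFIG$expression$effects,
  n_replicates = CONFIG$expression$n_replicates,
  dispersion = CONFIG$expression$dispersion,
  seed = smcreg:::derive_seed(MASTER_SEED, 99L))
message(sprintf("expression: %d genes x %d samples (%s)",
                nrow(expr$counts), ncol(expr$counts),
                paste(unique(expr$samples$condition), collapse = ", ")))

dir.create(file.path(RESULTS, "genome"), showWarnings = FALSE)
paths <- write_fixture(LAYOUT, reads = list(), expression = expr,
                       dir = file.path(RESULTS, "genome"))
message("planted truth written under results/genome/: ",
        paste(basename(paths), collapse = ", "))
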