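#!/usr/bin/env Rscript

## Stage 4 -- super-enhancer calling: stitch the OSN-defined enhancer
## constituents (12.5 kb), rank stitched enhancers by
## background-subtracted MED1 signal, split super from typical at the
## ranked-curve inflection, and quantify how much more MED1/NIPBL/
## CAPH2/SMC1 signal super-enhancers carry.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "common.R"))

wce <- sim_track_for("WCE")
occ <- sapply(c("OCT4", "SOX2", "NANOG"), occupancy_for,
              control_track = wce, simplify = FALSE)
enhancers <- define_enhancers(occ$OCT4, occ$SOX2, occ$NANOG)

med1 <- sim_track_for("MED1")
st <- stitch_constituents(enhancers, CONFIG$se$stitch_distance)
pa <- partition_super_enhancers(rank_by_signal(st, med1, wce))
tab <- partition_table(pa)
write_tsv(tab, "stitched_enhancers.tsv")

rec <- planted_se_recovery(pa, LAYOUT)
message(sprintf(
  "%d super-enhancers vs %d typical; planted recovery %.0f%%, typical misclassified %.1f%%",
  sum(pa$class == "super"), sum(pa$class == "typical"),
  100 * rec$se_recovered, 100 * rec$typical_misclassified))

folds <- do.call(rbind, lapply(CONFIG$se$fold_factors, function(f) {
  tr <- sim_track_for(f)
  data.frame(factor = f,
             fold_enhancers = fold_difference(tr, pa, "enhancers"),
             fold_constituents = fold_difference(tr, pa, "constituents"))
}))
write_tsv(folds, "fold_differences.tsv")
for (i in seq_len(nrow(folds)))
  message(sprintf(
    "%s: %.1f-fold more signal at super-enhancers, %.2f-fold denser at their constituents",
    folds$factor[i], folds$fold_enhancers[i], folds$fold_constituents[i]))
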