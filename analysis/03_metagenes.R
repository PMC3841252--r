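#!/usr/bin/env Rscript

## Stage 3 -- metagene profiles and the POL II-ranked gene matrix:
## average CAPH2/SMC1/NIPBL density over enhancers and promoters (+/-1 kb
## flanks, bodies rescaled to a common axis) and rank genes by POL II
## TSS density to show that SMC-complex occupancy tracks transcription.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "common.R"))

wce <- sim_track_for("WCE")
occ <- sapply(c("OCT4", "SOX2", "NANOG", "TBP", "POL2"),
              occupancy_for, control_track = wce, simplify = FALSE)
enhancers <- define_enhancers(occ$OCT4, occ$SOX2, occ$NANOG)
promoters <- define_promoters(occ$TBP, occ$POL2)

tracks <- sapply(c("CAPH2", "SMC1", "NIPBL", "POL2"), sim_track_for,
                 simplify = FALSE)

rows <- list()
for (f in c("CAPH2", "SMC1", "NIPBL")) {
  for (rn in c("enhancers", "promoters")) {
    set <- if (rn == "enhancers") enhancers else promoters
    pr <- metagene_profile(tracks[[f]], set,
                           flank_bp = CONFIG$metagene$flank_enhancer,
                           body_bins = CONFIG$metagene$body_bins)
    rows[[paste(f, rn)]] <- cbind(factor = f, region_class = rn,
                                  as.data.frame(pr))
    message(sprintf(
      "%s at %s: peak %.3f RPM/bp over %d regions (flank baseline %.3f)",
      f, rn, max(pr$density), pr$n_regions, pr$density[1]))
  }
}
write_tsv(do.call(rbind, rows), "metagene_profiles.tsv")

mat <- ranked_gene_matrix(tracks, LAYOUT$genes, window = 1000,
                          rank_factor = "POL2")
write_tsv(mat, "polii_ranked_gene_matrix.tsv")
top <- head(mat, 100); bottom <- tail(mat, 100)
message(sprintf(
  "CAPH2 density at the 100 most POL II-loaded genes: %.3f RPM/bp vs %.3f at the 100 least",
  mean(top$CAPH2), mean(bottom$CAPH2)))
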