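#!/usr/bin/env Rscript

## Stage 2 -- ChIP-seq coverage and region classes: simulate the factor
## panel, call occupied regions against the whole-cell-extract control,
## and derive the enhancer (OCT4+SOX2+NANOG), promoter (TBP+POL II) and
## heterochromatin (H3K9me3 or H4K20me3) classes.  The headline
## observation to reproduce: condensin II (CAPH2) and cohesin (SMC1)
## occupy active enhancers and promoters, not heterochromatin.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "common.R"))

wce <- sim_track_for("WCE")
occ <- sapply(c("OCT4", "SOX2", "NANOG", "TBP", "POL2", "H3K9me3",
                "H4K20me3", "CAPH2", "SMC1"),
              occupancy_for, control_track = wce, simplify = FALSE)

enhancers <- define_enhancers(occ$OCT4, occ$SOX2, occ$NANOG)
promoters <- define_promoters(occ$TBP, occ$POL2)
het <- define_heterochromatin(occ$H3K9me3, occ$H4K20me3)

caph2 <- sim_track_for("CAPH2"); smc1 <- sim_track_for("SMC1")
dens <- function(track, set)
  mean(region_signal(track, set$regions, "density_rpm_per_bp"))
tab <- data.frame(
  region_class = c("enhancers", "promoters", "heterochromatin"),
  n_regions = c(length(enhancers$regions), length(promoters$regions),
                length(het$regions)),
  caph2_density = c(dens(caph2, enhancers), dens(caph2, promoters),
                    dens(caph2, het)),
  smc1_density = c(dens(smc1, enhancers), dens(smc1, promoters),
                   dens(smc1, het)))
write_tsv(tab, "occupancy_by_region_class.tsv")

message(sprintf(
  "CAPH2 density at enhancers is %.0fx heterochromatin (%.3f vs %.4f RPM/bp); SMC1 %.0fx",
  tab$caph2_density[1] / tab$caph2_density[3], tab$caph2_density[1],
  tab$caph2_density[3], tab$smc1_density[1] / tab$smc1_density[3]))

co <- co_occupied_genes(occ$CAPH2, occ$SMC1, LAYOUT$genes,
                        window = CONFIG$genes$co_occupancy_window)
message(sprintf("%d of %d genes are co-occupied by CAPH2 and SMC1 near the TSS",
                length(co), nrow(LAYOUT$genes)))

for (nm in c("enhancers", "promoters", "heterochromatin"))
  write_bed(get(switch(nm, heterochromatin = "het", nm))$regions,
            file.path(RESULTS, paste0(nm, ".bed")))
writeLines(co, file.path(RESULTS, "co_occupied_genes.txt"))
message("region BED files and co-occupied gene list written under results/")
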