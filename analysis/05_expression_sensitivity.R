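#!/usr/bin/env Rscript

## Stage 5 -- knockdown expression sensitivity: log2 fold changes versus
## the shGFP control (the two CAPH2 hairpins pooled), Spearman agreement
## between knockdowns, the ranking of co-occupied genes by average fold
## change, and the super- vs typical-enhancer gene class comparison.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "common.R"))

expr <- simulate_knockdown_expression(
  LAYOUT, effects = CONFIG$expression$effects,
  n_replicates = CONFIG$expression$n_replicates,
  dispersion = CONFIG$expression$dispersion,
  seed = smcreg:::derive_seed(MASTER_SEED, 99L))

fc1 <- fold_changes(expr, "shCAPH2_1")
fc2 <- fold_changes(expr, "shCAPH2_2")
fc_caph2 <- fold_changes(expr, c("shCAPH2_1", "shCAPH2_2"))
fc_smc1 <- fold_changes(expr, "shSMC1")
message(sprintf("Spearman CAPH2 #1 vs #2: %.3f; CAPH2 avg vs SMC1: %.3f",
                spearman(fc1, fc2), spearman(fc_caph2, fc_smc1)))

write_tsv(data.frame(gene_id = names(fc_caph2), caph2_sh1 = unname(fc1),
                     caph2_sh2 = unname(fc2),
                     caph2_pooled = unname(fc_caph2),
                     smc1 = unname(fc_smc1)), "fold_changes.tsv")

## class comparison against the data-derived enhancer-gene assignment
wce <- sim_track_for("WCE")
occ <- sapply(c("OCT4", "SOX2", "NANOG"), occupancy_for,
              control_track = wce, simplify = FALSE)
st <- stitch_constituents(define_enhancers(occ$OCT4, occ$SOX2, occ$NANOG),
                          CONFIG$se$stitch_distance)
pa <- partition_super_enhancers(rank_by_signal(st, sim_track_for("MED1"),
                                               wce))
assign <- genes_of_enhancers(pa$ranked$spans, LAYOUT$genes,
                             CONFIG$genes$enhancer_gene_max_distance)
se_genes <- unique(assign$gene_id[pa$class == "super" &
                                  !is.na(assign$gene_id)])
te_genes <- setdiff(unique(assign$gene_id[pa$class == "typical" &
                                          !is.na(assign$gene_id)]),
                    se_genes)
for (kd in c("caph2", "smc1")) {
  fc <- if (kd == "caph2") fc_caph2 else fc_smc1
  cmp <- compare_gene_classes(fc, se_genes, te_genes)
  message(sprintf(
    "%s knockdown: SE-gene median lfc %.2f vs TE-gene %.2f (Welch two-tailed p = %.2e)",
    toupper(kd), cmp$box_a$median, cmp$box_b$median, cmp$p_value))
}

co <- co_occupied_genes(occupancy_for("CAPH2", wce),
                        occupancy_for("SMC1", wce), LAYOUT$genes,
                        CONFIG$genes$co_occupancy_window)
ranked <- rank_genes_by_avg_fc(list(fc1, fc2, fc_smc1),
                               intersect(co, names(fc1)))
write_tsv(data.frame(rank = seq_along(ranked), gene_id = ranked,
                     avg_fc = rowMeans(cbind(fc1[ranked], fc2[ranked],
                                             fc_smc1[ranked]))),
          "co_occupied_genes_ranked.tsv")
message(sprintf("most knockdown-sensitive co-occupied gene: %s", ranked[1]))
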