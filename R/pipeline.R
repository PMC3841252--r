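#' Default end-to-end pipeline configuration
#'
#' One master seed drives every stage; all other values are the demo
#' study conditions (20 Mb genome, 1e6 reads per factor, 50 bp bins with
#' 200 bp fragment extension, 12.5 kb stitching).  The ChIP panel
#' includes a `CAPH2_shNIPBL` profile -- condensin II after knockdown of
#' the loading factor, with enhancer/promoter enrichment reduced to 40%
#' -- used by the rank-normalization stage.
#'
#' @param seed master integer seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  profiles <- default_factor_profiles()
  profiles$CAPH2_shNIPBL <- enrichment_rule(1, c(
    typical_constituent = 4, se_constituent = 10, promoter = 4,
    gene_body = 1, heterochromatin = 0), fold_cv = 0.8)
  list(
    seed = seed,
    genome = layout_config(factor_profiles = profiles,
                           seed = derive_seed(seed, 1L)),
    chip = list(
      factors = c("OCT4", "SOX2", "NANOG", "MED1", "NIPBL", "SMC1",
                  "CAPH2", "TBP", "POL2", "H3K9me3", "H4K20me3",
                  "CAPH2_shNIPBL", "WCE"),
      depth = 1e6, read_len = 36, extend_len = 200, bin_size = 50),
    calling = list(p_cutoff = 1e-5, min_width = 100, merge_gap = 200,
                   factors = c("OCT4", "SOX2", "NANOG", "TBP", "POL2",
                               "H3K9me3", "H4K20me3", "CAPH2", "SMC1")),
    se = list(stitch_distance = 12500, rank_factor = "MED1",
              control = "WCE",
              fold_factors = c("MED1", "NIPBL", "CAPH2", "SMC1")),
    metagene = list(flank_enhancer = 1000, flank_se = 3000,
                    body_bins = 60),
    genes = list(co_occupancy_window = 2500,
                 enhancer_gene_max_distance = 50000),
    expression = list(
      n_replicates = 3, dispersion = 0.1, pseudocount = 1,
      effects = list(mean_lfc = c(se = -1, te = -0.3, other = 0),
                     sd_lfc = 0.5, complex_sd = 0.25, shrna_sd = 0.15))
  )
}

stage_msg <- function(stage, fmt, ...)
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

#' Run the full analysis pipeline
#'
#' Executes simulate -> coverage -> occupancy -> region classes ->
#' metagenes -> super-enhancers -> rank normalization -> expression, and
#' writes region BED files, ranked/metagene/fold-change TSVs, a
#' machine-readable `summary.json` and a `manifest.json` of MD5 content
#' hashes.  Identical seeds give byte-identical summaries.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create %s", outdir)
  chip <- config$chip

  stage_msg("simulate", "genome layout (seed %d)", config$genome$seed)
  layout <- make_genome(config$genome)
  validate_layout(layout)
  stage_msg("simulate", "%d SE clusters, %d typical constituents, %d genes",
            length(layout$se_clusters), length(layout$typical_constituents),
            nrow(layout$genes))

  tracks <- list()
  for (i in seq_along(chip$factors)) {
    f <- chip$factors[i]
    reads <- simulate_chip_reads(layout, f, depth = chip$depth,
                                 read_len = chip$read_len,
                                 seed = derive_seed(config$seed, 10L + i))
    tracks[[f]] <- build_track(reads, bin_size = chip$bin_size,
                               extend_len = chip$extend_len)
    stage_msg("coverage", "%s: %d reads binned at %d bp", f,
              length(reads), chip$bin_size)
  }

  ctrl <- tracks[[config$se$control]]
  occ <- lapply(config$calling$factors, function(f)
    call_occupied_regions(tracks[[f]], ctrl, factor = f,
                          p_cutoff = config$calling$p_cutoff,
                          min_width = config$calling$min_width,
                          merge_gap = config$calling$merge_gap))
  names(occ) <- config$calling$factors
  for (f in names(occ))
    stage_msg("occupancy", "%s: %d regions", f, length(occ[[f]]$regions))

  enhancers <- define_enhancers(occ$OCT4, occ$SOX2, occ$NANOG)
  promoters <- define_promoters(occ$TBP, occ$POL2)
  heterochrom <- define_heterochromatin(occ$H3K9me3, occ$H4K20me3)
  co_genes <- co_occupied_genes(occ$CAPH2, occ$SMC1, layout$genes,
                                window = config$genes$co_occupancy_window)
  stage_msg("regions", "%d enhancers, %d promoters, %d heterochromatin, %d co-occupied genes",
            length(enhancers$regions), length(promoters$regions),
            length(heterochrom$regions), length(co_genes))
  for (nm in c("enhancers", "promoters", "heterochromatin")) {
    set <- switch(nm, enhancers = enhancers, promoters = promoters,
                  heterochromatin = heterochrom)
    write_bed(set$regions, file.path(outdir, paste0(nm, ".bed")))
  }

  mg <- config$metagene
  profiles <- list()
  for (f in c("CAPH2", "SMC1", "NIPBL")) {
    for (rn in c("enhancers", "promoters")) {
      set <- if (rn == "enhancers") enhancers else promoters
      pr <- metagene_profile(tracks[[f]], set, flank_bp = mg$flank_enhancer,
                             body_bins = mg$body_bins)
      profiles[[paste(f, rn, sep = "_")]] <- pr
    }
  }
  mg_df <- do.call(rbind, lapply(names(profiles), function(nm)
    cbind(profile = nm, as.data.frame(profiles[[nm]]))))
  write.table(mg_df, file.path(outdir, "metagene_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ranked_mat <- ranked_gene_matrix(
    tracks[c("POL2", "CAPH2", "SMC1", "NIPBL")], layout$genes,
    window = 1000, rank_factor = "POL2")
  write.table(ranked_mat, file.path(outdir, "polii_ranked_gene_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("metagene", "%d profiles, gene matrix %d x %d",
            length(profiles), nrow(ranked_mat), ncol(ranked_mat) - 1L)

  stitched <- stitch_constituents(enhancers,
                                  stitch_distance = config$se$stitch_distance)
  ranked <- rank_by_signal(stitched, tracks[[config$se$rank_factor]], ctrl)
  partition <- partition_super_enhancers(ranked)
  ptab <- partition_table(partition)
  write.table(ptab, file.path(outdir, "stitched_enhancers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- list()
  for (f in config$se$fold_factors)
    folds[[f]] <- list(
      enhancers = fold_difference(tracks[[f]], partition, "enhancers"),
      constituents = fold_difference(tracks[[f]], partition, "constituents"))
  recovery <- planted_se_recovery(partition, layout)
  stage_msg("superenhancers",
            "%d super / %d typical; planted SE recovery %.1f%%, typical misclassified %.1f%%",
            sum(partition$class == "super"),
            sum(partition$class == "typical"),
            100 * recovery$se_recovered, 100 * recovery$typical_misclassified)

  rn <- rank_normalize(tracks$CAPH2, tracks$CAPH2_shNIPBL)
  gfp_enh <- region_signal_of_normalized(rn$tracks[[1]], enhancers$regions)
  kd_enh <- region_signal_of_normalized(rn$tracks[[2]], enhancers$regions)
  gfp_pro <- region_signal_of_normalized(rn$tracks[[1]], promoters$regions)
  kd_pro <- region_signal_of_normalized(rn$tracks[[2]], promoters$regions)
  ranknorm_stats <- list(
    enhancer_decrease_p = one_tailed_t(gfp_enh, kd_enh, "greater"),
    promoter_decrease_p = one_tailed_t(gfp_pro, kd_pro, "greater"),
    enhancer_mean_ratio = mean(kd_enh) / mean(gfp_enh),
    promoter_mean_ratio = mean(kd_pro) / mean(gfp_pro))
  stage_msg("ranknorm",
            "CAPH2 after shNIPBL: enhancer signal ratio %.2f (p=%.3g)",
            ranknorm_stats$enhancer_mean_ratio,
            ranknorm_stats$enhancer_decrease_p)

  ex <- config$expression
  expr <- simulate_knockdown_expression(
    layout, effects = ex$effects, n_replicates = ex$n_replicates,
    dispersion = ex$dispersion, seed = derive_seed(config$seed, 99L))
  fc_caph2 <- fold_changes(expr, c("shCAPH2_1", "shCAPH2_2"),
                           pseudocount = ex$pseudocount)
  fc_caph2_1 <- fold_changes(expr, "shCAPH2_1", pseudocount = ex$pseudocount)
  fc_caph2_2 <- fold_changes(expr, "shCAPH2_2", pseudocount = ex$pseudocount)
  fc_smc1 <- fold_changes(expr, "shSMC1", pseudocount = ex$pseudocount)
  assign <- genes_of_enhancers(partition$ranked$spans, layout$genes,
                               max_distance = config$genes$enhancer_gene_max_distance)
  se_genes <- unique(assign$gene_id[partition$class == "super" &
                                    !is.na(assign$gene_id)])
  te_genes <- setdiff(unique(assign$gene_id[partition$class == "typical" &
                                            !is.na(assign$gene_id)]),
                      se_genes)
  cmp_caph2 <- compare_gene_classes(fc_caph2, se_genes, te_genes)
  cmp_smc1 <- compare_gene_classes(fc_smc1, se_genes, te_genes)
  co_ranked <- rank_genes_by_avg_fc(
    list(fc_caph2_1, fc_caph2_2, fc_smc1),
    intersect(co_genes, names(fc_caph2_1)))
  fc_df <- data.frame(gene_id = names(fc_caph2),
                      caph2_pooled = unname(fc_caph2),
                      caph2_sh1 = unname(fc_caph2_1),
                      caph2_sh2 = unname(fc_caph2_2),
                      smc1 = unname(fc_smc1))
  write.table(fc_df, file.path(outdir, "fold_changes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("expression",
            "SE genes (n=%d) mean lfc %.2f vs TE genes (n=%d) %.2f; CAPH2 p=%.3g",
            length(se_genes), cmp_caph2$mean_a, length(te_genes),
            cmp_caph2$mean_b, cmp_caph2$p_value)

  summary <- list(
    seed = config$seed,
    parameters = list(depth = chip$depth, bin_size = chip$bin_size,
                      extend_len = chip$extend_len,
                      stitch_distance = config$se$stitch_distance,
                      p_cutoff = config$calling$p_cutoff),
    region_counts = list(
      enhancers = length(enhancers$regions),
      promoters = length(promoters$regions),
      heterochromatin = length(heterochrom$regions),
      stitched_enhancers = length(partition$class),
      super_enhancers = sum(partition$class == "super"),
      typical_enhancers = sum(partition$class == "typical"),
      co_occupied_genes = length(co_genes)),
    planted_recovery = recovery,
    fold_differences = folds,
    rank_normalization = ranknorm_stats,
    expression = list(
      spearman_caph2_sh1_vs_sh2 = spearman(fc_caph2_1, fc_caph2_2),
      spearman_caph2_avg_vs_smc1 = spearman(fc_caph2, fc_smc1),
      n_se_genes = length(se_genes), n_te_genes = length(te_genes),
      caph2 = summarize_comparison(cmp_caph2),
      smc1 = summarize_comparison(cmp_smc1),
      most_sensitive_co_occupied = head(co_ranked, 10))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(outdir)
  invisible(summary)
}

summarize_comparison <- function(cmp) {
  list(median_se = cmp$box_a$median, median_te = cmp$box_b$median,
       q1_se = cmp$box_a$q1, q3_se = cmp$box_a$q3,
       whisker_low_se = cmp$box_a$whisker_low,
       whisker_high_se = cmp$box_a$whisker_high,
       mean_se = cmp$mean_a, mean_te = cmp$mean_b,
       t = cmp$t, p_value = cmp$p_value)
}

## mean rank-normalized bin value per region (pro-rata over bins)
region_signal_of_normalized <- function(track, regions) {
  cnt <- region_counts0(track,
                        as.character(GenomeInfoDb::seqnames(regions)),
                        GenomicRanges::start(regions) - 1,
                        GenomicRanges::end(regions))
  cnt * track$bin_size / GenomicRanges::width(regions)
}

#' Compare a super-enhancer partition to the planted truth
#'
#' @param partition an `se_partition` from data-derived enhancers.
#' @param layout the generating [make_genome()] layout.
#' @return List with `se_recovered` (fraction of planted clusters whose
#'   span overlaps a called super-enhancer) and `typical_misclassified`
#'   (fraction of planted typical constituents overlapping a called
#'   super-enhancer).
#' @export
planted_se_recovery <- function(partition, layout) {
  super <- partition_spans(partition, "super")
  hit <- vapply(layout$se_clusters, function(cl)
    sum(GenomicRanges::countOverlaps(cl, super)) > 0, TRUE)
  mis <- GenomicRanges::countOverlaps(layout$typical_constituents,
                                      super) > 0
  list(se_recovered = mean(hit),
       typical_misclassified = if (length(mis)) mean(mis) else 0,
       n_planted_se = length(layout$se_clusters),
       n_planted_typical = length(layout$typical_constituents))
}

#' Write / verify the output manifest
#'
#' Every pipeline output is listed with its MD5 hash;
#' `verify_manifest()` recomputes the hashes and reports mismatches.
#'
#' @param outdir pipeline output directory.
#' @return For `write_manifest`, the manifest path; for
#'   `verify_manifest`, `TRUE` if all hashes match (stops otherwise).
#' @export
write_manifest <- function(outdir) {
  files <- setdiff(list.files(outdir), "manifest.json")
  md5 <- tools::md5sum(file.path(outdir, files))
  manifest <- list(files = as.list(setNames(unname(md5), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(outdir, "manifest.json"))
}

#' @rdname write_manifest
#' @export
verify_manifest <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  for (f in names(manifest$files)) {
    h <- unname(tools::md5sum(file.path(outdir, f)))
    if (is.na(h) || h != manifest$files[[f]])
      stopf("manifest mismatch for %s", f)
  }
  invisible(TRUE)
}
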