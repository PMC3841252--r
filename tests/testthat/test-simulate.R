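test_that("genome generation is deterministic and honours the empty case", {
  cfg <- small_layout_config(seed = 7)
  a <- make_genome(cfg); b <- make_genome(cfg)
  expect_identical(a$genes, b$genes)
  expect_same_intervals(elements_of(a), elements_of(b))

  empty <- layout_config(chrom_sizes = c(chr1 = 1e6), n_se_clusters = 0,
                         n_typical = 0, n_other_genes = 0,
                         n_heterochromatin = 0)
  lay0 <- make_genome(empty)
  expect_equal(length(elements_of(lay0)), 0L)
  expect_equal(nrow(lay0$genes), 0L)
})

test_that("the demo layout passes an independent overlap/spacing scan", {
  lay <- make_genome(layout_config(seed = 2))
  expect_equal(length(lay$se_clusters), 20L)
  expect_equal(length(lay$typical_constituents), 300L)
  validate_layout(lay)

  # independent oracle: brute-force pairwise scan over all elements
  el <- elements_of(lay)
  df <- data.frame(chrom = as.character(seqnames(el)), s = start(el),
                   e = end(el), class = el$class)
  sizes <- lay$chrom_sizes
  expect_true(all(df$s >= 1 & df$e <= sizes[df$chrom]))
  for (ch in names(sizes)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$s), ]
    if (nrow(d) > 1)
      expect_true(all(d$s[-1] > d$e[-nrow(d)]))   # pairwise disjoint
  }
  # constituents of one cluster stitch together; clusters stay isolated
  const <- c(do.call(c, lay$se_clusters), lay$typical_constituents)
  stitched <- merge_intervals(const, gap = lay$stitch_distance)
  expect_equal(length(stitched),
               length(lay$se_clusters) + length(lay$typical_constituents))
})

test_that("infeasible packings fail loudly", {
  expect_error(make_genome(layout_config(chrom_sizes = c(chr1 = 1e5),
                                         n_typical = 50)),
               "infeasible")
})

test_that("uniform-rate simulation matches the Poisson closed form", {
  flat <- layout_config(chrom_sizes = c(chr1 = 1e7), n_se_clusters = 0,
                        n_typical = 0, n_other_genes = 0,
                        n_heterochromatin = 0)
  lay <- make_genome(flat)
  reads <- simulate_chip_reads(lay, "WCE", depth = 1e6, seed = 5)
  tr <- build_track(reads, bin_size = 100, extend_len = 1)
  counts <- tr$counts$chr1
  expect_equal(length(counts), 1e5)
  # mean reads per bin ~ Poisson(10): the mean over 1e5 bins must fall
  # within 3 standard errors of 10
  se3 <- 3 * sqrt(10 / 1e5)
  expect_lt(abs(mean(counts) - 10), se3)

  expect_equal(length(simulate_chip_reads(lay, "WCE", depth = 0)), 0L)
  expect_error(simulate_chip_reads(lay, "NOPE"), "unknown factor")
})

test_that("fold-0 classes receive no reads and identical seeds reproduce reads", {
  lay <- make_genome(small_layout_config(seed = 3))
  reads <- simulate_chip_reads(lay, "H3K9me3", depth = 2e5, seed = 9)
  enh <- union_all(list(do.call(c, lay$se_clusters),
                        lay$typical_constituents, lay$promoters))
  expect_equal(midpoints_in(reads, enh), 0L)
  expect_gt(midpoints_in(reads, lay$heterochromatin), 0L)

  again <- simulate_chip_reads(lay, "H3K9me3", depth = 2e5, seed = 9)
  expect_same_intervals(reads, again)
})

test_that("read counts per element class conserve fold x background x footprint", {
  lay <- make_genome(small_layout_config(seed = 4))
  rule <- lay$factor_profiles$MED1
  el <- elements_of(lay)
  classes <- unique(el$class)
  foot <- vapply(classes, function(cl)
    sum(width(el[el$class == cl])), 0)
  folds <- rule$folds[classes]
  bg_foot <- sum(lay$chrom_sizes) - sum(foot)
  exp_rate <- c(folds * foot, background = bg_foot)
  depth <- 2e4
  n_seeds <- 50
  obs <- numeric(length(exp_rate))
  for (s in seq_len(n_seeds)) {
    reads <- simulate_chip_reads(lay, "MED1", depth = depth, seed = 100 + s)
    cnt <- vapply(classes, function(cl)
      midpoints_in(reads, el[el$class == cl]), 0L)
    obs <- obs + c(cnt, background = length(reads) - sum(cnt))
  }
  expected <- exp_rate / sum(exp_rate) * depth * n_seeds
  # chi-square goodness of fit at alpha = 0.01 (df = classes - 1)
  keep <- expected > 0
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, qchisq(0.99, df = sum(keep) - 1))
})

test_that("null knockdown effects give unit expression ratios", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:150),
                      class = rep(c("se", "te", "other"), each = 50),
                      stringsAsFactors = FALSE)
  tbl <- simulate_knockdown_expression(
    genes, effects = list(mean_lfc = c(se = 0, te = 0, other = 0),
                          sd_lfc = 0, shrna_sd = 0),
    n_replicates = 4, seed = 21)
  kd <- rowMeans(tbl$counts[, tbl$samples$condition == "shCAPH2_1"])
  ctrl <- rowMeans(tbl$counts[, tbl$samples$condition == "shGFP"])
  lr <- log2((kd + 1) / (ctrl + 1))
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("planted class effects are recovered from raw count ratios", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:400),
                      class = rep(c("se", "te"), each = 200),
                      stringsAsFactors = FALSE)
  tbl <- simulate_knockdown_expression(
    genes, effects = list(mean_lfc = c(se = -1, te = -0.3),
                          sd_lfc = 0.5, shrna_sd = 0.2),
    n_replicates = 3, seed = 8)
  kd <- rowMeans(tbl$counts[, tbl$samples$condition %in%
                              c("shCAPH2_1", "shCAPH2_2")])
  ctrl <- rowMeans(tbl$counts[, tbl$samples$condition == "shGFP"])
  lr <- log2(kd / ctrl)
  cls <- tbl$gene_class[rownames(tbl$counts)]
  expect_lt(abs(mean(lr[cls == "se"]) - (-1)), 0.1)
  expect_lt(abs(mean(lr[cls == "te"]) - (-0.3)), 0.1)

  again <- simulate_knockdown_expression(
    genes, effects = list(mean_lfc = c(se = -1, te = -0.3),
                          sd_lfc = 0.5, shrna_sd = 0.2),
    n_replicates = 3, seed = 8)
  expect_identical(tbl$counts, again$counts)
  expect_error(simulate_knockdown_expression(genes, dispersion = -1),
               "dispersion")
})

test_that("fixtures round trip through the package readers", {
  lay <- make_genome(small_layout_config(seed = 6))
  reads <- list(MED1 = simulate_chip_reads(lay, "MED1", depth = 5000,
                                           seed = 2))
  expr <- simulate_knockdown_expression(lay, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture(lay, reads, expr, dir)
  expect_true(all(file.exists(paths)))

  back_reads <- read_bed(paths[["reads_MED1"]],
                         chrom_sizes = lay$chrom_sizes)
  expect_same_intervals(back_reads, sort(reads$MED1, ignore.strand = TRUE))
  back_genes <- read_gene_table(paths[["genes"]])
  expect_equal(back_genes, lay$genes)
  back_expr <- read_expression_table(paths[["expression"]],
                                     paths[["samples"]])
  expect_equal(unname(back_expr$counts), unname(expr$counts))
  el <- read_bed(paths[["elements"]], chrom_sizes = lay$chrom_sizes)
  expect_equal(length(el), length(elements_of(lay)))
  # BED lines sorted by chrom,start
  tab <- read.table(paths[["reads_MED1"]], sep = "\t")
  expect_false(is.unsorted(order(tab$V1, tab$V2)))
  for (ch in unique(tab$V1))
    expect_false(is.unsorted(tab$V2[tab$V1 == ch]))

  empty <- make_genome(layout_config(chrom_sizes = c(chr1 = 1e6),
                                     n_se_clusters = 0, n_typical = 0,
                                     n_other_genes = 0,
                                     n_heterochromatin = 0))
  d2 <- withr::local_tempdir()
  p2 <- write_fixture(empty, dir = d2)
  expect_equal(length(read_bed(p2[["elements"]])), 0L)
})
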