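## hand-made partition: first k ranked entries typical, rest super
manual_partition <- function(ranked, k) {
  structure(list(ranked = ranked, cutoff_index = k,
                 class = ifelse(seq_along(ranked$signal) > k, "super",
                                "typical")),
            class = "se_partition")
}

test_that("stitching merges clusters and leaves isolated constituents alone", {
  far <- genomic_intervals("chrT", c(1000, 50000), c(1500, 50500),
                           chrom_sizes = c(chrT = 1e5))
  st <- stitch_constituents(far, stitch_distance = 12500)
  expect_equal(length(st$spans), 2L)
  expect_equal(st$spans$n_constituents, c(1L, 1L))

  cluster <- genomic_intervals("chrT", c(1000, 3000, 5000),
                               c(1800, 3800, 5800),
                               chrom_sizes = c(chrT = 1e5))
  st2 <- stitch_constituents(cluster, stitch_distance = 12500)
  expect_equal(length(st2$spans), 1L)
  expect_equal(st2$spans$n_constituents, 3L)
  expect_equal(c(start(st2$spans), end(st2$spans)), c(1000, 5800))
  expect_same_intervals(st2$constituents[[1]], cluster)
})

test_that("stitching equals the transitive-closure oracle and is monotone", {
  skip_if_not_installed("igraph")
  withr::with_seed(83, {
    for (rep in 1:25) {
      gr <- random_intervals(sample(2:50, 1))
      d <- sample(c(0, 100, 500, 2000), 1)
      st <- stitch_constituents(gr, stitch_distance = d)
      expect_same_intervals(st$spans, oracle_merge(gr, d))
      # idempotence at the same distance
      st2 <- stitch_constituents(st$spans, stitch_distance = d)
      expect_same_intervals(st2$spans, st$spans)
      # non-increasing count in the stitch distance
      n <- vapply(c(0, 200, 1000, 5000), function(dd)
        length(stitch_constituents(gr, dd)$spans), 0L)
      expect_true(all(diff(n) <= 0))
    }
  })
})

test_that("ranking sorts ascending with tie-break by start and matches region_signal", {
  tr <- toy_track(list(chrT = c(rep(10, 20), rep(1, 20), rep(0, 160))),
                  50, total_mapped = 1e6)
  # enhancer A over the high block, B over the low block, 100 bp apart
  gr <- genomic_intervals("chrT", c(1, 1101), c(1000, 2000),
                          chrom_sizes = TOY_CHROM)
  st <- stitch_constituents(gr, stitch_distance = 0)
  rk <- rank_by_signal(st, tr)
  expect_equal(start(rk$spans), c(1101, 1))     # low signal first
  expect_equal(rk$signal,
               sort(region_signal(tr, gr, "total_rpm")))

  # control equal to signal: all zeros, tie-break by start
  rk0 <- rank_by_signal(st, tr, tr)
  expect_equal(rk0$signal, c(0, 0))
  expect_equal(start(rk0$spans), c(1, 1101))

  # negative background-subtracted signal is kept raw but floored for rank
  big <- toy_track(list(chrT = rep(100, 200)), 50, total_mapped = 1e6)
  rkn <- rank_by_signal(st, tr, big)
  expect_true(all(rkn$signal_raw < 0))
  expect_equal(rkn$signal, c(0, 0))
})

test_that("the inflection cutoff finds the planted breakpoint", {
  # piecewise-linear: 90 points of shallow slope then 10 of steep slope
  sig <- c(seq(0, 9, length.out = 90), seq(10, 1000, length.out = 10))
  cut <- find_inflection_cutoff(sig)
  expect_lte(abs(cut - 90), 1)

  # affine invariance: adding a constant moves nothing
  expect_equal(find_inflection_cutoff(sig + 500), cut)

  # degenerate all-equal curve -> no super-enhancers
  expect_equal(find_inflection_cutoff(rep(3, 50)), 50L)
  expect_error(find_inflection_cutoff(5), "at least 2")
  expect_error(find_inflection_cutoff(c(3, 1)), "ascending")
})

test_that("partition classes are exhaustive and counts add up", {
  withr::with_seed(89, {
    sig <- sort(c(rgamma(95, 2), 50 + rgamma(5, 2)))
    gr <- genomic_intervals("chrT", seq(1, 9901, 100)[1:100],
                            seq(50, 9950, 100)[1:100],
                            chrom_sizes = TOY_CHROM)
    st <- stitch_constituents(gr, 0)
    st$signal <- sig; st$signal_raw <- sig; st$rank <- 1:100
    pa <- partition_super_enhancers(st)
    expect_equal(sum(pa$class == "super") + sum(pa$class == "typical"),
                 100L)
    expect_true(all(which(pa$class == "super") > pa$cutoff_index))
    tab <- partition_table(pa)
    expect_equal(nrow(tab), 100L)
    expect_equal(tab$class, pa$class)
  })
})

test_that("fold differences behave on constructed fixtures", {
  # constant density everywhere: both modes give exactly 1
  const <- toy_track(list(chrT = rep(5, 200)), 50, total_mapped = 1e6)
  # super span wide (3 constituents), typical narrow
  consts <- genomic_intervals("chrT", c(1001, 2001, 3001, 8001),
                              c(1500, 2500, 3500, 8500),
                              chrom_sizes = TOY_CHROM)
  st <- stitch_constituents(consts, stitch_distance = 1000)
  rk <- rank_by_signal(st, const)
  expect_equal(length(rk$spans), 2L)
  pa <- manual_partition(rk, 1)
  expect_equal(fold_difference(const, pa, "constituents"), 1)
  # equal density but a wider super span: enhancer-mode fold exceeds
  # constituent-mode fold
  expect_gt(fold_difference(const, pa, "enhancers"), 1)

  empty_super <- manual_partition(rk, 2)
  expect_error(fold_difference(const, empty_super), "non-empty")
})

test_that("planted constituent density ratios are recovered from simulation", {
  lay <- make_genome(small_layout_config(seed = 91))
  tr <- build_track(simulate_chip_reads(lay, "MED1", depth = 1e6, seed = 92))
  ctl <- build_track(simulate_chip_reads(lay, "WCE", depth = 1e6, seed = 93))
  occ <- call_occupied_regions(tr, ctl, "MED1")
  # restrict to enhancer constituents: drop promoter-overlapping calls
  enh_calls <- occ$regions[!(occ$regions %over% lay$promoters)]
  st <- stitch_constituents(enh_calls, lay$stitch_distance)
  pa <- partition_super_enhancers(rank_by_signal(st, tr, ctl))
  ratio <- fold_difference(tr, pa, "constituents")
  expect_lt(abs(ratio - 2.5) / 2.5, 0.15)
})
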