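toy_expr <- function(counts, conds) {
  samples <- data.frame(sample = paste0(conds, "_", seq_along(conds)),
                        condition = conds,
                        replicate = ave(seq_along(conds), conds,
                                        FUN = seq_along),
                        stringsAsFactors = FALSE)
  expression_table(counts, samples)
}

test_that("CPM normalization follows the stated arithmetic", {
  one <- toy_expr(matrix(c(1000, 500), 1, dimnames = list("g1", NULL)),
                  c("shGFP", "shSMC1"))
  expect_equal(unname(normalize_counts(one)[1, ]), c(1e6, 1e6))

  m <- matrix(c(300, 100, 50, 150), 2,
              dimnames = list(c("g1", "g2"), NULL))
  tbl <- toy_expr(m, c("shGFP", "shSMC1"))
  cpm <- normalize_counts(tbl)
  expect_equal(unname(cpm[, 1]), c(750000, 250000))   # 3x2 hand arithmetic
  expect_equal(unname(cpm[, 2]), c(250000, 750000))
  # doubling all counts in a sample leaves levels unchanged
  expect_equal(normalize_counts(toy_expr(m * 2, c("shGFP", "shSMC1"))),
               cpm)
  bad <- toy_expr(matrix(c(1, 0), 1), c("shGFP", "shSMC1"))
  expect_error(normalize_counts(bad), "library")
})

test_that("fold changes are zero at equality, +1 at doubling, antisymmetric", {
  # libraries are equal by construction, so CPM ratios = count ratios
  m <- cbind(c(100, 50, 150), c(100, 50, 150), c(200, 100, 0))
  rownames(m) <- c("g1", "g2", "g3")
  tbl <- toy_expr(m, c("shGFP", "shCAPH2_1", "shCAPH2_2"))
  expect_equal(unname(fold_changes(tbl, "shCAPH2_1", pseudocount = 0)),
               c(0, 0, 0))
  # kd level exactly 2x control for g1 and g2
  expect_equal(unname(fold_changes(tbl, "shCAPH2_2",
                                   pseudocount = 0))[1:2], c(1, 1))
  # antisymmetry at pseudocount 0: swap the roles of kd and control
  fc <- fold_changes(tbl, "shCAPH2_1", "shGFP", pseudocount = 0)
  t2 <- toy_expr(m[, c(2, 1, 3)], c("shCAPH2_1", "shGFP", "shCAPH2_2"))
  rev <- fold_changes(t2, "shGFP", "shCAPH2_1", pseudocount = 0)
  expect_equal(unname(rev), -unname(fc))
  expect_error(fold_changes(tbl, "shNOPE"), "absent")
})

test_that("pooling averages the two hairpins before the ratio", {
  # 2-gene toy, hand arithmetic: kd1 = (40, 10), kd2 = (20, 30), ctrl = (20, 20)
  m <- cbind(shGFP = c(20, 20), k1 = c(40, 10), k2 = c(20, 30))
  rownames(m) <- c("g1", "g2")
  tbl <- toy_expr(m, c("shGFP", "shCAPH2_1", "shCAPH2_2"))
  cpm <- normalize_counts(tbl)
  want <- log2(rowMeans(cpm[, 2:3]) / cpm[, 1])
  got <- fold_changes(tbl, c("shCAPH2_1", "shCAPH2_2"), pool = TRUE,
                      pseudocount = 0)
  expect_equal(unname(got), unname(want))
})

test_that("spearman matches brute-force Pearson on mean ranks", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, -(1:10)), -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  mean_rank <- function(v)
    vapply(v, function(vi) mean(which(sort(v) == vi)), 0)
  rx <- mean_rank(x); ry <- mean_rank(y)
  pearson <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(x, y), pearson)
  expect_warning(out <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_error(spearman(1:2, 1:2), "length")
})

test_that("genes rank by ascending mean fold change with id tie-breaks", {
  maps <- list(c(a = -2, b = 1, c = 0), c(a = -2, b = 1, c = 0))
  expect_equal(rank_genes_by_avg_fc(maps, c("a", "b", "c")),
               c("a", "c", "b"))
  expect_equal(rank_genes_by_avg_fc(maps, "b"), "b")
  tie <- list(c(z = 1, a = 1))
  expect_equal(rank_genes_by_avg_fc(tie, c("z", "a")), c("a", "z"))
  expect_error(rank_genes_by_avg_fc(maps, c("a", "missing")), "missing")
  withr::with_seed(101, {
    fc1 <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    fc2 <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    got <- rank_genes_by_avg_fc(list(fc1, fc2), names(fc1))
    avg <- (fc1 + fc2) / 2
    expect_equal(got, names(sort(avg)))
  })
})

test_that("box statistics match a sorted-array quartile oracle", {
  withr::with_seed(103, {
    x <- round(rnorm(11, 0, 2), 3)
    b <- box_stats(x)
    s <- sort(x)
    # interpolated quartile positions for n = 11: h = (n-1)p + 1
    q_at <- function(p) {
      h <- (11 - 1) * p + 1
      s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    }
    expect_equal(b$q1, q_at(0.25))
    expect_equal(b$median, q_at(0.5))
    expect_equal(b$q3, q_at(0.75))
    iqr <- b$q3 - b$q1
    expect_gte(b$whisker_low, b$q1 - 1.5 * iqr)
    expect_lte(b$whisker_high, b$q3 + 1.5 * iqr)
    expect_equal(b$whisker_low, min(s[s >= b$q1 - 1.5 * iqr]))
    expect_true(all(b$outliers < b$q1 - 1.5 * iqr |
                      b$outliers > b$q3 + 1.5 * iqr))
  })
})

test_that("class comparison detects planted separation and nulls out at identity", {
  same <- c(1, 2, 3, 4)
  cmp0 <- compare_gene_classes(setNames(c(same, same),
                                        c(paste0("a", 1:4), paste0("b", 1:4))),
                               paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)

  withr::with_seed(107, {
    fc <- setNames(c(rnorm(200, -1, 0.5), rnorm(200, -0.3, 0.5)),
                   sprintf("g%03d", 1:400))
    se <- sprintf("g%03d", 1:200); te <- sprintf("g%03d", 201:400)
    cmp <- compare_gene_classes(fc, se, te)
    expect_lt(cmp$p_value, 0.01)
    expect_lt(cmp$box_a$median, cmp$box_b$median)
  })
  expect_error(compare_gene_classes(c(a = 1, b = 2), "a", "b"), "n >= 2")
})

test_that("one-tailed Welch behaves at t = 0 and under direction reversal", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  expect_equal(one_tailed_t(a, b, "greater"), 0.5)
  x <- c(1.2, 3.4, 2.2, 4.1); y <- c(0.3, 1.1, 0.9, 2.0)
  expect_equal(one_tailed_t(x, y, "greater") + one_tailed_t(x, y, "less"),
               1)
  expect_error(one_tailed_t(1, y), "n >= 2")
})

test_that("one-tailed Welch agrees with the exhaustive permutation test", {
  withr::with_seed(109, {
    a <- round(rnorm(5, 1.2, 1), 2)
    b <- round(rnorm(5, 0, 1), 2)
    p_welch <- one_tailed_t(a, b, "greater")
    pool <- c(a, b)
    combs <- combn(10, 5)
    obs <- mean(a) - mean(b)
    perm <- apply(combs, 2, function(idx)
      mean(pool[idx]) - mean(pool[-idx]))
    p_perm <- mean(perm >= obs)
    expect_lt(abs(p_welch - p_perm), 0.05)
  })
})

test_that("qPCR fold values follow 2^-ddCt", {
  expect_equal(qpcr_relative_quantity(20, 15, 20, 15), 1)
  expect_equal(qpcr_relative_quantity(19, 15, 20, 15), 2)
  expect_equal(qpcr_relative_quantity(20, 15, 22, 15), 4)
  expect_error(qpcr_relative_quantity(NA, 15, 20, 15), "finite")
})
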