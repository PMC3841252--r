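#' Gene-by-sample expression table
#'
#' @param counts non-negative integer/numeric matrix, genes in rows
#'   (rownames = gene ids), samples in columns.
#' @param samples data frame with columns `sample`, `condition`,
#'   `replicate`; every condition must have at least one sample.
#' @return A list of class `expression_table`.
#' @export
expression_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (!all(c("sample", "condition", "replicate") %in% names(samples)))
    stopf("samples needs columns sample, condition, replicate")
  if (ncol(counts) != nrow(samples))
    stopf("counts columns (%d) != samples rows (%d)", ncol(counts),
          nrow(samples))
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples),
            class = "expression_table")
}

#' @rdname expression_table
#' @param x object to test.
#' @export
is_expression_table <- function(x) inherits(x, "expression_table")

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Library-size normalization to counts per million
#'
#' @param tbl an [expression_table()].
#' @return Matrix of CPM values, same shape as the counts.
#' @export
normalize_counts <- function(tbl) {
  stopifnot(is_expression_table(tbl))
  libs <- colSums(tbl$counts)
  if (any(libs == 0)) stopf("zero library size in sample(s): %s",
                            paste(colnames(tbl$counts)[libs == 0],
                                  collapse = ", "))
  sweep(tbl$counts, 2, libs, "/") * 1e6
}

condition_means <- function(tbl, conditions) {
  cpm <- normalize_counts(tbl)
  vapply(conditions, function(cond) {
    sel <- tbl$samples$condition == cond
    if (!any(sel)) stopf("condition '%s' absent from the table", cond)
    rowMeans(cpm[, sel, drop = FALSE])
  }, numeric(nrow(tbl$counts)))
}

#' Knockdown log2 fold changes versus a control condition
#'
#' Per gene, `log2((mean knockdown CPM + pseudocount) / (mean control CPM
#' + pseudocount))`.  With `pool = TRUE` the supplied knockdown
#' conditions (e.g. the two CAPH2 hairpins, whose expression profiles are
#' highly similar) are averaged at the level of normalized values before
#' the ratio is taken.
#'
#' @param tbl an [expression_table()].
#' @param kd_conditions character vector of knockdown condition names.
#' @param ctrl_condition control condition name (default `"shGFP"`).
#' @param pool average the knockdown conditions before forming the ratio
#'   (default `TRUE` when more than one is supplied).
#' @param pseudocount added to both means (CPM units, default 1).
#' @return Named numeric vector of per-gene log2 fold changes (or, with
#'   `pool = FALSE` and several conditions, a matrix with one column per
#'   condition).
#' @export
fold_changes <- function(tbl, kd_conditions, ctrl_condition = "shGFP",
                         pool = length(kd_conditions) > 1L,
                         pseudocount = 1) {
  m <- condition_means(tbl, c(kd_conditions, ctrl_condition))
  ctrl <- m[, ctrl_condition]
  kd <- m[, kd_conditions, drop = FALSE]
  if (pool) {
    lfc <- log2((rowMeans(kd) + pseudocount) / (ctrl + pseudocount))
    setNames(lfc, rownames(tbl$counts))
  } else if (length(kd_conditions) == 1L) {
    setNames(log2((kd[, 1L] + pseudocount) / (ctrl + pseudocount)),
             rownames(tbl$counts))
  } else {
    log2(sweep(kd + pseudocount, 1, ctrl + pseudocount, "/"))
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with mean ranks for ties; `NA` (with a warning) if
#' either vector is constant.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return The correlation coefficient rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("x and y must have equal length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("spearman undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Rank genes by average fold change across shRNAs
#'
#' @param fc_maps list of named fold-change vectors (one per shRNA).
#' @param gene_set genes to rank; every gene must be present in every
#'   map.
#' @return Character vector of gene ids, ascending mean fold change
#'   (most down-regulated first), ties broken by gene id.
#' @export
rank_genes_by_avg_fc <- function(fc_maps, gene_set) {
  for (m in fc_maps)
    if (!all(gene_set %in% names(m)))
      stopf("gene(s) missing from a fold-change map: %s",
            paste(head(setdiff(gene_set, names(m)), 3), collapse = ", "))
  avg <- rowMeans(matrix(vapply(fc_maps, function(m) m[gene_set],
                                numeric(length(gene_set))),
                         nrow = length(gene_set)))
  gene_set[order(avg, gene_set)]
}

#' Box-plot statistics with 1.5 x IQR whiskers
#'
#' Quartiles use the default interpolation (type 7); whiskers extend to
#' the most extreme data points within 1.5 interquartile ranges of the
#' quartiles, and points beyond are outliers.
#'
#' @param x numeric vector (length >= 1).
#' @return A list of class `box_stats`: `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stopf("no data")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr; hi_lim <- q[3] + 1.5 * iqr
  inside <- x >= lo_lim & x <= hi_lim
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(x[inside]),
                 whisker_high = max(x[inside]),
                 outliers = sort(x[!inside]), n = length(x)),
            class = "box_stats")
}

#' Compare fold changes between two gene classes
#'
#' Welch two-sample, two-tailed t test on per-gene fold changes (e.g.
#' super-enhancer-associated versus typical-enhancer genes), plus
#' box-plot statistics per class.
#'
#' @param fc named fold-change vector.
#' @param class_a_genes,class_b_genes gene-id vectors (each n >= 2; ids
#'   must be present in `fc`).
#' @param pooled_variance use the pooled-variance (Student) test instead
#'   of Welch.
#' @return A list: `box_a`, `box_b` ([box_stats()]), `t`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
compare_gene_classes <- function(fc, class_a_genes, class_b_genes,
                                 pooled_variance = FALSE) {
  miss <- setdiff(c(class_a_genes, class_b_genes), names(fc))
  if (length(miss)) stopf("genes missing from fc: %s",
                          paste(head(miss, 3), collapse = ", "))
  a <- fc[class_a_genes]; b <- fc[class_b_genes]
  if (length(a) < 2L || length(b) < 2L) stopf("each class needs n >= 2")
  tt <- t.test(a, b, alternative = "two.sided",
               var.equal = pooled_variance)
  list(box_a = box_stats(a), box_b = box_stats(b),
       t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' One-tailed Welch t test
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each).
#' @param direction alternative for `sample_a` relative to `sample_b`:
#'   `"greater"` or `"less"`.
#' @param pooled_variance use the pooled-variance test instead of Welch.
#' @return The one-tailed p-value.
#' @export
one_tailed_t <- function(sample_a, sample_b,
                         direction = c("greater", "less"),
                         pooled_variance = FALSE) {
  direction <- match.arg(direction)
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("each sample needs n >= 2")
  t.test(sample_a, sample_b, alternative = direction,
         var.equal = pooled_variance)$p.value
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Standard delta-delta-Ct arithmetic behind fold-enrichment and
#' transcript-level bar plots: the target Ct is normalized to a reference
#' gene within each condition, and the experimental condition compared to
#' the control.
#'
#' @param ct_target,ct_reference Ct values in the experimental condition.
#' @param ct_target_ctrl,ct_reference_ctrl Ct values in the control
#'   condition.
#' @return Fold value `2^-((ct_target - ct_reference) -
#'   (ct_target_ctrl - ct_reference_ctrl))`.
#' @export
qpcr_relative_quantity <- function(ct_target, ct_reference,
                                   ct_target_ctrl, ct_reference_ctrl) {
  vals <- c(ct_target, ct_reference, ct_target_ctrl, ct_reference_ctrl)
  if (any(!is.finite(vals))) stopf("Ct values must be finite")
  2^-((ct_target - ct_reference) - (ct_target_ctrl - ct_reference_ctrl))
}
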