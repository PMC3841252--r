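#' Simulate aligned ChIP-seq reads for one factor
#'
#' Reads are emitted directly as aligned fixed-length intervals (no
#' sequence model).  The expected number of read midpoints per bp is
#' `background_rate * fold(class at that bp)` -- piecewise constant over
#' the planted elements -- rescaled so that the expected total equals
#' `depth`; per-segment counts are Poisson and positions uniform within
#' the segment.  Strand is assigned uniformly and is cosmetic (all
#' densities downstream are unstranded).
#'
#' @param layout a [make_genome()] layout.
#' @param factor factor name; must have a profile in
#'   `layout$factor_profiles`.
#' @param depth expected total read count (>= 0).
#' @param read_len read length in bp (default 36).
#' @param seed integer seed.
#' @return A `GRanges` of reads with strand and seqlengths set.
#' @export
simulate_chip_reads <- function(layout, factor, depth = 1e6, read_len = 36,
                                seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  rule <- layout$factor_profiles[[factor]]
  if (is.null(rule)) stopf("unknown factor '%s'", factor)
  if (!is_count(depth)) stopf("`depth` must be >= 0")
  with_seed(seed, simulate_reads_impl(layout, rule, depth, read_len))
}

## piecewise-constant rate segments per chromosome: planted elements at
## background*fold, everything else at background
rate_segments <- function(layout, rule) {
  el <- elements_of(layout)
  sizes <- layout$chrom_sizes
  segs <- lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    e <- el[as.character(GenomeInfoDb::seqnames(el)) == ch]
    e <- e[order(GenomicRanges::start(e))]
    st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    fold <- rule$folds[S4Vectors::mcols(e)$class]
    fold[is.na(fold)] <- 1
    cv <- rule$fold_cv
    if (!is.null(cv) && cv > 0) {
      enriched <- fold > 1
      mult <- rlnorm(sum(enriched), meanlog = -cv^2 / 2, sdlog = cv)
      fold[enriched] <- pmax(fold[enriched] * mult, 1)
    }
    # interleave background gaps with elements
    bst <- c(1, en + 1); ben <- c(st - 1, L)
    keep <- ben >= bst
    data.frame(chrom = ch,
               start = c(bst[keep], st), end = c(ben[keep], en),
               rate = rule$background_rate * c(rep(1, sum(keep)), fold))
  })
  do.call(rbind, segs)
}

simulate_reads_impl <- function(layout, rule, depth, read_len) {
  segs <- rate_segments(layout, rule)
  expected <- segs$rate * (segs$end - segs$start + 1)
  tot <- sum(expected)
  empty <- genomic_intervals(character(), integer(), integer(),
                             chrom_sizes = layout$chrom_sizes)
  if (depth == 0 || tot == 0) return(empty)
  lambda <- expected * depth / tot
  n <- rpois(length(lambda), lambda)
  if (sum(n) == 0) return(empty)
  idx <- rep.int(seq_along(n), n)
  w <- segs$end[idx] - segs$start[idx] + 1
  mid <- segs$start[idx] + floor(runif(sum(n)) * w)
  start <- mid - read_len %/% 2L
  sizes <- layout$chrom_sizes[segs$chrom[idx]]
  start <- pmin(pmax(start, 1), sizes - read_len + 1)
  gr <- genomic_intervals(segs$chrom[idx], start, start + read_len - 1L,
                          strand = sample(c("+", "-"), sum(n), replace = TRUE),
                          chrom_sizes = layout$chrom_sizes)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate knockdown RNA-seq counts
#'
#' Draws negative-binomial counts for control (shGFP) and knockdown
#' samples (two CAPH2 shRNAs and one SMC1 shRNA).  Each gene carries a
#' baseline mean (log-normal across genes) and, per knockdown, a true
#' log2 fold change drawn around its class mean: genes associated with
#' super-enhancers are planted with larger expression decreases than
#' typical-enhancer genes, the direction the downstream class comparison
#' is designed to detect.  The true effect decomposes into a per-gene
#' core shared by all knockdowns, a complex-specific deviation (CAPH2
#' versus SMC1), and a smaller hairpin-specific deviation -- so two
#' hairpins against the same target agree more closely than knockdowns
#' of different complexes, as in the real experiment.
#'
#' @param genes either a `genome_layout` (its gene table, with planted
#'   classes, is used) or a data frame with `gene_id` and `class`
#'   (`"se"`, `"te"`, `"other"`).
#' @param effects list with `mean_lfc` (named per class), `sd_lfc`
#'   (between-gene SD of the true core effect), `complex_sd` (SD of the
#'   per-gene complex-specific deviation) and `shrna_sd` (SD of the
#'   hairpin-specific deviation); omitted SD components default to 0.
#' @param n_replicates samples per condition.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline expression mean.
#' @param dispersion negative-binomial dispersion (1/size; must be >= 0;
#'   0 degenerates to Poisson).
#' @param seed integer seed.
#' @return An [expression_table()]; the planted per-gene, per-condition
#'   log2 fold changes are attached as component `truth`.
#' @export
simulate_knockdown_expression <- function(genes,
                                          effects = list(
                                            mean_lfc = c(se = -1, te = -0.3,
                                                         other = 0),
                                            sd_lfc = 0.5, complex_sd = 0.25,
                                            shrna_sd = 0.15),
                                          n_replicates = 3,
                                          baseline_meanlog = log(200),
                                          baseline_sdlog = 1,
                                          dispersion = 0.1,
                                          seed = 1) {
  if (inherits(genes, "genome_layout")) genes <- genes$genes
  if (!all(c("gene_id", "class") %in% names(genes)))
    stopf("`genes` needs gene_id and class columns")
  if (!is.numeric(dispersion) || dispersion < 0)
    stopf("dispersion must be >= 0")
  if (!all(genes$class %in% names(effects$mean_lfc)))
    stopf("every gene class needs an entry in effects$mean_lfc")
  eff <- utils::modifyList(list(sd_lfc = 0, complex_sd = 0, shrna_sd = 0),
                           effects)
  with_seed(seed, {
    ng <- nrow(genes)
    mu0 <- rlnorm(ng, baseline_meanlog, baseline_sdlog)
    core <- eff$mean_lfc[genes$class] + rnorm(ng, 0, eff$sd_lfc)
    complex_dev <- list(CAPH2 = rnorm(ng, 0, eff$complex_sd),
                        SMC1 = rnorm(ng, 0, eff$complex_sd))
    conds <- c("shGFP", "shCAPH2_1", "shCAPH2_2", "shSMC1")
    complex_of <- c(shCAPH2_1 = "CAPH2", shCAPH2_2 = "CAPH2",
                    shSMC1 = "SMC1")
    truth <- sapply(conds, function(cond) {
      if (cond == "shGFP") rep(0, ng)
      else core + complex_dev[[complex_of[[cond]]]] +
        rnorm(ng, 0, eff$shrna_sd)
    })
    rownames(truth) <- genes$gene_id
    samples <- data.frame(
      sample = paste0(rep(conds, each = n_replicates), "_r",
                      rep(seq_len(n_replicates), length(conds))),
      condition = rep(conds, each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(conds)),
      stringsAsFactors = FALSE)
    counts <- matrix(0L, ng, nrow(samples),
                     dimnames = list(genes$gene_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- mu0 * 2^truth[, samples$condition[j]]
      counts[, j] <- if (dispersion == 0) rpois(ng, mu)
                     else rnbinom(ng, mu = mu, size = 1 / dispersion)
    }
    tbl <- expression_table(counts, samples)
    tbl$truth <- truth
    tbl$gene_class <- setNames(genes$class, genes$gene_id)
    tbl
  })
}

#' Write a simulated study to plain-text files
#'
#' Emits, under `dir`: `chrom_sizes.tsv`; `elements.bed` (planted
#' elements, class in the name field); one sorted `reads_<factor>.bed`
#' per read set; `genes.tsv` (0-based on disk); and
#' `expression_counts.tsv` + `samples.tsv`.  Everything round-trips
#' through the package readers.
#'
#' @param layout a [make_genome()] layout.
#' @param reads named list of read `GRanges` (may be empty).
#' @param expression an [expression_table()] or `NULL`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(layout, reads = list(), expression = NULL, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", dir)
  paths <- c()
  p <- file.path(dir, "chrom_sizes.tsv")
  write.table(data.frame(chrom = names(layout$chrom_sizes),
                         length = as.numeric(layout$chrom_sizes)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["chrom_sizes"] <- p
  el <- elements_of(layout)
  if (length(el)) S4Vectors::mcols(el)$name <- S4Vectors::mcols(el)$class
  S4Vectors::mcols(el)$class <- NULL
  paths["elements"] <- write_bed(el, file.path(dir, "elements.bed"))
  for (f in names(reads))
    paths[paste0("reads_", f)] <-
      write_bed(reads[[f]], file.path(dir, sprintf("reads_%s.bed", f)))
  paths["genes"] <- write_gene_table(layout$genes, file.path(dir, "genes.tsv"))
  if (!is.null(expression)) {
    write_expression_table(expression,
                           file.path(dir, "expression_counts.tsv"),
                           file.path(dir, "samples.tsv"))
    paths["expression"] <- file.path(dir, "expression_counts.tsv")
    paths["samples"] <- file.path(dir, "samples.tsv")
  }
  invisible(paths)
}
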