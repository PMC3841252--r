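## Independent oracles and small fixture builders.  Everything here is
## deliberately brute force: per-base scans and transitive closures that
## do not share code paths with the package implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

## explicit bindings so the helpers resolve identically whether the suite
## runs against the installed package or a dev load
seqnames <- GenomeInfoDb::seqnames
start <- BiocGenerics::start
end <- BiocGenerics::end
width <- BiocGenerics::width
strand <- BiocGenerics::strand
sort <- BiocGenerics::sort
countOverlaps <- GenomicRanges::countOverlaps
`%over%` <- IRanges::`%over%`

TOY_CHROM <- c(chrT = 10000)

## random interval set on the toy chromosome
random_intervals <- function(n, max_len = 10000, max_width = 300) {
  if (n == 0)
    return(genomic_intervals(character(), integer(), integer(),
                             chrom_sizes = c(chrT = max_len)))
  st <- sample.int(max_len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals("chrT", st, pmin(st + w - 1, max_len),
                    chrom_sizes = c(chrT = max_len))
}

## merge-with-gap oracle: transitive closure over the pairwise
## "gap <= g" relation, via igraph connected components
oracle_merge <- function(gr, gap) {
  n <- length(gr)
  if (n == 0) return(gr)
  s <- start(gr); e <- end(gr)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    pmax(s[i], s[j]) - pmin(e[i], e[j]) - 1 <= gap)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  st <- tapply(s, comp, min); en <- tapply(e, comp, max)
  ord <- order(st)
  genomic_intervals("chrT", as.integer(st[ord]), as.integer(en[ord]),
                    chrom_sizes = c(chrT = max(en) + 10))
}

## per-base boolean coverage of a GRanges on the toy chromosome
base_cover <- function(gr, len = 10000) {
  v <- logical(len)
  for (i in seq_along(gr))
    v[start(gr)[i]:min(end(gr)[i], len)] <- TRUE
  v
}

## covered-base runs back to intervals
runs_to_intervals <- function(v) {
  r <- rle(v)
  en <- cumsum(r$lengths); st <- en - r$lengths + 1
  keep <- r$values
  genomic_intervals(rep("chrT", sum(keep)), st[keep], en[keep],
                    chrom_sizes = c(chrT = length(v)))
}

## per-base AND oracle for intersect_all
oracle_intersect <- function(sets, len = 10000) {
  v <- Reduce(`&`, lapply(sets, base_cover, len = len))
  runs_to_intervals(v)
}

expect_same_intervals <- function(a, b) {
  expect_equal(as.character(seqnames(a)), as.character(seqnames(b)))
  expect_equal(start(a), start(b))
  expect_equal(end(a), end(b))
}

## hand-built coverage track from explicit per-chromosome bin vectors
toy_track <- function(counts, bin_size, total_mapped,
                      chrom_sizes = NULL) {
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(counts, function(v) length(v) * bin_size, 0)
  coverage_track(counts, bin_size, total_mapped, chrom_sizes,
                 extend_len = NA_real_)
}

## per-base expansion of a track's density (RPM per bp) on one chromosome
base_density <- function(track, chrom) {
  v <- track$counts[[chrom]]
  rep(v / track$bin_size, each = track$bin_size)[
    seq_len(track$chrom_sizes[[chrom]])] * 1e6 / track$total_mapped
}

## integral of the per-base density over real-valued [a, b), 0-based
base_integral <- function(dens, a, b) {
  C <- function(x) {
    f <- floor(x)
    base <- if (f >= 1) sum(dens[seq_len(min(f, length(dens)))]) else 0
    frac <- if (f < length(dens)) dens[f + 1] * (x - f) else 0
    base + frac
  }
  C(b) - C(a)
}

## per-base metagene oracle: mean density per sub-bin, regions on one chrom
oracle_metagene <- function(track, regions, flank_bp, body_bins) {
  dens <- base_density(track, as.character(seqnames(regions))[1])
  nf <- flank_bp / track$bin_size
  rows <- lapply(seq_along(regions), function(i) {
    s0 <- start(regions)[i] - 1; e0 <- end(regions)[i]
    bounds <- c(s0 - flank_bp + (0:(nf - 1)) * track$bin_size,
                s0 + (0:body_bins) * (e0 - s0) / body_bins,
                e0 + (1:nf) * track$bin_size)
    vapply(seq_len(length(bounds) - 1), function(j)
      base_integral(dens, bounds[j], bounds[j + 1]) /
        (bounds[j + 1] - bounds[j]), 0)
  })
  colMeans(do.call(rbind, rows))
}

## small, fast genome layout used across the simulation tests
small_layout_config <- function(seed = 11, ...) {
  layout_config(chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                n_se_clusters = 4, n_typical = 40, n_other_genes = 8,
                n_heterochromatin = 2, heterochromatin_width = 20000,
                seed = seed, ...)
}

read_midpoints <- function(reads) (start(reads) + end(reads) + 1) %/% 2

## count reads whose midpoint falls in a region set
midpoints_in <- function(reads, regions) {
  mids <- GRanges(seqnames(reads),
                  IRanges(read_midpoints(reads), width = 1))
  sum(countOverlaps(mids, regions, ignore.strand = TRUE) > 0)
}
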