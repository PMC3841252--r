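#' Merge intervals separated by at most a fixed gap
#'
#' Two intervals are merged (transitively) whenever the number of bases
#' strictly between them is at most `gap`; touching or overlapping
#' intervals are always merged.  This is the shared primitive behind
#' enhancer-constituent stitching and occupied-region merging.
#'
#' @param x a `GRanges`.
#' @param gap maximum edge-to-edge gap (bp, >= 0) across which intervals
#'   are still merged.
#' @return A sorted, disjoint `GRanges`.  Strand is ignored.
#' @examples
#' gr <- genomic_intervals("chr1", c(11, 26), c(20, 30))
#' merge_intervals(gr, gap = 5)   # one interval
#' merge_intervals(gr, gap = 4)   # unchanged
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(is(x, "GRanges"))
  if (!is_count(gap)) stopf("`gap` must be a single non-negative number")
  out <- GenomicRanges::reduce(x, min.gapwidth = gap + 1, ignore.strand = TRUE)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Bases covered by every one of several interval sets
#'
#' Returns the maximal intervals covered by at least one interval from
#' *every* input set -- the operation used to define enhancers (regions
#' occupied by OCT4, SOX2 and NANOG) and promoters (TBP and POL II).
#'
#' @param sets a list of `GRanges` (at least one).
#' @return A sorted, disjoint `GRanges`.
#' @export
intersect_all <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L)
    stopf("`sets` must be a non-empty list of GRanges")
  sets <- lapply(sets, function(s) merge_intervals(s, gap = 0))
  Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets)
}

#' Union of interval sets, merged
#'
#' @param sets a list of `GRanges`.
#' @return A sorted, disjoint `GRanges` covering the union.
#' @export
union_all <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L)
    stopf("`sets` must be a non-empty list of GRanges")
  merge_intervals(do.call(c, lapply(sets, function(s) {
    GenomicRanges::strand(s) <- "*"
    S4Vectors::mcols(s) <- NULL
    s
  })), gap = 0)
}

## edge-to-edge distance from a point (1-based bp) to a 1-based closed
## interval; 0 if the point lies inside
point_interval_distance <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}

#' Gene nearest to a region by TSS distance
#'
#' Finds the gene whose transcription start site lies closest to the
#' region (distance 0 if the TSS falls inside it).  Ties are broken by the
#' lexicographically smaller `gene_id`, and genes farther than
#' `max_distance` are never assigned.
#'
#' @param region a length-1 `GRanges`.
#' @param genes a gene table as returned by [make_genome()]: a data frame
#'   with columns `gene_id`, `chrom`, `strand`, `tss` (1-based), `start`,
#'   `end`.
#' @param max_distance maximum TSS distance (bp) for an assignment.
#' @return A list with `gene_id` (or `NA_character_`) and `distance`.
#' @export
nearest_tss <- function(region, genes, max_distance = Inf) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stopf("`genes` must be a non-empty data frame")
  same <- genes$chrom == as.character(GenomeInfoDb::seqnames(region))
  if (!any(same)) return(list(gene_id = NA_character_, distance = NA_real_))
  g <- genes[same, , drop = FALSE]
  d <- point_interval_distance(g$tss, GenomicRanges::start(region),
                               GenomicRanges::end(region))
  ord <- order(d, g$gene_id)
  best <- ord[1L]
  if (d[best] > max_distance)
    return(list(gene_id = NA_character_, distance = NA_real_))
  list(gene_id = g$gene_id[best], distance = as.numeric(d[best]))
}

covered_bases <- function(x) sum(GenomicRanges::width(merge_intervals(x, 0)))
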