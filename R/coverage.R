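#' Binned coverage track
#'
#' @param counts named list of per-chromosome numeric bin vectors.
#' @param bin_size bin width (bp, > 0).
#' @param total_mapped total mapped reads the track was built from (used
#'   for reads-per-million scaling; this is the read count, not a bin
#'   sum).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param extend_len fragment extension used when building (bp).
#' @return A list of class `coverage_track`.
#' @export
coverage_track <- function(counts, bin_size, total_mapped, chrom_sizes,
                           extend_len = NA_real_) {
  if (!is_count(bin_size, allow_zero = FALSE)) stopf("bin_size must be > 0")
  if (any(unlist(counts, use.names = FALSE) < 0)) stopf("negative bin counts")
  structure(list(counts = counts, bin_size = bin_size,
                 total_mapped = total_mapped,
                 chrom_sizes = chrom_sizes[names(counts)],
                 extend_len = extend_len),
            class = "coverage_track")
}

#' @rdname coverage_track
#' @param x object to test.
#' @export
is_coverage_track <- function(x) inherits(x, "coverage_track")

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %d chrom(s), bin %d bp, extend %s bp, %.0f mapped reads\n",
    length(x$counts), x$bin_size,
    format(x$extend_len), x$total_mapped))
  invisible(x)
}

n_bins <- function(len, bin) as.integer(ceiling(len / bin))

#' Build a binned coverage track from aligned reads
#'
#' Each read is extended to `extend_len` bp in its strand direction
#' (midpoint-symmetric for unstranded reads) to approximate the sequenced
#' fragment, and every bin counts the extended reads overlapping it.
#'
#' @param reads a `GRanges` of reads; chromosome lengths must be set (or
#'   supplied via `chrom_sizes`).
#' @param bin_size bin width in bp (default 50).
#' @param extend_len fragment extension in bp (default 200).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [coverage_track()]; `total_mapped` is the number of reads.
#' @export
build_track <- function(reads, bin_size = 50, extend_len = 200,
                        chrom_sizes = NULL) {
  stopifnot(is(reads, "GRanges"))
  if (!is_count(bin_size, allow_zero = FALSE) ||
      !is_count(extend_len, allow_zero = FALSE))
    stopf("bin_size and extend_len must be > 0")
  if (is.null(chrom_sizes)) chrom_sizes <- chrom_sizes_of(reads)

  st <- GenomicRanges::start(reads); en <- GenomicRanges::end(reads)
  sdir <- as.character(GenomicRanges::strand(reads))
  xs <- ifelse(sdir == "-", en - extend_len + 1,
        ifelse(sdir == "+", st,
               (st + en) %/% 2L - extend_len %/% 2L))
  xe <- xs + extend_len - 1
  lens <- chrom_sizes[as.character(GenomeInfoDb::seqnames(reads))]
  xs <- pmax(xs, 1); xe <- pmin(xe, lens)

  ch <- as.character(GenomeInfoDb::seqnames(reads))
  counts <- lapply(names(chrom_sizes), function(cc) {
    nb <- n_bins(chrom_sizes[[cc]], bin_size)
    sel <- ch == cc
    if (!any(sel)) return(numeric(nb))
    sb <- (xs[sel] - 1) %/% bin_size + 1          # first overlapped bin
    eb <- (xe[sel] - 1) %/% bin_size + 1          # last overlapped bin
    delta <- tabulate(sb, nbins = nb)
    dec <- tabulate(eb[eb < nb] + 1L, nbins = nb)
    cumsum(delta - dec)
  })
  names(counts) <- names(chrom_sizes)
  coverage_track(counts, bin_size, total_mapped = length(reads),
                 chrom_sizes = chrom_sizes, extend_len = extend_len)
}

## cumulative per-base integral of bin counts up to 0-based position x
## (real-valued); each base in bin b carries count[b]/bin_size
cum_counts_at <- function(v, bin, x) {
  nb <- length(v)
  cs <- c(0, cumsum(v))
  b <- pmin(pmax(floor(x / bin), 0), nb - 1)
  frac <- pmin(pmax(x - b * bin, 0), bin)
  cs[b + 1] + v[b + 1] * frac / bin
}

## pro-rata read counts over 0-based half-open [start0, end0) intervals
## (vectorized; boundaries may be fractional, used by metagene rescaling)
region_counts0 <- function(track, chrom, start0, end0) {
  out <- numeric(length(chrom))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    v <- track$counts[[cc]]
    if (is.null(v)) stopf("chromosome '%s' not in track", cc)
    L <- track$chrom_sizes[[cc]]
    s <- pmin(pmax(start0[sel], 0), L); e <- pmin(pmax(end0[sel], 0), L)
    out[sel] <- cum_counts_at(v, track$bin_size, e) -
      cum_counts_at(v, track$bin_size, s)
  }
  out
}

#' Signal of a track over regions, in the study's units
#'
#' `total_rpm` is reads overlapping the region per million mapped reads
#' ("reads per million"); `density_rpm_per_bp` divides by the region
#' length ("reads per million per base pair").  Bins partially inside the
#' region contribute pro rata by the fraction of the bin covered.
#'
#' @param track a [coverage_track()].
#' @param regions a `GRanges`.
#' @param mode `"total_rpm"` or `"density_rpm_per_bp"`.
#' @return Numeric vector, one value per region.
#' @export
region_signal <- function(track, regions,
                          mode = c("total_rpm", "density_rpm_per_bp")) {
  stopifnot(is_coverage_track(track), is(regions, "GRanges"))
  mode <- match.arg(mode)
  if (track$total_mapped == 0) stopf("track has no mapped reads")
  cnt <- region_counts0(track,
                        as.character(GenomeInfoDb::seqnames(regions)),
                        GenomicRanges::start(regions) - 1,
                        GenomicRanges::end(regions))
  rpm <- cnt * 1e6 / track$total_mapped
  if (mode == "total_rpm") rpm else rpm / GenomicRanges::width(regions)
}

#' Occupied-region set for a factor
#'
#' @param factor factor name.
#' @param regions disjoint sorted `GRanges`.
#' @param params list of calling parameters.
#' @return A list of class `occupancy_set`.
#' @export
occupancy_set <- function(factor, regions, params = list()) {
  regions <- merge_intervals(regions, 0)
  structure(list(factor = factor, regions = regions, params = params),
            class = "occupancy_set")
}

#' @export
print.occupancy_set <- function(x, ...) {
  cat(sprintf("occupancy_set '%s': %d regions, %.0f bp covered\n",
              x$factor, length(x$regions),
              sum(GenomicRanges::width(x$regions))))
  invisible(x)
}

## accept either an occupancy_set or a bare GRanges
as_regions <- function(x) {
  if (inherits(x, "occupancy_set")) x$regions
  else if (is(x, "GRanges")) x
  else stopf("expected an occupancy_set or GRanges")
}

#' Call factor-occupied regions against an input control
#'
#' Per-bin Poisson enrichment test: the expected count is the
#' depth-scaled control bin count, floored at the genome-average scaled
#' control rate so that control dropouts cannot inflate significance.
#' Bins with upper-tail p below `p_cutoff` are merged across gaps up to
#' `merge_gap`, and regions narrower than `min_width` are dropped.
#'
#' @param track,control [coverage_track()]s with identical binning.
#' @param factor label for the resulting set.
#' @param p_cutoff per-bin Poisson upper-tail p-value threshold.
#' @param min_width minimum region width (bp).
#' @param merge_gap gap (bp) across which passing bins are merged.
#' @return An [occupancy_set()].
#' @export
call_occupied_regions <- function(track, control, factor = "factor",
                                  p_cutoff = 1e-5, min_width = 100,
                                  merge_gap = 200) {
  stopifnot(is_coverage_track(track), is_coverage_track(control))
  if (track$bin_size != control$bin_size ||
      !identical(names(track$counts), names(control$counts)) ||
      !all(vapply(names(track$counts), function(ch)
        length(track$counts[[ch]]) == length(control$counts[[ch]]), TRUE)))
    stopf("track and control must share binning and chromosomes")
  if (control$total_mapped == 0) stopf("control has no mapped reads")
  scale <- track$total_mapped / control$total_mapped
  avg <- mean(unlist(control$counts, use.names = FALSE)) * scale

  bs <- track$bin_size
  hits <- lapply(names(track$counts), function(ch) {
    obs <- track$counts[[ch]]
    lam <- pmax(control$counts[[ch]] * scale, avg)
    p <- ppois(obs - 1, lam, lower.tail = FALSE)
    i <- which(p < p_cutoff)
    list(chrom = rep(ch, length(i)), start = (i - 1L) * bs + 1L,
         end = pmin(i * bs, track$chrom_sizes[[ch]]))
  })
  gr <- genomic_intervals(unlist(lapply(hits, `[[`, "chrom")),
                          unlist(lapply(hits, `[[`, "start")),
                          unlist(lapply(hits, `[[`, "end")),
                          chrom_sizes = track$chrom_sizes)
  merged <- merge_intervals(gr, gap = merge_gap)
  merged <- merged[GenomicRanges::width(merged) >= min_width]
  occupancy_set(factor, merged,
                params = list(p_cutoff = p_cutoff, min_width = min_width,
                              merge_gap = merge_gap))
}
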