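#' Metagene density profile over a set of regions
#'
#' Averages ChIP-seq density (reads per million per bp) across regions on
#' a common axis: each region's body is rescaled to `body_bins` equal
#' fractions (so enhancers of very different widths -- ~700 bp typical
#' versus ~8.7 kb super-enhancers -- are comparable side by side) and the
#' flanks are fixed-bp bins of the track's bin size.  The mean across
#' regions is unweighted: each region counts once regardless of width.
#' Regions whose flanked window sticks out of the chromosome are dropped
#' with a message.
#'
#' @param track a [coverage_track()].
#' @param regions a `GRanges` (or [occupancy_set()]); at least one region
#'   must survive edge filtering.
#' @param flank_bp flank on each side (bp; must be a multiple of the
#'   track bin size; default 1000).
#' @param body_bins number of body fractions (default 60).
#' @return A list of class `metagene_profile` with `density` (mean
#'   RPM/bp per bin), `position` (bin centers; body bins on a 0..1
#'   fractional axis mapped between the flanks), `flank_bp`, `body_bins`,
#'   `n_regions`, `n_dropped`.
#' @export
metagene_profile <- function(track, regions, flank_bp = 1000,
                             body_bins = 60) {
  stopifnot(is_coverage_track(track))
  regions <- as_regions(regions)
  if (length(regions) == 0L) stopf("empty region list")
  if (flank_bp < 0 || flank_bp %% track$bin_size != 0)
    stopf("flank_bp must be a non-negative multiple of the bin size (%d)",
          track$bin_size)
  lens <- track$chrom_sizes[as.character(GenomeInfoDb::seqnames(regions))]
  keep <- GenomicRanges::start(regions) - flank_bp >= 1 &
    GenomicRanges::end(regions) + flank_bp <= lens
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("metagene_profile: dropped %d region(s) at chromosome edges",
                    n_dropped))
  regions <- regions[keep]
  if (length(regions) == 0L) stopf("no regions left after edge filtering")

  bs <- track$bin_size
  nf <- as.integer(flank_bp / bs)
  ch <- as.character(GenomeInfoDb::seqnames(regions))
  s0 <- GenomicRanges::start(regions) - 1   # 0-based
  e0 <- as.numeric(GenomicRanges::end(regions))
  W <- e0 - s0
  nr <- length(regions)
  ncol_total <- 2L * nf + body_bins

  ## per-region sub-interval boundaries: left flank | body fractions | right
  bounds <- matrix(0, nr, ncol_total + 1L)
  if (nf > 0) {
    bounds[, seq_len(nf + 1L)] <- outer(s0, (0:nf - nf) * bs, `+`)
    bounds[, ncol_total + 1L - (nf:0)] <- outer(e0, (0:nf) * bs, `+`)
  } else {
    bounds[, 1L] <- s0; bounds[, ncol_total + 1L] <- e0
  }
  bounds[, nf + 1L + 0:body_bins] <- s0 + outer(W, 0:body_bins / body_bins)

  counts <- matrix(region_counts0(track,
                                  rep(ch, ncol_total),
                                  as.vector(bounds[, -(ncol_total + 1L)]),
                                  as.vector(bounds[, -1L])),
                   nr, ncol_total)
  widths <- bounds[, -1L, drop = FALSE] - bounds[, -(ncol_total + 1L), drop = FALSE]
  dens <- counts * (1e6 / track$total_mapped) / widths
  centers <- c(-(nf:1) * bs + bs / 2,
               (seq_len(body_bins) - 0.5) / body_bins,
               (seq_len(nf) - 0.5) * bs)
  structure(list(density = colMeans(dens), position = centers,
                 flank_bp = flank_bp, body_bins = body_bins,
                 bin_size = bs, n_regions = nr, n_dropped = n_dropped),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "metagene_profile: %d regions, flank %d bp, %d body bins, peak %.4g RPM/bp\n",
    x$n_regions, x$flank_bp, x$body_bins, max(x$density)))
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(position = x$position, density = x$density)
}

#' Gene-by-factor density matrix ranked by one factor
#'
#' Computes each factor's density (RPM/bp) over the TSS +/- `window`
#' window per gene and orders genes by descending density of
#' `rank_factor` (ties by gene id) -- the representation used to show
#' that condensin II and cohesin track POL II levels at genes.
#'
#' @param tracks named list of [coverage_track()]s.
#' @param genes gene table.
#' @param window half-window around the TSS (bp, default 1000).
#' @param rank_factor name of the track to rank by (must be in `tracks`).
#' @return A data frame: `gene_id` then one density column per factor,
#'   rows ordered by the ranking factor.
#' @export
ranked_gene_matrix <- function(tracks, genes, window = 1000,
                               rank_factor = "POL2") {
  if (!rank_factor %in% names(tracks))
    stopf("rank_factor '%s' not among the supplied tracks", rank_factor)
  sizes <- tracks[[1L]]$chrom_sizes
  known <- genes$chrom %in% names(sizes)
  if (any(!known)) {
    message(sprintf("ranked_gene_matrix: skipping %d gene(s) on unknown chromosomes",
                    sum(!known)))
    genes <- genes[known, , drop = FALSE]
  }
  st <- pmax(genes$tss - window, 1)
  en <- pmin(genes$tss + window, sizes[genes$chrom])
  gr <- genomic_intervals(genes$chrom, st, en, chrom_sizes = sizes)
  m <- vapply(tracks, region_signal, numeric(length(gr)),
              regions = gr, mode = "density_rpm_per_bp")
  m <- matrix(m, nrow = length(gr),
              dimnames = list(NULL, names(tracks)))
  ord <- order(-m[, rank_factor], genes$gene_id)
  data.frame(gene_id = genes$gene_id[ord], m[ord, , drop = FALSE],
             stringsAsFactors = FALSE)
}
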