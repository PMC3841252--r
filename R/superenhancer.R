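#' Stitch enhancer constituents into candidate super-enhancer domains
#'
#' Constituents separated by at most `stitch_distance` bp are merged into
#' one stitched enhancer (default 12,500 bp, the conventional stitching
#' window for super-enhancer calling); each stitched enhancer records its
#' constituents.
#'
#' @param constituents a `GRanges` (or [occupancy_set()]) of enhancer
#'   constituents.
#' @param stitch_distance maximum gap (bp) across which constituents are
#'   stitched.
#' @return A list of class `stitched_enhancers` with `spans` (a sorted
#'   `GRanges`, mcols `n_constituents`), and `constituents` (list of
#'   `GRanges`, parallel to `spans`).
#' @export
stitch_constituents <- function(constituents, stitch_distance = 12500) {
  constituents <- as_regions(constituents)
  constituents <- merge_intervals(constituents, 0)
  red <- GenomicRanges::reduce(constituents,
                               min.gapwidth = stitch_distance + 1,
                               with.revmap = TRUE, ignore.strand = TRUE)
  ord <- GenomicRanges::order(red)
  red <- red[ord]
  revmap <- S4Vectors::mcols(red)$revmap
  parts <- lapply(seq_along(red), function(i) constituents[revmap[[i]]])
  spans <- GenomicRanges::granges(red)
  S4Vectors::mcols(spans)$n_constituents <- lengths(revmap)
  structure(list(spans = spans, constituents = parts,
                 stitch_distance = stitch_distance),
            class = "stitched_enhancers")
}

#' @export
print.stitched_enhancers <- function(x, ...) {
  cat(sprintf("stitched_enhancers: %d domains from %d constituents (stitch %d bp)\n",
              length(x$spans), sum(lengths(x$constituents)),
              x$stitch_distance))
  invisible(x)
}

#' Rank stitched enhancers by background-subtracted signal
#'
#' Signal is the total RPM of the factor track over the stitched span
#' minus the total RPM of the control track (if given); negative values
#' are recorded but floored at 0 for ranking so the cutoff geometry stays
#' stable.  Output is sorted by ascending ranking signal, ties broken by
#' span start.
#'
#' @param stitched a [stitch_constituents()] result.
#' @param signal_track a [coverage_track()] (e.g. MED1).
#' @param control_track optional control [coverage_track()] with the same
#'   binning.
#' @return A `stitched_enhancers` list with additional fields: `signal`
#'   (floored, ascending), `signal_raw`, and `rank`.
#' @export
rank_by_signal <- function(stitched, signal_track, control_track = NULL) {
  stopifnot(inherits(stitched, "stitched_enhancers"))
  raw <- region_signal(signal_track, stitched$spans, "total_rpm")
  if (!is.null(control_track)) {
    if (control_track$bin_size != signal_track$bin_size)
      stopf("signal and control tracks must share binning")
    raw <- raw - region_signal(control_track, stitched$spans, "total_rpm")
  }
  sig <- pmax(raw, 0)
  ord <- order(sig, GenomicRanges::start(stitched$spans),
               as.character(GenomeInfoDb::seqnames(stitched$spans)))
  out <- stitched
  out$spans <- stitched$spans[ord]
  out$constituents <- stitched$constituents[ord]
  out$signal <- sig[ord]
  out$signal_raw <- raw[ord]
  out$rank <- seq_along(ord)
  out
}

#' Inflection cutoff on the ranked signal curve
#'
#' Both axes of the ranked curve (rank, signal) are scaled to \[0, 1\]
#' and the cutoff is placed where a line of slope 1 is tangent to the
#' curve -- the point at which, descending from the top, the slope of the
#' curve falls through 1.  On sampled data the per-adjacent-point slope
#' is noisy, so the tangent point is located as the position where the
#' scaled curve lies farthest below the unit-slope diagonal (for a convex
#' ranked curve the two definitions coincide); the highest such position
#' is taken when tied.  Entries strictly above the cutoff are
#' super-enhancers.  A curve with all signals equal (no geometry) yields
#' no super-enhancers.
#'
#' @param signals numeric vector of ranking signals in ascending order.
#' @return The cutoff index (number of typical enhancers).
#' @export
find_inflection_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 2L) stopf("need at least 2 enhancers to locate a cutoff")
  if (is.unsorted(signals)) stopf("`signals` must be ascending")
  rng <- max(signals) - min(signals)
  if (rng == 0) return(n)
  y <- (signals - min(signals)) / rng
  x <- (seq_len(n) - 1) / (n - 1)
  d <- y - x                       # depth below the slope-1 diagonal
  max(which(d == min(d)))
}

#' Partition stitched enhancers into super and typical
#'
#' @param ranked a [rank_by_signal()] result.
#' @return A list of class `se_partition` with the ranked object,
#'   `cutoff_index`, and `class` (`"typical"`/`"super"`, parallel to the
#'   ranked spans).
#' @export
partition_super_enhancers <- function(ranked) {
  stopifnot(inherits(ranked, "stitched_enhancers"),
            !is.null(ranked$signal))
  cut <- find_inflection_cutoff(ranked$signal)
  cls <- ifelse(seq_along(ranked$signal) > cut, "super", "typical")
  structure(list(ranked = ranked, cutoff_index = cut, class = cls),
            class = "se_partition")
}

#' @export
print.se_partition <- function(x, ...) {
  cat(sprintf("se_partition: %d super-enhancers, %d typical enhancers\n",
              sum(x$class == "super"), sum(x$class == "typical")))
  invisible(x)
}

partition_spans <- function(partition, which) {
  partition$ranked$spans[partition$class == which]
}

partition_constituents <- function(partition, which) {
  parts <- partition$ranked$constituents[partition$class == which]
  if (length(parts) == 0L) return(NULL)
  do.call(c, parts)
}

#' Signal fold difference between super- and typical enhancers
#'
#' `mode = "enhancers"`: mean total ChIP-seq signal (RPM) over
#' super-enhancer spans divided by the mean over typical-enhancer spans.
#' `mode = "constituents"`: mean ChIP-seq *density* (RPM per bp) at
#' super-enhancer constituents divided by the mean density at typical
#' constituents.
#'
#' @param track a [coverage_track()] for the factor of interest.
#' @param partition a [partition_super_enhancers()] result.
#' @param mode `"enhancers"` or `"constituents"`.
#' @return A single fold-difference value.
#' @export
fold_difference <- function(track, partition,
                            mode = c("enhancers", "constituents")) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "se_partition"))
  if (!any(partition$class == "super") || !any(partition$class == "typical"))
    stopf("both enhancer classes must be non-empty")
  if (mode == "enhancers") {
    num <- mean(region_signal(track, partition_spans(partition, "super"),
                              "total_rpm"))
    den <- mean(region_signal(track, partition_spans(partition, "typical"),
                              "total_rpm"))
  } else {
    num <- mean(region_signal(track, partition_constituents(partition, "super"),
                              "density_rpm_per_bp"))
    den <- mean(region_signal(track, partition_constituents(partition, "typical"),
                              "density_rpm_per_bp"))
  }
  if (den == 0) stopf("typical-enhancer signal is zero; fold undefined")
  num / den
}

#' Export a partition as a ranked table
#'
#' @param partition an `se_partition`.
#' @return Data frame with rank, span, constituent count, signal, class.
#' @export
partition_table <- function(partition) {
  r <- partition$ranked
  data.frame(rank = r$rank,
             chrom = as.character(GenomeInfoDb::seqnames(r$spans)),
             start = GenomicRanges::start(r$spans),
             end = GenomicRanges::end(r$spans),
             n_constituents = S4Vectors::mcols(r$spans)$n_constituents,
             signal = r$signal, signal_raw = r$signal_raw,
             class = partition$class, stringsAsFactors = FALSE)
}
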