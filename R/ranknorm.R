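#' Rank-normalize a pair of coverage tracks
#'
#' Puts two conditions (e.g. a factor's ChIP-seq before and after a
#' knockdown) on a shared quantile scale so occupancy can be compared
#' across them.  The support is the set of bins nonzero in either track;
#' over the support, each track's values are replaced by the value at the
#' same rank in the averaged reference distribution -- the mean of the two
#' samples' sorted support values -- with ties sharing the mean of their
#' rank range.  By construction the two outputs have (up to tie
#' averaging) identical value multisets.  Bins zero in both tracks stay
#' zero; no display floor is applied here (see [write_bedgraph()] for the
#' export-time floor).
#'
#' @param track_a,track_b [coverage_track()]s with identical binning and
#'   chromosomes; neither may be all zero.
#' @param reference optional sorted numeric vector to map both tracks
#'   onto instead of the averaged reference computed from the pair;
#'   normalizing against a fixed reference depends on each track only
#'   through its ranks, so it is invariant under strictly increasing,
#'   zero-preserving transforms of the counts.
#' @return A list with `tracks` (list of the two normalized tracks) and
#'   `reference` (the sorted reference distribution used).
#' @export
rank_normalize <- function(track_a, track_b, reference = NULL) {
  stopifnot(is_coverage_track(track_a), is_coverage_track(track_b))
  if (track_a$bin_size != track_b$bin_size ||
      !identical(names(track_a$counts), names(track_b$counts)))
    stopf("tracks must share binning and chromosomes")
  va_all <- unlist(track_a$counts, use.names = FALSE)
  vb_all <- unlist(track_b$counts, use.names = FALSE)
  if (length(va_all) != length(vb_all))
    stopf("tracks must share binning and chromosomes")
  if (all(va_all == 0) || all(vb_all == 0))
    stopf("cannot rank-normalize an all-zero track")
  support <- which(va_all != 0 | vb_all != 0)
  va <- va_all[support]; vb <- vb_all[support]
  if (is.null(reference)) reference <- (sort(va) + sort(vb)) / 2
  if (length(reference) != length(va))
    stopf("reference length does not match the support (%d bins)",
          length(va))
  rebuild <- function(track, mapped) {
    full <- numeric(length(va_all))
    full[support] <- mapped
    counts <- list()
    off <- 0L
    for (ch in names(track$counts)) {
      nb <- length(track$counts[[ch]])
      counts[[ch]] <- full[off + seq_len(nb)]
      off <- off + nb
    }
    coverage_track(counts, track$bin_size, track$total_mapped,
                   track$chrom_sizes, track$extend_len)
  }
  list(tracks = list(rebuild(track_a, map_to_reference(va, reference)),
                     rebuild(track_b, map_to_reference(vb, reference))),
       reference = reference)
}

#' Map values onto a reference distribution by rank
#'
#' The workhorse of [rank_normalize()]: value at rank r receives the r-th
#' smallest reference value; tied values share the mean of the reference
#' values over their rank range.
#'
#' @param values numeric vector.
#' @param reference sorted numeric vector, same length as `values`.
#' @return Numeric vector of mapped values.
#' @export
map_to_reference <- function(values, reference) {
  if (length(values) != length(reference))
    stopf("values and reference must have equal length")
  ord <- order(values)
  sorted <- values[ord]
  grp <- cumsum(c(TRUE, sorted[-1] != sorted[-length(sorted)]))
  ref_mean <- stats::ave(reference, grp)      # mean of each tie block
  out <- numeric(length(values))
  out[ord] <- ref_mean
  out
}
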