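#' Define enhancer regions from master transcription-factor co-occupancy
#'
#' Enhancers are the regions occupied simultaneously by OCT4, SOX2 and
#' NANOG; the result is the per-base intersection of the three occupancy
#' sets, labelled "OSN".
#'
#' @param oct4,sox2,nanog [occupancy_set()]s (or bare `GRanges`).
#' @return An [occupancy_set()] with factor `"OSN"`.
#' @export
define_enhancers <- function(oct4, sox2, nanog) {
  occupancy_set("OSN", intersect_all(lapply(list(oct4, sox2, nanog),
                                            as_regions)))
}

#' Define promoter regions from TBP and POL II co-occupancy
#'
#' @param tbp, polii [occupancy_set()]s (or bare `GRanges`).
#' @param polii second occupancy set.
#' @return An [occupancy_set()] with factor `"TBP_POL2"`.
#' @export
define_promoters <- function(tbp, polii) {
  occupancy_set("TBP_POL2", intersect_all(lapply(list(tbp, polii),
                                                 as_regions)))
}

#' Define heterochromatin as the union of repressive-mark domains
#'
#' Regions carrying H3K9me3 *or* H4K20me3, merged.
#'
#' @param h3k9me3,h4k20me3 [occupancy_set()]s (or bare `GRanges`).
#' @return An [occupancy_set()] with factor `"heterochromatin"`.
#' @export
define_heterochromatin <- function(h3k9me3, h4k20me3) {
  occupancy_set("heterochromatin",
                union_all(lapply(list(h3k9me3, h4k20me3), as_regions)))
}

#' Genes co-occupied by condensin II and cohesin near the TSS
#'
#' A gene counts as co-occupied when at least one CAPH2 region *and* at
#' least one SMC1 region lie within `window` bp of its TSS
#' (edge-to-point distance, 0 if the TSS falls inside a region).
#'
#' @param caph2,smc1 [occupancy_set()]s (or bare `GRanges`).
#' @param genes gene table (see [make_genome()]).
#' @param window TSS window in bp (default 2500).
#' @return Sorted character vector of gene ids.
#' @export
co_occupied_genes <- function(caph2, smc1, genes, window = 2500) {
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stopf("`genes` must be a non-empty data frame")
  near <- function(set) {
    r <- as_regions(set)
    vapply(seq_len(nrow(genes)), function(i) {
      sel <- as.character(GenomeInfoDb::seqnames(r)) == genes$chrom[i]
      if (!any(sel)) return(FALSE)
      any(point_interval_distance(genes$tss[i],
                                  GenomicRanges::start(r)[sel],
                                  GenomicRanges::end(r)[sel]) <= window)
    }, TRUE)
  }
  sort(genes$gene_id[near(caph2) & near(smc1)])
}

#' Assign each enhancer to its nearest gene
#'
#' Applies [nearest_tss()] per enhancer with a maximum assignment
#' distance (default 50 kb); enhancers farther than that from every TSS
#' stay unassigned.
#'
#' @param enhancers a `GRanges` (e.g. stitched enhancer spans).
#' @param genes gene table.
#' @param max_distance maximum TSS distance (bp).
#' @return A data frame with one row per enhancer: `chrom`, `start`,
#'   `end`, `gene_id` (`NA` if unassigned), `distance`.
#' @export
genes_of_enhancers <- function(enhancers, genes, max_distance = 50000) {
  stopifnot(is(enhancers, "GRanges"))
  res <- lapply(seq_along(enhancers), function(i)
    nearest_tss(enhancers[i], genes, max_distance))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(enhancers)),
             start = GenomicRanges::start(enhancers),
             end = GenomicRanges::end(enhancers),
             gene_id = vapply(res, `[[`, "", "gene_id"),
             distance = vapply(res, `[[`, 0, "distance"),
             stringsAsFactors = FALSE)
}
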