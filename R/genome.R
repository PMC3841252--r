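#' Configuration for the toy regulatory genome
#'
#' Collects the layout parameters of the synthetic genome on which the
#' whole pipeline is exercised.  The defaults define the demo study
#' conditions: a 20 Mb two-chromosome genome carrying 20 super-enhancer
#' constituent clusters, 300 typical enhancer constituents, one gene (with
#' promoter) per enhancer plus unassociated genes, and heterochromatin
#' domains, with factor enrichment rules for the ChIP-seq panel
#' (OCT4/SOX2/NANOG, MED1, NIPBL, SMC1, CAPH2, TBP, POL2, H3K9me3,
#' H4K20me3, CTCF, WCE control).
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_se_clusters number of planted super-enhancer clusters.
#' @param constituents_per_cluster constituents per cluster.
#' @param se_constituent_width,se_constituent_gap constituent width and
#'   intra-cluster gap (bp); with the defaults a cluster spans 9 kb,
#'   commensurate with the ~8.7 kb median super-enhancer.
#' @param n_typical number of typical enhancer constituents (default
#'   width 700 bp, close to the ~703 bp median typical enhancer).
#' @param typical_width typical constituent width (bp).
#' @param n_other_genes genes with a promoter but no planted enhancer.
#' @param n_heterochromatin,heterochromatin_width heterochromatin domains.
#' @param gene_span gene length (bp).
#' @param promoter_halfwidth promoter half-width around the TSS (bp).
#' @param gene_offset_range min/max distance (bp) from an enhancer to its
#'   gene's proximal edge.
#' @param stitch_distance stitching distance (bp) used both to space
#'   planted elements (clusters are guaranteed farther than this from any
#'   other constituent) and downstream by [stitch_constituents()].
#' @param factor_profiles named list of [enrichment_rule()]s.
#' @param seed integer seed making the layout reproducible.
#' @return A list of class `genome_config`.
#' @export
layout_config <- function(chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                          n_se_clusters = 20,
                          constituents_per_cluster = 5,
                          se_constituent_width = 1000,
                          se_constituent_gap = 1000,
                          n_typical = 300,
                          typical_width = 700,
                          n_other_genes = 60,
                          n_heterochromatin = 10,
                          heterochromatin_width = 50000,
                          gene_span = 8000,
                          promoter_halfwidth = 250,
                          gene_offset_range = c(3000, 8000),
                          stitch_distance = 12500,
                          factor_profiles = default_factor_profiles(),
                          seed = 1) {
  cfg <- as.list(environment())
  if (any(chrom_sizes <= 0)) stopf("chromosome sizes must be positive")
  counts <- c(n_se_clusters, n_typical, n_other_genes, n_heterochromatin)
  if (any(counts < 0)) stopf("element counts must be >= 0")
  structure(cfg, class = "genome_config")
}

#' Factor-specific enrichment rule
#'
#' Expected reads per bp inside an element class are
#' `background_rate * fold[class]` (and `background_rate * 1` elsewhere),
#' before rescaling to the requested sequencing depth.  A fold of 0 means
#' the factor is depleted to nothing in that class (used for the
#' heterochromatin marks at enhancers/promoters and vice versa).
#'
#' @param background_rate relative background read rate per bp (> 0).
#' @param folds named numeric vector of per-class fold enrichments
#'   (finite, >= 0); classes are `typical_constituent`, `se_constituent`,
#'   `promoter`, `gene_body`, `heterochromatin`.
#' @param fold_cv between-element variability of the fold: each enriched
#'   element's fold is multiplied by a mean-1 log-normal factor with this
#'   log-scale SD (default 0 = homogeneous).  Used to model site-to-site
#'   differences in factor dependence, e.g. condensin II binding after
#'   NIPBL knockdown, where some sites lose far more signal than others.
#' @return A list of class `enrichment_rule`.
#' @export
enrichment_rule <- function(background_rate = 1, folds = numeric(),
                            fold_cv = 0) {
  if (!is.numeric(background_rate) || background_rate <= 0)
    stopf("background_rate must be > 0")
  if (length(folds) && (any(!is.finite(folds)) || any(folds < 0)))
    stopf("folds must be finite and >= 0")
  if (!is.numeric(fold_cv) || fold_cv < 0) stopf("fold_cv must be >= 0")
  structure(list(background_rate = background_rate, folds = folds,
                 fold_cv = fold_cv),
            class = "enrichment_rule")
}

element_classes <- c("typical_constituent", "se_constituent", "promoter",
                     "gene_body", "heterochromatin")

#' Default enrichment rules for the simulated ChIP-seq panel
#'
#' Magnitudes are free parameters of the simulation (the study reports no
#' quantitative enrichment values); they are fixed once here so that the
#' planted MED1 constituent-density ratio between super-enhancer and
#' typical constituents is 50/20 = 2.5.
#'
#' @return Named list of [enrichment_rule()]s.
#' @export
default_factor_profiles <- function() {
  rule <- function(te, se, prom, body, het)
    enrichment_rule(1, c(typical_constituent = te, se_constituent = se,
                         promoter = prom, gene_body = body,
                         heterochromatin = het))
  list(
    OCT4     = rule(20, 50,  1, 1,  0),
    SOX2     = rule(20, 50,  1, 1,  0),
    NANOG    = rule(20, 50,  1, 1,  0),
    MED1     = rule(20, 50, 10, 1,  0),
    NIPBL    = rule(10, 25, 10, 1,  0),
    SMC1     = rule(10, 25, 10, 1,  0),
    CAPH2    = rule(10, 25, 10, 1,  0),
    TBP      = rule( 1,  1, 30, 1,  0),
    POL2     = rule( 2,  2, 30, 3,  0),
    H3K9me3  = rule( 0,  0,  0, 1, 30),
    H4K20me3 = rule( 0,  0,  0, 1, 30),
    CTCF     = rule( 1,  1,  5, 1,  1),
    WCE      = rule( 1,  1,  1, 1,  1)
  )
}

## realize one placement unit (coordinates relative to the unit start,
## 0-based); returns element descriptors and the unit footprint
realize_unit <- function(type, cfg) {
  ph <- cfg$promoter_halfwidth
  gene_at <- function(at) {
    strand <- sample(c("+", "-"), 1L)
    start <- at + 1L                       # 1-based
    end <- at + cfg$gene_span
    tss <- if (strand == "+") start else end
    list(strand = strand, start = start, end = end, tss = tss,
         promoter = c(tss - ph, tss + ph))
  }
  out <- list(constituents = NULL, gene = NULL, het = NULL)
  if (type == "se") {
    k <- cfg$constituents_per_cluster
    w <- cfg$se_constituent_width; g <- cfg$se_constituent_gap
    st <- (seq_len(k) - 1L) * (w + g)
    out$constituents <- cbind(start = st + 1L, end = st + w)
    cluster_end <- st[k] + w
    off <- floor(runif(1, cfg$gene_offset_range[1], cfg$gene_offset_range[2]))
    out$gene <- gene_at(cluster_end + off)
  } else if (type == "te") {
    out$constituents <- cbind(start = 1L, end = cfg$typical_width)
    off <- floor(runif(1, cfg$gene_offset_range[1], cfg$gene_offset_range[2]))
    out$gene <- gene_at(cfg$typical_width + off)
  } else if (type == "gene") {
    out$gene <- gene_at(ph + 50L)
  } else if (type == "het") {
    out$het <- c(1L, cfg$heterochromatin_width)
  }
  ends <- c(if (!is.null(out$constituents)) max(out$constituents[, "end"]),
            if (!is.null(out$gene)) max(out$gene$end, out$gene$promoter[2]),
            if (!is.null(out$het)) out$het[2])
  out$width <- max(ends) + 100L            # small pad
  out$type <- type
  out
}

#' Generate a toy genome with planted regulatory elements
#'
#' Places super-enhancer constituent clusters, typical enhancer
#' constituents, genes with promoters, and heterochromatin domains on the
#' configured chromosomes.  Placement guarantees the layout invariants:
#' all elements lie within their chromosome; constituents of one cluster
#' are mutually within the stitch distance while clusters (and all other
#' planted elements) are separated by more than the stitch distance; and
#' element classes are pairwise disjoint.
#'
#' @param config a [layout_config()].
#' @return A list of class `genome_layout` with components `chrom_sizes`,
#'   `genes` (data frame incl. planted `class`: `"se"`, `"te"`,
#'   `"other"`), `se_clusters` (list of `GRanges`), the planted element
#'   `GRanges` (`typical_constituents`, `promoters`, `gene_bodies`,
#'   `heterochromatin`), `factor_profiles`, `stitch_distance`.
#' @export
make_genome <- function(config = layout_config()) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(config$seed, make_genome_impl(config))
}

make_genome_impl <- function(cfg) {
  types <- c(rep("se", cfg$n_se_clusters), rep("te", cfg$n_typical),
             rep("gene", cfg$n_other_genes),
             rep("het", cfg$n_heterochromatin))
  if (length(types)) types <- sample(types)
  units <- lapply(types, realize_unit, cfg = cfg)

  min_spacing <- cfg$stitch_distance + 1000
  total <- sum(cfg$chrom_sizes)
  required <- sum(vapply(units, `[[`, 0, "width")) +
    length(units) * min_spacing
  if (required > total)
    stopf("infeasible packing: %d elements need %.0f bp but genome has %.0f",
          length(units), required, total)
  slack <- (total - required) / max(1L, length(units))

  chroms <- names(cfg$chrom_sizes)
  ci <- 1L; cursor <- 0
  placed <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    repeat {
      gap <- min_spacing + floor(runif(1, 0, max(1, slack)))
      at <- cursor + gap
      if (at + u$width <= cfg$chrom_sizes[[ci]]) break
      ci <- ci + 1L; cursor <- 0
      if (ci > length(chroms))
        stopf("infeasible packing: ran out of genome while placing elements")
    }
    u$chrom <- chroms[ci]; u$offset <- at
    cursor <- at + u$width
    placed[[i]] <- u
  }

  gather <- function(sel, f) {
    rows <- lapply(placed[vapply(placed, sel, TRUE)], f)
    do.call(rbind, rows)
  }
  empty_gr <- genomic_intervals(character(), integer(), integer(),
                                chrom_sizes = cfg$chrom_sizes)
  gr_of <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(empty_gr)
    genomic_intervals(m[, 1], as.integer(m[, 2]), as.integer(m[, 3]),
                      chrom_sizes = cfg$chrom_sizes)
  }

  se_units <- placed[vapply(placed, function(u) u$type == "se", TRUE)]
  se_clusters <- lapply(se_units, function(u)
    gr_of(cbind(u$chrom, u$offset + u$constituents[, "start"],
                u$offset + u$constituents[, "end"])))
  typical <- gr_of(gather(function(u) u$type == "te", function(u)
    cbind(u$chrom, u$offset + u$constituents[, "start"],
          u$offset + u$constituents[, "end"])))
  het <- gr_of(gather(function(u) u$type == "het", function(u)
    cbind(u$chrom, u$offset + u$het[1], u$offset + u$het[2])))

  gene_units <- placed[vapply(placed, function(u) !is.null(u$gene), TRUE)]
  genes <- if (length(gene_units)) {
    data.frame(
      gene_id = sprintf("G%04d", seq_along(gene_units)),
      chrom = vapply(gene_units, `[[`, "", "chrom"),
      strand = vapply(gene_units, function(u) u$gene$strand, ""),
      tss = vapply(gene_units, function(u) u$offset + u$gene$tss, 0),
      start = vapply(gene_units, function(u) u$offset + u$gene$start, 0),
      end = vapply(gene_units, function(u) u$offset + u$gene$end, 0),
      class = vapply(gene_units, function(u)
        switch(u$type, se = "se", te = "te", "other"), ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), tss = numeric(), start = numeric(),
               end = numeric(), class = character())
  }

  promoters <- if (length(gene_units)) {
    gr_of(do.call(rbind, lapply(gene_units, function(u)
      cbind(u$chrom, u$offset + u$gene$promoter[1],
            u$offset + u$gene$promoter[2]))))
  } else empty_gr
  spans <- if (nrow(genes)) {
    genomic_intervals(genes$chrom, genes$start, genes$end,
                      chrom_sizes = cfg$chrom_sizes)
  } else empty_gr
  gene_bodies <- GenomicRanges::setdiff(spans, promoters,
                                        ignore.strand = TRUE)

  structure(list(chrom_sizes = cfg$chrom_sizes, genes = genes,
                 se_clusters = se_clusters,
                 typical_constituents = typical,
                 promoters = promoters, gene_bodies = gene_bodies,
                 heterochromatin = het,
                 factor_profiles = cfg$factor_profiles,
                 stitch_distance = cfg$stitch_distance,
                 config = cfg),
            class = "genome_layout")
}

#' All planted elements of a layout, labelled by class
#'
#' @param layout a [make_genome()] layout.
#' @return A `GRanges` with an mcols `class` column; classes are pairwise
#'   disjoint by construction.
#' @export
elements_of <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  se <- if (length(layout$se_clusters))
    do.call(c, layout$se_clusters)
  else layout$typical_constituents[0]
  parts <- list(typical_constituent = layout$typical_constituents,
                se_constituent = se,
                promoter = layout$promoters,
                gene_body = layout$gene_bodies,
                heterochromatin = layout$heterochromatin)
  gr <- do.call(c, unname(parts))
  S4Vectors::mcols(gr)$class <- rep(names(parts),
                                    vapply(parts, length, 0L))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Check the structural invariants of a layout
#'
#' Verifies containment within chromosomes, pairwise disjointness of the
#' element classes, intra-cluster proximity (constituents of one cluster
#' mutually within the stitch distance) and cluster isolation (every
#' cluster farther than the stitch distance from any other constituent).
#'
#' @param layout a [make_genome()] layout.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_layout <- function(layout) {
  el <- elements_of(layout)
  sizes <- layout$chrom_sizes
  if (length(el)) {
    lens <- sizes[as.character(GenomeInfoDb::seqnames(el))]
    if (any(GenomicRanges::start(el) < 1) ||
        any(GenomicRanges::end(el) > lens))
      stopf("element outside chromosome bounds")
    if (!GenomicRanges::isDisjoint(el, ignore.strand = TRUE))
      stopf("element classes overlap")
  }
  d <- layout$stitch_distance
  all_const <- c(if (length(layout$se_clusters)) do.call(c, layout$se_clusters)
                 else layout$typical_constituents[0],
                 layout$typical_constituents)
  for (cl in layout$se_clusters) {
    if (length(cl) > 1L) {
      gaps <- GenomicRanges::start(cl)[-1] - GenomicRanges::end(cl)[-length(cl)] - 1L
      if (any(gaps > d)) stopf("cluster constituents farther than stitch distance")
    }
    others <- all_const[!all_const %over% cl]
    others <- others[as.character(GenomeInfoDb::seqnames(others)) %in%
                     as.character(GenomeInfoDb::seqnames(cl))]
    if (length(others)) {
      dd <- GenomicRanges::distanceToNearest(others, cl)
      if (length(dd) && any(S4Vectors::mcols(dd)$distance <= d))
        stopf("cluster within stitch distance of an outside constituent")
    }
  }
  ep <- union_all(list(layout$typical_constituents,
                       if (length(layout$se_clusters)) do.call(c, layout$se_clusters)
                       else layout$typical_constituents[0],
                       layout$promoters))
  if (length(GenomicRanges::intersect(ep, layout$heterochromatin,
                                      ignore.strand = TRUE)))
    stopf("heterochromatin overlaps enhancer/promoter elements")
  invisible(TRUE)
}
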