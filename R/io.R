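#' Read a BED file of intervals or reads
#'
#' BED is treated as 0-based half-open on disk; the returned `GRanges`
#' uses the usual 1-based closed convention.  An empty file yields an
#' empty `GRanges`.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, coordinates are validated against it (strict mode).
#' @return A `GRanges`, with `name`/`score` columns when present.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L)
    return(genomic_intervals(character(), integer(), integer(),
                             chrom_sizes = chrom_sizes))
  problems <- validate_bed(path, chrom_sizes = chrom_sizes)
  if (nrow(problems) > 0L)
    stopf("malformed BED %s: %s", path,
          paste(sprintf("line %d: %s", problems$line, problems$problem),
                collapse = "; "))
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(chrom_sizes))
    GenomeInfoDb::seqlengths(gr)[names(chrom_sizes)] <- as.numeric(chrom_sizes)
  }
  gr
}

#' Validate a BED file line by line
#'
#' Reports malformed lines with their line numbers instead of failing on
#' the first problem: too few fields, non-numeric or negative coordinates,
#' `start >= end` (which also flags 1-based off-by-one input whose width-1
#' features collapse), and, when `chrom_sizes` is given, unknown
#' chromosomes or out-of-range ends.
#'
#' @inheritParams read_bed
#' @return A data frame with columns `line` and `problem` (zero rows if
#'   the file is clean).
#' @export
validate_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  probs <- list()
  note <- function(i, msg) probs[[length(probs) + 1L]] <<-
    data.frame(line = i, problem = msg)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) { note(i, "fewer than 3 fields"); next }
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) { note(i, "non-numeric coordinates"); next }
    if (s < 0) note(i, "negative start")
    else if (s >= e) note(i, "start >= end (check 0-based half-open convention)")
    else if (!is.null(chrom_sizes)) {
      if (!f[1L] %in% names(chrom_sizes)) note(i, sprintf("unknown chrom '%s'", f[1L]))
      else if (e > chrom_sizes[[f[1L]]]) note(i, "end beyond chromosome length")
    }
  }
  if (length(probs) == 0L)
    return(data.frame(line = integer(), problem = character()))
  do.call(rbind, probs)
}

#' Write intervals to BED, sorted by chromosome and start
#'
#' @param x a `GRanges`; `name`/`score` metadata columns are written when
#'   present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  x <- GenomeInfoDb::sortSeqlevels(x)
  x <- GenomicRanges::sort(x, ignore.strand = TRUE)
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Export a coverage track as bedGraph
#'
#' Bins are written as per-bin intervals with the RPM value as score.
#' `floor` reproduces the display convention of rank-normalized tracks
#' (y-axis floor, default 0.2 in the analyses that use it): values below
#' the floor are *exported* as the floor; in-memory analysis values are
#' never floored.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param floor optional display floor applied at export only.
#' @param rpm write reads-per-million (default) rather than raw bin counts.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, floor = NULL, rpm = TRUE) {
  stopifnot(is_coverage_track(track))
  scale <- if (rpm) {
    if (track$total_mapped == 0) stopf("cannot scale to RPM: no mapped reads")
    1e6 / track$total_mapped
  } else 1
  grl <- lapply(names(track$counts), function(ch) {
    v <- track$counts[[ch]] * scale
    if (!is.null(floor)) v <- pmax(v, floor)
    nb <- length(v)
    keep <- v != 0 | !is.null(floor)
    st <- (seq_len(nb) - 1L) * track$bin_size + 1L
    en <- pmin(seq_len(nb) * track$bin_size, track$chrom_sizes[[ch]])
    GenomicRanges::GRanges(ch, IRanges::IRanges(st[keep], en[keep]),
                           score = v[keep])
  })
  gr <- do.call(c, grl)
  GenomeInfoDb::seqlevels(gr) <- names(track$chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- as.numeric(track$chrom_sizes)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path file path.
#' @return A `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0L)
    return(GenomicRanges::GRanges(score = numeric()))
  rtracklayer::import(path, format = "bedGraph")
}

#' Read and write the gene-model table
#'
#' On disk the table is TSV with 0-based coordinates (`tss0`, `start0`
#' inclusive, `end0` exclusive); in memory coordinates are 1-based closed,
#' matching the `GRanges` convention used throughout.
#'
#' @param path file path.
#' @return A data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end` (plus `class` if stored).
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss0", "start0", "end0")
  if (!all(need %in% names(df)))
    stopf("gene table %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    strand = df$strand, tss = df$tss0 + 1L,
                    start = df$start0 + 1L, end = df$end0,
                    stringsAsFactors = FALSE)
  if ("class" %in% names(df)) out$class <- df$class
  out
}

#' @rdname read_gene_table
#' @param genes in-memory gene table (1-based).
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss0 = genes$tss - 1L,
                    start0 = genes$start - 1L, end0 = genes$end)
  if ("class" %in% names(genes)) out$class <- genes$class
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene-by-sample count tables
#'
#' TSV with a `gene_id` column followed by one column per sample; a
#' companion samples TSV (`sample`, `condition`, `replicate`) carries the
#' metadata.
#'
#' @param counts_path,samples_path file paths.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(counts_path, samples_path) {
  cts <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  expression_table(m, samples)
}

#' @rdname read_expression_table
#' @param tbl an [expression_table()].
#' @export
write_expression_table <- function(tbl, counts_path, samples_path) {
  stopifnot(is_expression_table(tbl))
  df <- data.frame(gene_id = rownames(tbl$counts), tbl$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tbl$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}
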