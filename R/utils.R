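#' @importFrom methods is
#' @importFrom stats rpois rnbinom rlnorm runif rnorm ppois t.test cor
#'   quantile median setNames ave
#' @importFrom utils read.delim write.table head tail
#' @importFrom IRanges %over%
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, allow_zero = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= if (allow_zero) 0 else 1
}

## all package randomness goes through this so that a single integer seed
## determines every simulated object without touching the caller's RNG state
with_seed <- function(seed, code) {
  if (!is_count(seed)) stopf("`seed` must be a single non-negative number")
  withr::with_seed(as.integer(seed), code)
}

## derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483647L
}

#' Construct a set of genomic intervals
#'
#' Thin constructor building a [GenomicRanges::GRanges] from 1-based closed
#' coordinates, with chromosome lengths attached when supplied.  All
#' exported functions in this package accept and return `GRanges`; on disk
#' the package reads and writes BED (0-based half-open), with the
#' conversion handled by rtracklayer.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based closed interval bounds.
#' @param strand optional strand (`"+"`, `"-"`, `"*"`).
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @return A `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*",
                              chrom_sizes = NULL) {
  strand <- rep(strand, length.out = length(start))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- as.numeric(chrom_sizes)
  }
  gr
}

chrom_sizes_of <- function(x) {
  sl <- GenomeInfoDb::seqlengths(x)
  if (any(is.na(sl))) stopf("chromosome lengths are not set on this object")
  sl
}
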