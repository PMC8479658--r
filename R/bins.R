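#' Genome binning scheme
#'
#' A `genome_bins` object describes a fixed-width partition of a genome into
#' non-overlapping bins: ordered chromosome names, chromosome lengths, the bin
#' size in base pairs, and the mapping from (chromosome, start) to a dense
#' global bin ordinal.  Coordinates are 0-based half-open; every bin start is
#' a multiple of the bin size and the last bin of a chromosome may be short.
#'
#' @param chrom_names character vector of chromosome identifiers (order kept).
#' @param chrom_lengths integer vector of chromosome lengths in bp, parallel
#'   to `chrom_names`.
#' @param bin_size bin width in bp (> 0).
#' @return An object of class `genome_bins` with elements `chrom_names`,
#'   `chrom_lengths` (named), `bin_size`, `n_bins` (named, per chromosome),
#'   `offset` (named, 0-based global ordinal of each chromosome's first bin)
#'   and `total_bins`.
#' @examples
#' gb <- genome_bins(c("chr1", "chr2"), c(12000, 7000), 5000)
#' gb$n_bins       # chr1: 3 bins, chr2: 2 bins
#' @export
genome_bins <- function(chrom_names, chrom_lengths, bin_size) {
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) == 0L) stop("at least one chromosome required")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_lengths must be parallel to chrom_names")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop("bin_size must be > 0")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  names(chrom_lengths) <- chrom_names
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  names(n_bins) <- chrom_names
  offset <- c(0L, cumsum(n_bins))[seq_along(chrom_names)]
  names(offset) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         bin_size = bin_size, n_bins = n_bins, offset = offset,
         total_bins = sum(n_bins)),
    class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d chromosome(s), bin_size = %d bp, %d bins\n",
              length(x$chrom_names), x$bin_size, x$total_bins))
  invisible(x)
}

#' Per-bin coordinate table for one chromosome
#'
#' @param bins a `genome_bins` object.
#' @param chrom chromosome name.
#' @return data.frame with 0-based half-open `start`/`end` per bin, in bin
#'   order.
#' @keywords internal
bin_table <- function(bins, chrom) {
  n <- bins$n_bins[[chrom]]
  start <- (seq_len(n) - 1L) * bins$bin_size
  end <- pmin(start + bins$bin_size, bins$chrom_lengths[[chrom]])
  data.frame(start = start, end = end)
}

#' Locate the bin containing a genomic position
#'
#' @param bins a `genome_bins` object.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based positions.
#' @return 1-based bin index within each chromosome; `NA` for chromosomes not
#'   in the scheme or positions beyond the chromosome end.
#' @keywords internal
locate_bin <- function(bins, chrom, pos) {
  idx <- floor(pos / bins$bin_size) + 1L
  n <- bins$n_bins[chrom]
  idx[is.na(n) | idx < 1L | idx > n | pos < 0] <- NA_integer_
  as.integer(idx)
}

same_bins <- function(a, b) {
  isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    identical(a$chrom_names, b$chrom_names) &&
    isTRUE(all.equal(unname(a$chrom_lengths), unname(b$chrom_lengths)))
}
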