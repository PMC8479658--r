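#' Distance-decay normalization of a contact matrix
#'
#' Hi-C contact frequency decays strongly with genomic distance.  To compare
#' local interaction structure across samples, each count is divided by the
#' mean count over all intra-chromosomal bin pairs at the same distance on
#' the same chromosome, zeros included (a chromosome with `n` bins has
#' `n - d` pairs at distance `d` bins).  Distances whose mean is zero map to
#' zero.  The result is depth-invariant per chromosome: scaling all counts by
#' a constant leaves it unchanged.
#'
#' @param cm a [contact_matrix].
#' @param D_bins band half-width in bins; only pairs within this distance are
#'   normalized and retained.
#' @return An object of class `norm_band`: list with `chrom`, `n_bins`,
#'   `D_bins`, `band` (an `n_bins x (D_bins + 1)` matrix, column `d + 1`
#'   holding normalized values of pairs `(i, i + d)`, `NA` past the
#'   chromosome end) and `dist_means` (the raw per-distance means).
#' @export
normalize_by_distance <- function(cm, D_bins) {
  D_bins <- as.integer(D_bins)
  if (is.na(D_bins) || D_bins < 1L) stop("D_bins must be >= 1")
  n <- cm$n_bins
  if (D_bins > n - 1L)
    stop(sprintf("D_bins = %d exceeds the %d-bin span of chromosome %s",
                 D_bins, n, cm$chrom))
  band <- cm_band(cm, D_bins)
  n_pairs <- n - (0:D_bins)
  dist_means <- colSums(band, na.rm = TRUE) / n_pairs
  scale <- ifelse(dist_means > 0, dist_means, 1)   # zero-mean strata -> 0
  norm <- sweep(band, 2L, scale, "/")
  structure(list(chrom = cm$chrom, n_bins = n, D_bins = D_bins, band = norm,
                 dist_means = dist_means),
            class = "norm_band")
}

#' @export
print.norm_band <- function(x, ...) {
  cat(sprintf("norm_band: %s, %d bins, band half-width %d bins\n",
              x$chrom, x$n_bins, x$D_bins))
  invisible(x)
}

#' Contact score array of one bin
#'
#' The vector of distance-normalized interaction values between a bin and its
#' flanking bins at signed distances -D_bins..-1, +1..+D_bins, truncated at
#' chromosome ends.  The self-interaction (distance 0) is excluded by
#' default: the diagonal reflects self-ligation and coverage rather than
#' interaction with flanking regions.
#'
#' @param nm a `norm_band` from [normalize_by_distance].
#' @param bin 1-based bin index on the chromosome.
#' @param D_bins band half-width (defaults to the band's own).
#' @param include_diagonal also include the distance-0 value (default FALSE).
#' @return list with `values` and `positions` (the signed bin distances
#'   present, ascending), of class `contact_score_array`.
#' @export
extract_contact_score_array <- function(nm, bin, D_bins = nm$D_bins,
                                        include_diagonal = FALSE) {
  if (bin < 1L || bin > nm$n_bins) stop("bin out of range")
  if (D_bins > nm$D_bins) stop("D_bins exceeds the normalized band width")
  pos <- setdiff(seq.int(-D_bins, D_bins), if (include_diagonal) NULL else 0L)
  partner <- bin + pos
  keep <- partner >= 1L & partner <= nm$n_bins
  pos <- pos[keep]; partner <- partner[keep]
  i <- pmin(bin, partner); d <- abs(pos)
  structure(list(values = nm$band[cbind(i, d + 1L)], positions = pos),
            class = "contact_score_array")
}

# Full score-array matrix: one row per bin, columns at signed distances
# -D..-1, +1..+D (optionally 0); NA where the partner bin falls off the
# chromosome.  Row i is exactly extract_contact_score_array(nm, i)$values
# padded with NA at the truncated positions.
score_array_matrix <- function(nm, include_diagonal = FALSE) {
  n <- nm$n_bins; D <- nm$D_bins
  pos <- setdiff(seq.int(-D, D), if (include_diagonal) NULL else 0L)
  A <- matrix(NA_real_, n, length(pos))
  for (k in seq_along(pos)) {
    d <- abs(pos[k])
    v <- nm$band[seq_len(n - d), d + 1L]
    if (pos[k] > 0) A[seq_len(n - d), k] <- v else A[(d + 1L):n, k] <- v
  }
  colnames(A) <- pos
  A
}
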