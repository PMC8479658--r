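#' Sparse intra-chromosomal contact matrix
#'
#' Stores the raw Hi-C contact counts of one chromosome for one replicate as
#' canonical upper-triangle pixels (bin1 <= bin2, 1-based within the
#' chromosome).  Absent pixels are zero; the matrix is symmetric by contract.
#'
#' @param chrom chromosome identifier.
#' @param n_bins number of bins on the chromosome.
#' @param bin1,bin2 1-based bin indices of each pixel (any orientation;
#'   canonicalized on construction).
#' @param count non-negative contact counts.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, n_bins, bin1 = integer(), bin2 = integer(),
                           count = numeric()) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  bin1 <- as.integer(bin1); bin2 <- as.integer(bin2)
  count <- as.numeric(count)
  if (length(bin1) != length(bin2) || length(bin1) != length(count))
    stop("bin1, bin2, count must have equal length")
  if (length(bin1)) {
    if (any(bin1 < 1L | bin1 > n_bins | bin2 < 1L | bin2 > n_bins))
      stop("pixel bin index out of range for chromosome ", chrom)
    if (any(count < 0)) stop("negative contact count on chromosome ", chrom)
    i <- pmin(bin1, bin2); j <- pmax(bin1, bin2)
    px <- data.table::data.table(bin1 = i, bin2 = j, count = count)
    # symmetric duplicates (both (i,j) and (j,i) on input) must agree
    px <- px[, list(count = {
      u <- unique(count)
      if (length(u) > 1L)
        stop("conflicting duplicate pixels on chromosome ", chrom)
      u
    }), by = c("bin1", "bin2")]
    data.table::setorderv(px, c("bin1", "bin2"))
  } else {
    px <- data.table::data.table(bin1 = integer(), bin2 = integer(),
                                 count = numeric())
  }
  structure(list(chrom = as.character(chrom), n_bins = n_bins, pixels = px),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins, %d non-zero pixel(s)\n",
              x$chrom, x$n_bins, nrow(x$pixels)))
  invisible(x)
}

#' Densify a contact matrix (tests and small inputs only)
#'
#' @param cm a `contact_matrix`.
#' @return symmetric dense numeric matrix.
#' @export
cm_dense <- function(cm) {
  m <- matrix(0, cm$n_bins, cm$n_bins)
  px <- cm$pixels
  if (nrow(px)) {
    m[cbind(px$bin1, px$bin2)] <- px$count
    m[cbind(px$bin2, px$bin1)] <- px$count
  }
  m
}

#' Band view of a contact matrix
#'
#' Returns an `n_bins x (D_bins + 1)` matrix whose column `d + 1` holds the
#' counts of pairs `(i, i + d)` (rows beyond `n_bins - d` are `NA`: no such
#' pair exists).
#'
#' @param cm a `contact_matrix`.
#' @param D_bins band half-width in bins.
#' @return numeric matrix of raw counts along each diagonal.
#' @keywords internal
cm_band <- function(cm, D_bins) {
  n <- cm$n_bins
  band <- matrix(0, n, D_bins + 1L)
  for (d in seq_len(D_bins)) {
    if (d < n) band[(n - d + 1L):n, d + 1L] <- NA else band[, d + 1L] <- NA
  }
  px <- cm$pixels
  if (nrow(px)) {
    d <- px$bin2 - px$bin1
    keep <- d <= D_bins
    if (any(keep))
      band[cbind(px$bin1[keep], d[keep] + 1L)] <- px$count[keep]
  }
  band
}

#' Per-bin coverage within the tested band
#'
#' Row sums of raw counts over all partners within `D_bins` of each bin
#' (diagonal included) — the coverage covariate of the optional
#' regression-adjusted profile.
#'
#' @inheritParams cm_band
#' @return numeric vector of length `n_bins`.
#' @export
cm_coverage <- function(cm, D_bins) {
  n <- cm$n_bins
  cov <- numeric(n)
  px <- cm$pixels
  if (nrow(px)) {
    d <- px$bin2 - px$bin1
    keep <- d <= D_bins
    px <- px[keep, ]
    cov <- cov + tabulate_sum(px$bin1, px$count, n)
    off <- px$bin1 != px$bin2
    cov <- cov + tabulate_sum(px$bin2[off], px$count[off], n)
  }
  cov
}

tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' One condition's replicates of per-chromosome contact maps
#'
#' @param condition `"treatment"` or `"control"`.
#' @param replicates list of replicates; each replicate is a named list of
#'   `contact_matrix` objects keyed by chromosome.
#' @param bins the shared `genome_bins`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(condition, replicates, bins) {
  condition <- match.arg(condition, c("treatment", "control"))
  if (!length(replicates)) stop("zero replicates in ", condition, " set")
  for (rep in replicates) {
    if (!setequal(names(rep), bins$chrom_names))
      stop("replicate chromosomes do not match the binning scheme")
    for (chrom in bins$chrom_names) {
      cm <- rep[[chrom]]
      if (!inherits(cm, "contact_matrix") || cm$n_bins != bins$n_bins[[chrom]])
        stop("replicate matrix on ", chrom, " inconsistent with bins")
    }
  }
  structure(list(condition = condition, replicates = replicates, bins = bins),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %s, %d replicate(s), %d chromosome(s) at %d bp\n",
              x$condition, length(x$replicates), length(x$bins$chrom_names),
              x$bins$bin_size))
  invisible(x)
}

#' Check two conditions share one binning scheme
#'
#' Asserts that every replicate of both conditions uses the same bin size and
#' the same chromosome set and lengths; chromosomes present in only one
#' condition are a hard error, never silently intersected.
#'
#' @param treatment,control `sample_set` objects.
#' @return the common `genome_bins`.
#' @export
validate_sample_sets <- function(treatment, control) {
  if (!inherits(treatment, "sample_set") || !inherits(control, "sample_set"))
    stop("both arguments must be sample_set objects")
  if (!length(treatment$replicates) || !length(control$replicates))
    stop("zero replicates")
  a <- treatment$bins; b <- control$bins
  if (a$bin_size != b$bin_size)
    stop(sprintf("bin size mismatch: treatment %d bp vs control %d bp",
                 a$bin_size, b$bin_size))
  only_a <- setdiff(a$chrom_names, b$chrom_names)
  only_b <- setdiff(b$chrom_names, a$chrom_names)
  if (length(only_a) || length(only_b))
    stop("chromosome set mismatch: missing from control: ",
         paste(only_a, collapse = ","), "; missing from treatment: ",
         paste(only_b, collapse = ","))
  if (!isTRUE(all.equal(a$chrom_lengths[a$chrom_names],
                        b$chrom_lengths[a$chrom_names])))
    stop("chromosome length mismatch between conditions")
  a
}
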