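# fixture builders shared across test files

cm_from_dense <- function(m, chrom = "chr1") {
  stopifnot(isSymmetric(unname(m)))
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_matrix(chrom, nrow(m), idx[, 1], idx[, 2], m[idx])
}

# random symmetric non-negative integer count matrix
random_counts <- function(n, lambda = 5) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  v <- rpois(nrow(up), lambda)
  m[up] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

score_array <- function(values, positions = NULL) {
  if (is.null(positions)) {
    k <- length(values) / 2
    positions <- setdiff(seq.int(-k, k), 0L)
  }
  structure(list(values = values, positions = positions),
            class = "contact_score_array")
}

# one-replicate-per-condition sample sets from dense per-chromosome matrices
ss_from_dense <- function(mats, condition, bin_size = 5000L) {
  n_bins <- vapply(mats, nrow, 0L)
  bins <- genome_bins(names(mats), n_bins * bin_size, bin_size)
  reps <- list(mapply(cm_from_dense, mats, names(mats), SIMPLIFY = FALSE))
  sample_set(condition, reps, bins)
}

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(bins_per_chrom = 120L, n_cres = 400L, n_trs = 10L,
                   base_depth = 80, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
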