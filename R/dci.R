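# Differential chromatin interaction (DCI) scoring.
#
# Per bin, each control replicate's contact score array is compared with each
# treatment replicate's by a paired t-test on the per-position differences;
# the m x n p-values are combined with Fisher's method and the sign taken
# from the majority (sum) of the t statistics.  S = sign * (-log10 p).

# p-values are clamped here before any log so scores stay finite
P_FLOOR <- 1e-300

# surrogate magnitude for infinite t statistics when summing for the sign
T_CLAMP <- 1e6

#' Paired t-test between two contact score arrays
#'
#' Classical paired t on the differences `b - a` (treatment minus control)
#' with `L - 1` degrees of freedom and a two-sided p-value.  Degenerate
#' cases: identical arrays give `(t = 0, p = 1)`; a nonzero constant shift
#' has zero variance and returns `t = +/-Inf` with the p-value floor.
#'
#' @param a,b `contact_score_array` objects (control, treatment) with
#'   identical positions.
#' @return list with elements `t` and `p`.
#' @export
paired_t <- function(a, b) {
  if (!identical(a$positions, b$positions))
    stop("contact score arrays have mismatched positions")
  L <- length(a$values)
  if (L < 2L) stop("paired t-test undefined for fewer than 2 positions")
  d <- b$values - a$values
  m <- mean(d)
  v <- sum((d - m)^2) / (L - 1L)
  if (v == 0) {
    if (m == 0) return(list(t = 0, p = 1))
    return(list(t = sign(m) * Inf, p = P_FLOOR))
  }
  t <- m / sqrt(v / L)
  list(t = t, p = 2 * stats::pt(-abs(t), df = L - 1L))
}

#' Fisher's combined probability test
#'
#' Combines k p-values via `chi2 = -2 sum(log p)` referred to the upper tail
#' of the chi-square distribution with 2k degrees of freedom.  Inputs are
#' clamped to the floor `1e-300` first; with a single p-value the method is
#' the identity.
#'
#' @param ps numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisher_combine <- function(ps) {
  if (!length(ps)) stop("fisher_combine requires at least one p-value")
  if (any(ps > 1 | ps < 0)) stop("p-values must lie in [0, 1]")
  ps <- pmax(ps, P_FLOOR)
  chi2 <- -2 * sum(log(ps))
  stats::pchisq(chi2, df = 2 * length(ps), lower.tail = FALSE)
}

#' DCI score of one bin from replicate score arrays
#'
#' Runs [paired_t] for every (control, treatment) replicate pair (m x n
#' tests), combines the p-values with [fisher_combine], and signs the score
#' by the sum of the t statistics (the majority direction, with magnitude as
#' the tie-break).  `S = sign * (-log10 p)`, with p floored at `1e-300`.
#'
#' @param controls,treatments lists of `contact_score_array` objects sharing
#'   positions.
#' @return list with `S`, `p` and `sign`.
#' @export
dci_score <- function(controls, treatments) {
  if (!length(controls) || !length(treatments))
    stop("at least one replicate per condition required")
  tests <- list()
  for (a in controls) for (b in treatments) tests <- c(tests, list(paired_t(a, b)))
  ps <- vapply(tests, `[[`, 0, "p")
  ts <- vapply(tests, `[[`, 0, "t")
  p <- max(fisher_combine(ps), P_FLOOR)
  sgn <- sign(sum(pmin(pmax(ts, -T_CLAMP), T_CLAMP)))
  list(S = sgn * -log10(p), p = p, sign = sgn)
}

# Vectorized paired t across the rows of a difference matrix (NA = position
# truncated at a chromosome end; the NA pattern is identical across
# replicates by geometry).  Returns per-row t (clamped for summation), raw t
# sign via t itself, and two-sided p.
row_paired_t <- function(diff, L) {
  m <- rowMeans(diff, na.rm = TRUE)
  ss <- rowSums(diff * diff, na.rm = TRUE)
  v <- pmax(ss - L * m^2, 0) / pmax(L - 1L, 1L)
  t <- numeric(length(m)); p <- rep(1, length(m))
  ok <- L >= 2L
  zerovar <- ok & v == 0
  t[zerovar & m != 0] <- sign(m[zerovar & m != 0]) * T_CLAMP
  p[zerovar & m != 0] <- P_FLOOR
  pos <- ok & v > 0
  t[pos] <- m[pos] / sqrt(v[pos] / L[pos])
  p[pos] <- 2 * stats::pt(-abs(t[pos]), df = L[pos] - 1L)
  t[!ok] <- NA_real_; p[!ok] <- NA_real_
  list(t = t, p = p)
}

#' Genome-wide DCI profile
#'
#' Scans every chromosome: normalizes each replicate's contact matrix for
#' distance decay, extracts each bin's contact score array over the flanking
#' `+/-D` window, and computes the signed DCI score per bin.  Bins whose
#' arrays are all-zero in every replicate of both conditions are flagged
#' `no_data` and given `S = 0` (unmappable regions must not fabricate
#' signal).
#'
#' @param treatment,control [sample_set] objects (validated against each
#'   other).
#' @param D flanking distance bound in bp; must be a positive multiple of
#'   the bin size (default 200000).
#' @param include_diagonal include the self-interaction in the score arrays
#'   (default FALSE).
#' @return An object of class `dci_profile`: a data.frame with one row per
#'   bin (`chrom`, `start`, `end`, `score`, `p`, `sign`, `n_tests`,
#'   `no_data`), with the `genome_bins` and parameters as attributes.
#' @export
compute_dci_profile <- function(treatment, control, D = 200000L,
                                include_diagonal = FALSE) {
  bins <- validate_sample_sets(treatment, control)
  D <- as.numeric(D)
  if (D <= 0 || D %% bins$bin_size != 0)
    stop("genomic distance D must be a positive multiple of the bin size")
  D_bins <- as.integer(D / bins$bin_size)
  n_ctrl <- length(control$replicates)
  n_trt <- length(treatment$replicates)
  k <- n_ctrl * n_trt

  per_chrom <- lapply(bins$chrom_names, function(chrom) {
    arr <- function(ss) lapply(ss$replicates, function(rep)
      score_array_matrix(normalize_by_distance(rep[[chrom]], D_bins),
                         include_diagonal = include_diagonal))
    A_c <- arr(control); A_t <- arr(treatment)
    n <- bins$n_bins[[chrom]]
    L <- rowSums(!is.na(A_c[[1]]))
    no_data <- Reduce(`&`, lapply(c(A_c, A_t), function(A)
      rowSums(A != 0, na.rm = TRUE) == 0L))
    chi_terms <- matrix(0, n, k); t_terms <- matrix(0, n, k)
    idx <- 0L
    for (ac in A_c) for (at in A_t) {
      idx <- idx + 1L
      res <- row_paired_t(at - ac, L)
      chi_terms[, idx] <- -2 * log(pmax(res$p, P_FLOOR))
      t_terms[, idx] <- pmin(pmax(res$t, -T_CLAMP), T_CLAMP)
    }
    # sum per-pair terms in a canonical order so that swapping the two
    # conditions negates every score and preserves every p bit-for-bit
    if (k > 1L) {
      chi2 <- rowSums(t(apply(chi_terms, 1L, sort, na.last = TRUE)))
      tsum <- rowSums(t(apply(t_terms, 1L, function(v) v[order(abs(v))])))
    } else {
      chi2 <- chi_terms[, 1L]
      tsum <- t_terms[, 1L]
    }
    p <- pmax(stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE), P_FLOOR)
    sgn <- sign(tsum)
    undef <- L < 2L | is.na(tsum)
    no_data <- no_data | undef
    p[no_data] <- 1; sgn[no_data] <- 0
    tab <- bin_table(bins, chrom)
    data.frame(chrom = chrom, start = tab$start, end = tab$end,
               score = sgn * -log10(p), p = p, sign = as.integer(sgn),
               n_tests = k, no_data = no_data)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  structure(out, bins = bins, D = D, class = c("dci_profile", "data.frame"))
}

#' Per-bin band coverage of a sample set
#'
#' @param ss a [sample_set].
#' @param D distance bound in bp.
#' @return matrix (total bins x replicates) of raw within-band row sums.
#' @export
compute_coverage <- function(ss, D = 200000L) {
  bins <- ss$bins
  D_bins <- as.integer(D / bins$bin_size)
  vapply(ss$replicates, function(rep)
    unlist(lapply(bins$chrom_names, function(chrom)
      cm_coverage(rep[[chrom]], D_bins)), use.names = FALSE),
    numeric(bins$total_bins))
}

#' Coverage-adjusted DCI profile
#'
#' Read-coverage changes between conditions can confound the DCI signal.
#' The adjustment regresses the per-bin score on the log2 coverage ratio
#' `x = log2((mean treatment coverage + 1) / (mean control coverage + 1))`
#' by ordinary least squares over scored bins and replaces each score with
#' its residual; `no_data` bins are untouched.
#'
#' @param profile a `dci_profile`.
#' @param treatment_cov,control_cov coverage matrices from
#'   [compute_coverage] (bins x replicates).
#' @return the profile with `score` replaced by residuals and a
#'   `coverage_covariate` column added.
#' @export
adjust_for_coverage <- function(profile, treatment_cov, control_cov) {
  treatment_cov <- as.matrix(treatment_cov)
  control_cov <- as.matrix(control_cov)
  if (nrow(treatment_cov) != nrow(profile) ||
      nrow(control_cov) != nrow(profile))
    stop("coverage vectors are not aligned to the profile bins")
  x <- log2((rowMeans(treatment_cov) + 1) / (rowMeans(control_cov) + 1))
  scored <- !profile$no_data
  if (sum(scored) < 3L)
    stop("coverage adjustment requires at least 3 scored bins")
  out <- profile
  out$coverage_covariate <- x
  if (stats::var(x[scored]) == 0) {
    warning("coverage covariate is constant; profile returned unadjusted")
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, x[scored]), profile$score[scored])
  out$score[scored] <- fit$residuals
  attr(out, "coverage_adjusted") <- TRUE
  out
}

#' Compare DCI scores of bins with and without binding sites
#'
#' Partitions scored bins by overlap with a set of genomic regions (for
#' example, ChIP-seq peaks of a perturbed factor) and applies a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie and continuity
#' correction) to the two score samples.
#'
#' @param profile a `dci_profile`.
#' @param sites data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return list with `W` (rank-sum statistic of the bound group) and `p`.
#' @export
bound_vs_unbound_test <- function(profile, sites) {
  sites <- as.data.frame(sites)
  scored <- !profile$no_data
  bound <- rep(FALSE, nrow(profile))
  for (chrom in unique(sites$chrom)) {
    rows <- which(profile$chrom == chrom)
    if (!length(rows)) next
    s <- sites[sites$chrom == chrom, ]
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(profile$start[rows] + 1L, profile$end[rows]),
      IRanges::IRanges(s$start + 1L, s$end))
    bound[rows] <- hits
  }
  g1 <- profile$score[scored & bound]
  g0 <- profile$score[scored & !bound]
  if (!length(g1) || !length(g0))
    stop("both bound and unbound scored bins are required")
  wt <- stats::wilcox.test(g1, g0, exact = FALSE, correct = TRUE)
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Write a DCI profile as bedGraph
#'
#' @param profile a `dci_profile`.
#' @param path output path.
#' @param track_name track line name (omit the track line with `NULL`).
#' @return invisibly, `path`.
#' @export
write_dci_bedgraph <- function(profile, path, track_name = "DCI") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", profile$chrom, profile$start,
                     profile$end, profile$score), con)
  invisible(path)
}

#' Write the per-bin DCI table as TSV
#'
#' @inheritParams write_dci_bedgraph
#' @return invisibly, `path`.
#' @export
write_dci_table <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
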