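# paired t / Fisher kernels, DCI scoring and profile-level behavior

test_that("paired_t handles identity, degenerate shift and the textbook case", {
  a <- score_array(c(1, 2, 3, 4))
  expect_equal(paired_t(a, a), list(t = 0, p = 1))

  shift <- paired_t(score_array(c(1, 1, 1, 1)), score_array(c(2, 2, 2, 2)))
  expect_true(is.infinite(shift$t) && shift$t > 0)
  expect_equal(shift$p, 1e-300)

  x <- score_array(c(1.0, 2.0, 3.0), c(-1L, 1L, 2L))
  y <- score_array(c(1.5, 2.0, 3.1), c(-1L, 1L, 2L))
  got <- paired_t(x, y)
  want <- oracle_paired_t(x$values, y$values)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(sd(y$values - x$values), 0.2645751, tolerance = 1e-6)

  expect_error(paired_t(x, score_array(c(1, 2, 3), c(1L, 2L, 3L))),
               "mismatched positions")
  expect_error(paired_t(score_array(1, 1L), score_array(2, 1L)), "fewer than 2")
})

test_that("fisher_combine matches the even-df closed form", {
  expect_equal(fisher_combine(c(0.5, 0.5)), oracle_fisher(c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_equal(fisher_combine(1), 1)
  for (p in c(0.01, 0.3, 0.77))   # k = 1 is the identity
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  expect_error(fisher_combine(numeric()), "at least one")
  expect_equal(fisher_combine(c(0, 0.5)),
               oracle_fisher(c(1e-300, 0.5)), tolerance = 1e-12)
})

test_that("dci_score agrees with the composed brute-force oracle", {
  expect_equal(dci_score(list(score_array(c(1, 2, 3, 4))),
                         list(score_array(c(1, 2, 3, 4)))),
               list(S = 0, p = 1, sign = 0))

  up <- dci_score(list(score_array(c(1, 2, 3, 4))),
                  list(score_array(c(1.5, 2.2, 3.4, 4.1))))
  expect_equal(up$sign, 1)
  expect_gt(up$S, 0)

  set.seed(31)
  ctrl <- list(score_array(runif(8)), score_array(runif(8)))
  trt <- list(score_array(runif(8) + 0.2), score_array(runif(8) + 0.2))
  got <- dci_score(ctrl, trt)
  want <- oracle_dci(lapply(ctrl, `[[`, "values"),
                     lapply(trt, `[[`, "values"))
  expect_equal(got$S, want$S, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_identical(got$sign, want$sign)
})

test_that("profile scores match per-bin dci_score recomputation", {
  cfg <- small_cfg(bins_per_chrom = 60L, n_replicates = 2L)
  trt <- simulate_contact_maps(cfg, "treatment")
  ctl <- simulate_contact_maps(cfg, "control")
  D_bins <- 8L
  prof <- compute_dci_profile(trt, ctl, D = D_bins * cfg$bin_size)
  rows <- which(prof$chrom == "chr2")
  nb_c <- lapply(ctl$replicates, function(r)
    normalize_by_distance(r$chr2, D_bins))
  nb_t <- lapply(trt$replicates, function(r)
    normalize_by_distance(r$chr2, D_bins))
  for (bin in c(1L, 5L, 30L, 60L)) {
    want <- dci_score(lapply(nb_c, extract_contact_score_array, bin = bin),
                      lapply(nb_t, extract_contact_score_array, bin = bin))
    expect_equal(prof$score[rows[bin]], want$S, tolerance = 1e-10)
    expect_equal(prof$p[rows[bin]], want$p, tolerance = 1e-10)
  }
})

test_that("swapping conditions negates scores and preserves p-values", {
  cfg <- small_cfg(bins_per_chrom = 50L)
  trt <- simulate_contact_maps(cfg, "treatment")
  ctl <- simulate_contact_maps(cfg, "control")
  fwd <- compute_dci_profile(trt, ctl, D = 50000)
  rev <- compute_dci_profile(ctl, trt, D = 50000)
  expect_identical(fwd$score, -rev$score)
  expect_identical(fwd$p, rev$p)
})

test_that("implanted gained blocks carry the top scores", {
  cfg <- small_cfg(bins_per_chrom = 200L, base_depth = 100,
                   blocks = data.frame(chrom = "chr1", first_bin = 80L,
                                       last_bin = 110L, fold_change = 3))
  prof <- compute_dci_profile(simulate_contact_maps(cfg, "treatment"),
                              simulate_contact_maps(cfg, "control"),
                              D = 200000)
  inblk <- prof$chrom == "chr1" &
    prof$start >= 79 * 5000 & prof$end <= 110 * 5000
  expect_gt(mean(prof$score[inblk]),
            quantile(prof$score[!inblk], 0.95))
})

test_that("configuration and no-data degeneracies are handled", {
  cfg <- small_cfg(bins_per_chrom = 30L)
  trt <- simulate_contact_maps(cfg, "treatment")
  ctl <- simulate_contact_maps(cfg, "control")
  expect_error(compute_dci_profile(trt, ctl, D = 7777), "multiple")

  # zero out a stretch of both conditions on chr1 -> no-data bins
  blank <- function(ss, lo, hi) {
    ss$replicates <- lapply(ss$replicates, function(r) {
      px <- r$chr1$pixels
      keep <- !(px$bin1 >= lo & px$bin1 <= hi) & !(px$bin2 >= lo & px$bin2 <= hi)
      r$chr1 <- contact_matrix("chr1", r$chr1$n_bins, px$bin1[keep],
                               px$bin2[keep], px$count[keep])
      r
    })
    ss
  }
  prof <- compute_dci_profile(blank(trt, 10, 14), blank(ctl, 10, 14),
                              D = 2 * 5000)
  mid <- which(prof$chrom == "chr1")[12]
  expect_true(prof$no_data[mid])
  expect_identical(prof$score[mid], 0)
  expect_identical(prof$sign[mid], 0L)
})

test_that("coverage adjustment matches closed-form simple regression", {
  cfg <- small_cfg(bins_per_chrom = 40L)
  trt <- simulate_contact_maps(cfg, "treatment")
  ctl <- simulate_contact_maps(cfg, "control")
  prof <- compute_dci_profile(trt, ctl, D = 50000)
  tc <- compute_coverage(trt, 50000); cc <- compute_coverage(ctl, 50000)
  adj <- adjust_for_coverage(prof, tc, cc)
  x <- log2((rowMeans(tc) + 1) / (rowMeans(cc) + 1))
  s <- prof$score
  beta <- cov(s, x) / var(x)
  alpha <- mean(s) - beta * mean(x)
  expect_equal(adj$score, s - alpha - beta * x, tolerance = 1e-10)

  # identical coverage -> constant covariate -> unchanged with a warning
  expect_warning(same <- adjust_for_coverage(prof, tc, tc), "constant")
  expect_equal(same$score, prof$score)

  # scores perfectly linear in the covariate -> residuals all zero
  lin <- prof; lin$score <- 2 + 3 * x
  expect_equal(adjust_for_coverage(lin, tc, cc)$score,
               rep(0, nrow(prof)), tolerance = 1e-10)
})

test_that("bound vs unbound comparison uses the tie-corrected rank-sum", {
  cfg <- small_cfg(bins_per_chrom = 200L, base_depth = 100,
                   blocks = data.frame(chrom = "chr1", first_bin = 80L,
                                       last_bin = 110L, fold_change = 3))
  prof <- compute_dci_profile(simulate_contact_maps(cfg, "treatment"),
                              simulate_contact_maps(cfg, "control"),
                              D = 200000)
  sites <- data.frame(chrom = "chr1",
                      start = seq(80L, 109L) * 5000L + 100L,
                      end = seq(80L, 109L) * 5000L + 400L)
  res <- bound_vs_unbound_test(prof, sites)
  expect_lt(res$p, 1e-4)          # gained-block sites score higher

  # complete separation at n = 3 vs 3: U = 0 and exact enumeration p = 0.1
  toy <- prof[1:6, ]
  toy$score <- c(1, 2, 3, 10, 20, 30)
  toy$no_data <- FALSE
  toy_sites <- data.frame(chrom = toy$chrom[1:3], start = toy$start[1:3],
                          end = toy$end[1:3])
  got <- bound_vs_unbound_test(toy, toy_sites)
  expect_equal(got$W, 0)
  expect_equal(oracle_ranksum_exact(c(1, 2, 3), c(10, 20, 30), "two.sided"),
               0.1)

  # identical multisets: the tie-corrected statistic gives p = 1
  toy$score <- rep(c(4, 5, 6), 2)
  expect_equal(bound_vs_unbound_test(toy, toy_sites)$p, 1)
  expect_error(bound_vs_unbound_test(toy, data.frame(chrom = "chrZ",
                                                     start = 0, end = 10)),
               "bound and unbound")
})
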