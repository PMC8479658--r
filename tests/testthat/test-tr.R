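# AUROC, rank-aggregation statistics and the TR ranking table

ranked_from <- function(scores) {
  n <- length(scores)
  prof <- structure(data.frame(cre_id = seq_len(n) - 1L, chrom = "chr1",
                               start = 1, end = 2, score = scores,
                               scored = TRUE),
                    class = c("cre_profile", "cre_catalog", "data.frame"))
  ranked_cres(prof)
}

test_that("auroc matches trivial and hand-counted cases", {
  r <- ranked_from(c(5, 4, 3, 2, 1))
  expect_equal(auroc(r, c(0L, 1L)), 1)             # all bound on top
  expect_equal(auroc(ranked_from(rep(2, 6)), c(0L, 3L)), 0.5)  # all ties
  expect_equal(auroc(r, c(0L, 2L)), 5 / 6)         # binding (1,0,1,0,0)
  expect_true(is.na(auroc(r, 0:4)))                # degenerate: all bound
})

test_that("auroc equals exhaustive pair counting on random instances", {
  set.seed(123)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    scores <- sample(round(rnorm(n), 2))           # duplicates create ties
    bound <- sample(n, sample(seq_len(n - 1), 1)) - 1L
    got <- auroc(ranked_from(scores), bound)
    want <- oracle_auroc(scores, (seq_len(n) - 1L) %in% bound)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("TR-vs-rest Wilcoxon behaves at the null and under separation", {
  # clearly superior TR: approximation agrees with exact enumeration
  tr <- c(0.9, 0.85, 0.8); rest <- seq(0.3, 0.6, length.out = 30)
  got <- wilcoxon_tr_vs_rest(tr, rest)
  expect_lt(got$p, 0.01)
  expect_lt(abs(got$p - oracle_ranksum_exact(tr, rest, "greater")), 0.05)

  # symmetric null: statistic at its mean, p about one half
  sym <- wilcoxon_tr_vs_rest(c(0.4, 0.6), c(0.3, 0.5, 0.5, 0.7))
  expect_equal(sym$stat, 2 * 4 / 2)
  expect_gt(sym$p, 0.35); expect_lt(sym$p, 0.7)

  # a single dataset sitting at the median of the rest
  med <- wilcoxon_tr_vs_rest(0.5, c(0.3, 0.4, 0.6, 0.7))
  expect_gt(med$p, 0.35); expect_lt(med$p, 0.7)
  expect_error(wilcoxon_tr_vs_rest(0.5, 0.6), "too few")
})

test_that("the z-score is a standardized mean with translation invariance", {
  expect_equal(zscore_tr(0.6, c(0.4, 0.5, 0.6)), 1)
  expect_equal(zscore_tr(c(0.4, 0.6), c(0.4, 0.5, 0.6)), 0)
  expect_equal(zscore_tr(c(0.4, 0.6) + 0.2, c(0.4, 0.5, 0.6) + 0.2),
               zscore_tr(c(0.4, 0.6), c(0.4, 0.5, 0.6)))
  expect_error(zscore_tr(0.5, rep(0.5, 4)), "zero variance")
})

test_that("irwin_hall_p matches closed forms and Monte-Carlo", {
  expect_equal(irwin_hall_p(0.3, 1), 0.3)
  expect_equal(irwin_hall_p(1, 2), 0.5)
  expect_equal(irwin_hall_p(0.5, 3), 0.5^3 / 6, tolerance = 1e-12)
  expect_equal(irwin_hall_p(0.5, 3), 0.0208333, tolerance = 1e-5)
  expect_equal(irwin_hall_p(c(0, 3), 3), c(0, 1))
  expect_error(irwin_hall_p(3.2, 3), "outside")
  set.seed(17)
  for (s in c(0.5, 1.5, 2.5)) {
    mc <- oracle_irwin_hall_mc(s, 3, n = 2e5)
    expect_lt(abs(irwin_hall_p(s, 3) - mc$p), 3 * mc$se)
  }
})

# compendium where TR quality decreases with index: TR1 binds the top CREs,
# later TRs bind progressively lower-ranked ones
stairstep_fixture <- function(n_trs = 5, n_cres = 100) {
  prof <- structure(data.frame(cre_id = seq_len(n_cres) - 1L, chrom = "chr1",
                               start = 1, end = 2,
                               score = rev(seq_len(n_cres)), scored = TRUE),
                    class = c("cre_profile", "cre_catalog", "data.frame"))
  ds <- data.frame(dataset_id = paste0("d", seq_len(n_trs)),
                   tr_name = paste0("TR", seq_len(n_trs)))
  binding <- lapply(seq_len(n_trs), function(k)
    (k - 1L) * 10L + 0:9)                       # ten CREs per TR, descending
  names(binding) <- ds$dataset_id
  list(profile = prof, comp = binding_compendium(ds, binding, n_cres))
}

test_that("a TR best on all three statistics gets rank-sum 3/N", {
  fx <- stairstep_fixture(n_trs = 5)
  tab <- rank_trs(fx$profile, fx$comp, "increase")
  expect_identical(tab$tr_name[1], "TR1")
  expect_equal(tab$rank_sum[1], 3 / 5)
  expect_equal(tab$irwin_hall_p[1], (3 / 5)^3 / 6, tolerance = 1e-12)
  expect_identical(tab$rank, 1:5)
  expect_true(all(diff(tab$irwin_hall_p) >= 0))
})

test_that("decrease-direction ranking equals increase on the flipped profile", {
  cfg <- small_cfg()
  ex <- simulate_experiment(cfg)
  prof <- compute_dci_profile(ex$treatment, ex$control, D = 200000)
  cp <- suppressMessages(map_profile_to_cres(prof, ex$catalog))
  dec <- rank_trs(cp, ex$compendium, "decrease")
  inc_flip <- rank_trs(flip(cp), ex$compendium, "increase")
  attr(dec, "direction") <- NULL
  attr(inc_flip, "direction") <- NULL
  expect_identical(dec, inc_flip)
})

test_that("ranking is deterministic and validates its inputs", {
  fx <- stairstep_fixture()
  t1 <- rank_trs(fx$profile, fx$comp, "increase")
  t2 <- rank_trs(fx$profile, fx$comp, "increase")
  expect_identical(t1, t2)

  # degenerate dataset (binds everything) is skipped with a warning
  ds <- data.frame(dataset_id = c("a1", "a2", "b", "c"),
                   tr_name = c("TRa", "TRa", "TRb", "TRb"))
  binding <- list(a1 = 0:9, a2 = 3:12, b = 0:99, c = 5:14)
  comp <- binding_compendium(ds, binding, 100)
  expect_warning(tab <- rank_trs(fx$profile, comp, "increase"), "degenerate")
  expect_identical(sort(tab$tr_name), c("TRa", "TRb"))
  expect_identical(tab$n_datasets[tab$tr_name == "TRb"], 1L)
  expect_error(binding_compendium(data.frame(dataset_id = "a",
                                             tr_name = "only"),
                                  list(a = 1:3), 100),
               "at least 2 distinct TRs")
})

test_that("the compendium survives its TSV round-trip", {
  d <- withr::local_tempdir()
  fx <- stairstep_fixture()
  paths <- write_compendium(fx$comp, file.path(d, "ds.tsv"),
                            file.path(d, "bind.tsv"))
  back <- read_compendium(paths[1], paths[2], fx$comp$n_cres)
  expect_identical(back$datasets, fx$comp$datasets)
  expect_identical(back$binding, fx$comp$binding)
})
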