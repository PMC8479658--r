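# Transcriptional regulator (TR) inference against a binding compendium.
#
# Every ChIP-seq dataset in the compendium is scored by the AUROC of its
# bound CREs against the score-ranked CRE list; per TR the dataset AUCs are
# aggregated into three statistics (one-sided Wilcoxon versus all other
# datasets, a standardized mean AUC, and the maximum AUC), each converted to
# a rank quantile; the sum of the three quantiles is referred to the
# Irwin-Hall distribution with k = 3 for the final p-value.

#' Binding compendium over a CRE catalog
#'
#' @param datasets data.frame with columns `dataset_id` and `tr_name`.
#' @param binding named list (by `dataset_id`) of integer vectors of bound
#'   CRE ordinals (0-based).
#' @param n_cres size of the CRE catalog the ordinals refer to.
#' @return An object of class `binding_compendium`.
#' @export
binding_compendium <- function(datasets, binding, n_cres) {
  datasets <- data.frame(dataset_id = as.character(datasets$dataset_id),
                         tr_name = as.character(datasets$tr_name))
  if (anyDuplicated(datasets$dataset_id)) stop("duplicated dataset IDs")
  if (length(unique(datasets$tr_name)) < 2L)
    stop("a compendium needs at least 2 distinct TRs")
  missing <- setdiff(datasets$dataset_id, names(binding))
  if (length(missing))
    stop("no binding vector for dataset(s): ",
         paste(utils::head(missing, 5), collapse = ","))
  binding <- lapply(binding[datasets$dataset_id], function(b) {
    b <- sort(unique(as.integer(b)))
    if (length(b) && (b[1] < 0L || b[length(b)] >= n_cres))
      stop("bound CRE ordinal outside the catalog")
    b
  })
  structure(list(datasets = datasets, binding = binding,
                 n_cres = as.integer(n_cres)),
            class = "binding_compendium")
}

#' @export
print.binding_compendium <- function(x, ...) {
  cat(sprintf("binding_compendium: %d dataset(s), %d TR(s), %d CREs\n",
              nrow(x$datasets), length(unique(x$datasets$tr_name)), x$n_cres))
  invisible(x)
}

#' Read a binding compendium from its TSV sidecar pair
#'
#' @param dataset_path TSV with header `dataset_id`, `tr_name`.
#' @param binding_path sparse triplet TSV with header `dataset_id`,
#'   `cre_id` (0-based CRE ordinals), one row per bound element.
#' @param n_cres catalog size.
#' @return a [binding_compendium].
#' @export
read_compendium <- function(dataset_path, binding_path, n_cres) {
  for (p in c(dataset_path, binding_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ds <- data.table::fread(dataset_path, header = TRUE)
  tr <- data.table::fread(binding_path, header = TRUE)
  binding <- split(as.integer(tr$cre_id), as.character(tr$dataset_id))
  for (id in setdiff(ds$dataset_id, names(binding)))
    binding[[id]] <- integer()
  binding_compendium(as.data.frame(ds), binding, n_cres)
}

#' Write a binding compendium as its TSV sidecar pair
#'
#' @param compendium a [binding_compendium].
#' @param dataset_path,binding_path output paths (see [read_compendium]).
#' @return invisibly, the two paths.
#' @export
write_compendium <- function(compendium, dataset_path, binding_path) {
  data.table::fwrite(compendium$datasets, dataset_path, sep = "\t")
  trips <- data.table::rbindlist(lapply(compendium$datasets$dataset_id,
    function(id) data.table::data.table(dataset_id = id,
                                        cre_id = compendium$binding[[id]])))
  data.table::fwrite(trips, binding_path, sep = "\t")
  invisible(c(dataset_path, binding_path))
}

#' Rank the scored CREs of a profile
#'
#' Scored CREs sorted by descending score, ties broken by ordinal for
#' determinism.
#'
#' @param profile a `cre_profile`.
#' @return An object of class `ranked_cres`: list with `cre_id` (ordinals in
#'   rank order) and `score` (their scores, same order).
#' @export
ranked_cres <- function(profile) {
  keep <- which(profile$scored)
  if (!length(keep)) stop("profile has no scored CREs")
  ord <- keep[order(-profile$score[keep], profile$cre_id[keep])]
  structure(list(cre_id = profile$cre_id[ord], score = profile$score[ord]),
            class = "ranked_cres")
}

#' AUROC of a binding vector against a ranked CRE list
#'
#' Mann-Whitney formulation with midranks for ties:
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank-sum of
#' the bound CREs under ascending score ranks.  An AUC above 0.5 means the
#' dataset's bound CREs concentrate at high profile scores.
#'
#' @param ranked a [ranked_cres] list.
#' @param bound integer vector of bound CRE ordinals (0-based).
#' @return the AUC, or `NA` when all or none of the scored CREs are bound.
#' @export
auroc <- function(ranked, bound) {
  is_bound <- ranked$cre_id %in% bound
  n1 <- sum(is_bound); n0 <- length(is_bound) - n1
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(ranked$score)                      # ascending, midranks for ties
  (sum(r[is_bound]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-sided Wilcoxon: a TR's AUCs versus all other datasets' AUCs
#'
#' Alternative: the TR's AUCs are larger.  The exact rank-sum distribution
#' is used for small tie-free samples (both groups under 50); otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param tr_aucs,other_aucs numeric vectors of dataset AUCs.
#' @return list with `stat` (Mann-Whitney U of the TR group) and `p`.
#' @export
wilcoxon_tr_vs_rest <- function(tr_aucs, other_aucs) {
  if (!length(tr_aucs) || !length(other_aucs))
    stop("both AUC groups must be non-empty")
  if (length(tr_aucs) + length(other_aucs) < 3L)
    stop("too few AUCs for a rank-sum test")
  wt <- suppressWarnings(
    stats::wilcox.test(tr_aucs, other_aucs, alternative = "greater",
                       correct = TRUE))
  list(stat = unname(wt$statistic), p = wt$p.value)
}

#' Standardized mean AUC of a TR against the compendium background
#'
#' @param tr_aucs the TR's dataset AUCs.
#' @param all_aucs every usable dataset AUC in the compendium.
#' @return `z = (mean(tr_aucs) - mean(all_aucs)) / sd(all_aucs)` (sample sd).
#' @export
zscore_tr <- function(tr_aucs, all_aucs) {
  if (length(all_aucs) < 2L) stop("background requires at least 2 AUCs")
  s <- stats::sd(all_aucs)
  if (s == 0) stop("background AUCs have zero variance")
  (mean(tr_aucs) - mean(all_aucs)) / s
}

#' Irwin-Hall lower-tail probability
#'
#' CDF at `s` of the sum of `k` independent uniform(0,1) variables, by the
#' standard alternating closed form.  Small rank-quantile sums (strong,
#' consistent association) give small p-values.
#'
#' @param s rank-quantile sum, in `[0, k]`.
#' @param k number of summed quantiles.
#' @return `P(U1 + ... + Uk <= s)`.
#' @export
irwin_hall_p <- function(s, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (any(s < 0 | s > k)) stop("rank sum outside [0, k]")
  vapply(s, function(si) {
    j <- 0:floor(si)
    # at si = k the alternating sum telescopes to k!, i.e. p = 1
    min(max(sum((-1)^j * choose(k, j) * (si - j)^k) / factorial(k), 0), 1)
  }, 0)
}

#' Rank transcriptional regulators against a cis-regulatory profile
#'
#' Scores every dataset by [auroc] on the ranked profile (for direction
#' `"decrease"` the profile is flipped first), aggregates per-TR statistics
#' (one-sided Wilcoxon vs the rest, z-score vs all datasets, maximum AUC),
#' converts each statistic to a rank quantile `r = rank / N_TRs` (ties share
#' the mean rank; best value, smallest `r`), and refers the quantile sum to
#' the Irwin-Hall distribution with `k = 3`.  Datasets with degenerate
#' binding (no bound or no unbound scored CRE) are skipped with a warning;
#' a TR left without usable datasets is dropped.
#'
#' @param profile a `cre_profile`.
#' @param compendium a [binding_compendium].
#' @param direction `"increase"` or `"decrease"`.
#' @return data.frame of class `tr_result_table`, sorted by ascending
#'   Irwin-Hall p (ties broken by TR name): `tr_name`, `n_datasets`,
#'   `max_auc`, `avg_auc`, `wilcoxon_stat`, `wilcoxon_p`, `z_score`,
#'   `rank_sum`, `irwin_hall_p`, `rank`.
#' @export
rank_trs <- function(profile, compendium,
                     direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (direction == "decrease") profile <- flip(profile)
  ranked <- ranked_cres(profile)
  ds <- compendium$datasets
  aucs <- vapply(ds$dataset_id, function(id)
    auroc(ranked, compendium$binding[[id]]), 0)
  bad <- is.na(aucs)
  if (any(bad))
    warning(sum(bad), " dataset(s) skipped for degenerate binding: ",
            paste(utils::head(ds$dataset_id[bad], 5), collapse = ","))
  ds <- ds[!bad, , drop = FALSE]; aucs <- aucs[!bad]
  trs <- sort(unique(ds$tr_name))
  if (length(trs) < 2L) stop("fewer than 2 TRs with usable datasets")

  per <- lapply(trs, function(tr) {
    mine <- ds$tr_name == tr
    w <- wilcoxon_tr_vs_rest(aucs[mine], aucs[!mine])
    data.frame(tr_name = tr, n_datasets = sum(mine),
               max_auc = max(aucs[mine]), avg_auc = mean(aucs[mine]),
               wilcoxon_stat = w$stat, wilcoxon_p = w$p,
               z_score = zscore_tr(aucs[mine], aucs))
  })
  tab <- do.call(rbind, per)
  n <- nrow(tab)
  r_w <- rank(tab$wilcoxon_p, ties.method = "average") / n
  r_z <- rank(-tab$z_score, ties.method = "average") / n
  r_m <- rank(-tab$max_auc, ties.method = "average") / n
  tab$rank_sum <- r_w + r_z + r_m
  tab$irwin_hall_p <- irwin_hall_p(tab$rank_sum, 3L)
  tab <- tab[order(tab$irwin_hall_p, tab$tr_name), , drop = FALSE]
  tab$rank <- seq_len(n)
  rownames(tab) <- NULL
  structure(tab, direction = direction,
            class = c("tr_result_table", "data.frame"))
}

#' Write a TR result table as TSV
#'
#' @param table a `tr_result_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tr_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}
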