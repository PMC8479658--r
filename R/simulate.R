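# Synthetic data with known ground truth: distance-decay Poisson contact
# maps with implanted differential blocks, a toy CRE catalog, and a toy
# binding compendium in which one "causal" TR binds preferentially inside
# the implanted blocks.  Every consuming module's validators accept the
# generated objects, so the whole pipeline is testable offline.

#' Simulation configuration
#'
#' Expected counts follow `lambda0 * (d + 1)^(-alpha)` at bin distance `d`;
#' inside an implanted block (both partners within the block's bin range)
#' the treatment condition's expectation is multiplied by `fold_change`.
#' The causal TR binds CREs inside blocks with probability
#' `bound_fraction * enrichment` (capped at 1) and `bound_fraction`
#' elsewhere; decoy TRs bind uniformly at `bound_fraction`.
#'
#' @param n_chroms,bins_per_chrom,bin_size genome geometry.
#' @param decay_exponent distance-decay exponent `alpha`.
#' @param base_depth expected count at distance 0 (`lambda0`).
#' @param n_replicates replicates per condition.
#' @param blocks data.frame with `chrom`, `first_bin`, `last_bin` (1-based,
#'   inclusive) and `fold_change`; `NULL` for the default one 30-bin block
#'   per chromosome at fold change 3.
#' @param n_cres,n_trs,n_datasets_per_tr,bound_fraction,enrichment compendium
#'   parameters.
#' @param dispersion `NULL` for Poisson noise, or a negative-binomial size
#'   parameter for overdispersed counts.
#' @param seed base random seed (all generation is reproducible from it).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, bins_per_chrom = 400L, bin_size = 5000L,
                       decay_exponent = 1.0, base_depth = 100,
                       n_replicates = 2L, blocks = NULL,
                       n_cres = 2000L, n_trs = 50L, n_datasets_per_tr = 2L,
                       bound_fraction = 0.05, enrichment = 10,
                       dispersion = NULL, seed = 1L) {
  if (is.null(blocks)) {
    mid <- bins_per_chrom %/% 2L
    blocks <- data.frame(chrom = paste0("chr", seq_len(n_chroms)),
                         first_bin = mid - 14L, last_bin = mid + 15L,
                         fold_change = 3)
  }
  stopifnot(n_chroms >= 1, bins_per_chrom >= 2, bin_size >= 1,
            base_depth > 0, n_replicates >= 1, all(blocks$fold_change > 0),
            all(blocks$first_bin >= 1), all(blocks$last_bin <= bins_per_chrom),
            n_cres >= 1, n_trs >= 2, n_datasets_per_tr >= 1,
            bound_fraction > 0, bound_fraction <= 1, enrichment >= 1)
  structure(list(n_chroms = as.integer(n_chroms),
                 bins_per_chrom = as.integer(bins_per_chrom),
                 bin_size = as.integer(bin_size),
                 decay_exponent = decay_exponent, base_depth = base_depth,
                 n_replicates = as.integer(n_replicates), blocks = blocks,
                 n_cres = as.integer(n_cres), n_trs = as.integer(n_trs),
                 n_datasets_per_tr = as.integer(n_datasets_per_tr),
                 bound_fraction = bound_fraction, enrichment = enrichment,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

sim_bins <- function(cfg) {
  genome_bins(paste0("chr", seq_len(cfg$n_chroms)),
              rep(cfg$bins_per_chrom * cfg$bin_size, cfg$n_chroms),
              cfg$bin_size)
}

# derived sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, ...) {
  k <- seed
  for (x in c(...)) k <- (k * 1009 + x) %% 2147483647
  as.integer(k)
}

#' Simulate one condition's contact maps
#'
#' @param cfg a [sim_config].
#' @param condition `"treatment"` or `"control"`; implanted blocks multiply
#'   the expectation only in the treatment.
#' @return a [sample_set] with `cfg$n_replicates` replicates.
#' @export
simulate_contact_maps <- function(cfg, condition = c("treatment", "control")) {
  condition <- match.arg(condition)
  bins <- sim_bins(cfg)
  n <- cfg$bins_per_chrom
  cond_idx <- match(condition, c("control", "treatment"))
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    mats <- lapply(seq_len(cfg$n_chroms), function(ci) {
      chrom <- bins$chrom_names[ci]
      set.seed(sub_seed(cfg$seed, cond_idx, r, ci))
      blk <- cfg$blocks[cfg$blocks$chrom == chrom, , drop = FALSE]
      i_all <- integer(); j_all <- integer(); c_all <- numeric()
      for (d in 0:(n - 1L)) {
        lam <- rep(cfg$base_depth * (d + 1)^(-cfg$decay_exponent), n - d)
        if (condition == "treatment" && nrow(blk)) {
          i <- seq_len(n - d)
          for (b in seq_len(nrow(blk))) {
            inside <- i >= blk$first_bin[b] & (i + d) <= blk$last_bin[b]
            lam[inside] <- lam[inside] * blk$fold_change[b]
          }
        }
        cnt <- if (is.null(cfg$dispersion)) stats::rpois(n - d, lam)
               else stats::rnbinom(n - d, size = cfg$dispersion, mu = lam)
        nz <- which(cnt > 0L)
        i_all <- c(i_all, nz); j_all <- c(j_all, nz + d)
        c_all <- c(c_all, cnt[nz])
      }
      contact_matrix(chrom, n, i_all, j_all, c_all)
    })
    names(mats) <- bins$chrom_names
    mats
  })
  sample_set(condition, reps, bins)
}

#' Simulate a toy CRE catalog
#'
#' Elements of 200 bp placed uniformly at random over the genome, sorted by
#' position, with dense stable ordinals.
#'
#' @param cfg a [sim_config].
#' @return a [cre_catalog].
#' @export
simulate_cre_catalog <- function(cfg) {
  bins <- sim_bins(cfg)
  set.seed(sub_seed(cfg$seed, 91))
  chrom <- sample(bins$chrom_names, cfg$n_cres, replace = TRUE)
  mid <- floor(stats::runif(cfg$n_cres, 100,
                            bins$chrom_lengths[chrom] - 100))
  reg <- data.frame(chrom = chrom, start = as.integer(mid - 100L),
                    end = as.integer(mid + 100L))
  reg <- reg[order(match(reg$chrom, bins$chrom_names), reg$start), ]
  cre_catalog(reg, genome = "synthetic")
}

# TRUE for catalog elements whose midpoint bin lies inside an implanted block
cres_in_blocks <- function(cfg, catalog) {
  bins <- sim_bins(cfg)
  mid <- (catalog$start + catalog$end) %/% 2
  bin <- locate_bin(bins, catalog$chrom, mid)
  inside <- rep(FALSE, nrow(catalog))
  for (b in seq_len(nrow(cfg$blocks)))
    inside <- inside | (catalog$chrom == cfg$blocks$chrom[b] &
                          !is.na(bin) &
                          bin >= cfg$blocks$first_bin[b] &
                          bin <= cfg$blocks$last_bin[b])
  inside
}

#' Simulate a toy binding compendium
#'
#' The first TR (`TR001`, the causal one) binds block CREs at an enriched
#' rate; every other TR binds uniformly.  Each dataset is an independent
#' Bernoulli draw per CRE.
#'
#' @param cfg a [sim_config].
#' @param catalog the [cre_catalog] generated from the same config.
#' @return a [binding_compendium]; the causal TR's name is stored in the
#'   `causal_tr` attribute.
#' @export
simulate_compendium <- function(cfg, catalog) {
  inside <- cres_in_blocks(cfg, catalog)
  p_causal <- ifelse(inside, pmin(cfg$bound_fraction * cfg$enrichment, 1),
                     cfg$bound_fraction)
  tr_names <- sprintf("TR%03d", seq_len(cfg$n_trs))
  datasets <- data.frame(
    dataset_id = as.vector(t(outer(tr_names, seq_len(cfg$n_datasets_per_tr),
                                   function(t, j) sprintf("%s_ds%d", t, j)))),
    tr_name = rep(tr_names, each = cfg$n_datasets_per_tr))
  binding <- lapply(seq_len(nrow(datasets)), function(k) {
    set.seed(sub_seed(cfg$seed, 173, k))
    p <- if (datasets$tr_name[k] == tr_names[1]) p_causal
         else rep(cfg$bound_fraction, nrow(catalog))
    which(stats::runif(nrow(catalog)) < p) - 1L
  })
  names(binding) <- datasets$dataset_id
  comp <- binding_compendium(datasets, binding, nrow(catalog))
  attr(comp, "causal_tr") <- tr_names[1]
  comp
}

#' Simulate a complete two-condition experiment
#'
#' @param cfg a [sim_config].
#' @return list with `treatment`, `control` ([sample_set]s), `catalog`,
#'   `compendium` and `causal_tr`.
#' @export
simulate_experiment <- function(cfg) {
  catalog <- simulate_cre_catalog(cfg)
  compendium <- simulate_compendium(cfg, catalog)
  list(treatment = simulate_contact_maps(cfg, "treatment"),
       control = simulate_contact_maps(cfg, "control"),
       catalog = catalog, compendium = compendium,
       causal_tr = attr(compendium, "causal_tr"))
}

#' Write a sample set in multiple on-disk dialects
#'
#' Writes every replicate in the HiC-Pro triplet dialect, the cooler dialect
#' and the Juicer .hic dialect, enabling cross-dialect reader equivalence
#' tests.
#'
#' @param ss a [sample_set].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return list with per-replicate path vectors: `hicpro` (as
#'   `"<matrix>,<bed>"` pairs ready for [read_sample_set]), `cool`, `hic`.
#' @export
write_fixture_dialects <- function(ss, dir, prefix = ss$condition) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hicpro <- character(); cool <- character(); hic <- character()
  for (r in seq_along(ss$replicates)) {
    base <- file.path(dir, sprintf("%s_rep%d", prefix, r))
    hp <- write_hicpro(ss$replicates[[r]], ss$bins, base)
    hicpro <- c(hicpro, paste(hp[["matrix"]], hp[["bed"]], sep = ","))
    cool <- c(cool, write_cool(ss$replicates[[r]], ss$bins,
                               paste0(base, ".cool")))
    hic <- c(hic, write_juicer_hic(ss$replicates[[r]], ss$bins,
                                   paste0(base, ".hic")))
  }
  list(hicpro = hicpro, cool = cool, hic = hic)
}
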