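#' Run the full differential-interaction analysis
#'
#' End-to-end driver mirroring the command-line interface: read both
#' conditions' contact maps, validate them against each other, compute the
#' genome-wide DCI profile (optionally coverage-adjusted), project it onto
#' the CRE catalog, and rank the compendium's TRs in both directions.
#' Outputs written to `outdir`: `dci.bedGraph`, `dci_bins.tsv`,
#' `tr_increase.txt`, `tr_decrease.txt` and `run.log` (every effective
#' parameter plus dropped-data counts).  On any error, partial outputs are
#' removed and the error is re-thrown.
#'
#' @param treatment,control character vectors of replicate inputs (for
#'   `file_type = "hicpro"`, `"<matrix>,<bed>"` pairs).
#' @param file_type `"hicpro"`, `"cool"` or `"hic"`.
#' @param cre_catalog path to a BED file of candidate elements.
#' @param compendium_datasets,compendium_binding the compendium TSV sidecar
#'   pair (see [read_compendium]).
#' @param outdir output directory (created).
#' @param bin_size bin size in bp (required for `cool`/`hic` inputs; for
#'   `hicpro` it is inferred and checked when given).
#' @param genomic_distance flanking distance bound D in bp.
#' @param coverage_adjust regress out the coverage-ratio covariate.
#' @param species metadata label recorded in the log (no computational
#'   effect; catalog and compendium are explicit paths).
#' @return invisibly, a list with `profile`, `cre_profile`, `increase`,
#'   `decrease` and `paths`.
#' @export
dci_run <- function(treatment, control,
                    file_type = c("hicpro", "cool", "hic"),
                    cre_catalog, compendium_datasets, compendium_binding,
                    outdir, bin_size = NULL, genomic_distance = 200000L,
                    coverage_adjust = FALSE, species = NA_character_) {
  file_type <- match.arg(file_type)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("dci.bedGraph", "dci_bins.tsv",
                               "tr_increase.txt", "tr_decrease.txt",
                               "run.log"))
  names(paths) <- c("bedgraph", "bins", "increase", "decrease", "log")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths[file.exists(paths)]), add = TRUE)

  log_lines <- c(
    "# differential chromatin interaction run",
    paste0("treatment = ", paste(treatment, collapse = " ")),
    paste0("control = ", paste(control, collapse = " ")),
    paste0("file_type = ", file_type),
    paste0("bin_size = ", if (is.null(bin_size)) "auto" else bin_size),
    paste0("genomic_distance = ", genomic_distance),
    paste0("cre_catalog = ", cre_catalog),
    paste0("compendium_datasets = ", compendium_datasets),
    paste0("compendium_binding = ", compendium_binding),
    paste0("coverage_adjust = ", coverage_adjust),
    paste0("species = ", species),
    paste0("outdir = ", outdir))

  trt <- read_sample_set(treatment, file_type, "treatment", bin_size)
  ctl <- read_sample_set(control, file_type, "control", bin_size)
  bins <- validate_sample_sets(trt, ctl)
  if (!is.null(bin_size) && bins$bin_size != bin_size)
    stop(sprintf("bin size mismatch: data at %d bp, requested %d bp",
                 bins$bin_size, as.integer(bin_size)))

  profile <- compute_dci_profile(trt, ctl, D = genomic_distance)
  if (coverage_adjust)
    profile <- adjust_for_coverage(profile,
                                   compute_coverage(trt, genomic_distance),
                                   compute_coverage(ctl, genomic_distance))
  catalog <- read_cre_catalog(cre_catalog)
  n_unscored <- 0
  withCallingHandlers(
    cre_prof <- map_profile_to_cres(profile, catalog),
    message = function(m) {
      n_unscored <<- sum(as.numeric(
        regmatches(conditionMessage(m), regexpr("[0-9]+", conditionMessage(m)))))
      invokeRestart("muffleMessage")
    })
  comp <- read_compendium(compendium_datasets, compendium_binding,
                          nrow(catalog))
  inc <- rank_trs(cre_prof, comp, "increase")
  dec <- rank_trs(cre_prof, comp, "decrease")

  write_dci_bedgraph(profile, paths[["bedgraph"]])
  write_dci_table(profile, paths[["bins"]])
  write_tr_table(inc, paths[["increase"]])
  write_tr_table(dec, paths[["decrease"]])
  log_lines <- c(log_lines,
                 paste0("n_bins = ", nrow(profile)),
                 paste0("n_no_data_bins = ", sum(profile$no_data)),
                 paste0("n_cres = ", nrow(catalog)),
                 paste0("n_unscored_cres = ", n_unscored),
                 paste0("n_datasets = ", nrow(comp$datasets)),
                 paste0("n_trs = ", length(unique(comp$datasets$tr_name))))
  writeLines(log_lines, paths[["log"]])
  ok <- TRUE
  invisible(list(profile = profile, cre_profile = cre_prof,
                 increase = inc, decrease = dec, paths = paths))
}
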