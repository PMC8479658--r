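#' Catalog of candidate cis-regulatory elements
#'
#' A fixed, ordered list of genomic intervals — typically a union of DNaseI
#' hypersensitive sites — used as the common coordinate system between the
#' binned interaction profile and the binding compendium.  Ordinal IDs are
#' dense `0..N-1` in file order and stable across runs.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome optional genome label.
#' @return An object of class `cre_catalog`.
#' @export
cre_catalog <- function(regions, genome = NA_character_) {
  if (!nrow(regions)) stop("empty CRE catalog")
  if (any(regions$start >= regions$end))
    stop("invalid CRE interval (start >= end)")
  out <- data.frame(cre_id = seq_len(nrow(regions)) - 1L,
                    chrom = as.character(regions$chrom),
                    start = as.integer(regions$start),
                    end = as.integer(regions$end))
  structure(out, genome = genome, class = c("cre_catalog", "data.frame"))
}

#' Read a CRE catalog from a BED file
#'
#' @param path BED3+ file (0-based half-open; extra columns ignored).
#' @param genome optional genome label.
#' @return a [cre_catalog] in file order.
#' @export
read_cre_catalog <- function(path, genome = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- data.table::fread(path, header = FALSE, select = 1:3,
                           col.names = c("chrom", "start", "end"),
                           colClasses = list(character = 1))
  cre_catalog(as.data.frame(bed), genome = genome)
}

#' Project a DCI profile onto a CRE catalog
#'
#' Each element takes the score of the bin containing its midpoint — CREs
#' (~0.1-1 kb) are tiny relative to the bins (>= 5 kb), so the midpoint rule
#' is unambiguous and order-independent.  Elements whose midpoint falls on a
#' chromosome absent from the profile, beyond the chromosome end, or in a
#' `no_data` bin are left unscored; unscored elements are excluded from
#' ranking rather than zero-filled, since zero is a meaningful "no change"
#' score.
#'
#' @param profile a `dci_profile`.
#' @param catalog a [cre_catalog].
#' @return An object of class `cre_profile`: the catalog with `score` and
#'   `scored` columns.
#' @export
map_profile_to_cres <- function(profile, catalog) {
  if (!nrow(catalog)) stop("empty CRE catalog")
  bins <- attr(profile, "bins")
  mid <- (catalog$start + catalog$end) %/% 2
  local <- locate_bin(bins, catalog$chrom, mid)
  global <- local + bins$offset[catalog$chrom]
  scored <- !is.na(global) & !profile$no_data[ifelse(is.na(global), 1L, global)]
  score <- rep(NA_real_, nrow(catalog))
  score[scored] <- profile$score[global[scored]]
  if (!any(scored)) stop("no CRE could be scored against the profile")
  n_miss <- sum(!scored)
  if (n_miss) message(n_miss, " CRE(s) left unscored")
  out <- catalog
  out$score <- score
  out$scored <- scored
  structure(out, class = c("cre_profile", class(catalog)))
}

#' Flip a cis-regulatory profile
#'
#' Negates every score (the scored mask is unchanged), so that regulators
#' associated with decreased interactions can be ranked by the same
#' machinery that ranks increases.  Flipping twice is the identity.
#'
#' @param profile a `cre_profile`.
#' @return the flipped profile.
#' @export
flip <- function(profile) {
  profile$score <- -profile$score
  profile
}

#' Write a CRE profile as TSV
#'
#' @param profile a `cre_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cre_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
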