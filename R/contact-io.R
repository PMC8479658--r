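#' Read a HiC-Pro raw count matrix
#'
#' HiC-Pro emits a sparse whitespace-separated triplet file
#' (`binID1 binID2 count`, 1-based genome-wide bin IDs) plus a companion
#' `_abs.bed` file (`chrom start end binID`) defining the bins.  Only
#' intra-chromosomal pixels are kept; the number of dropped inter-chromosomal
#' pixels is reported with a message.
#'
#' @param matrix_path path to the `.matrix` triplet file.
#' @param bed_path path to the `_abs.bed` bin definition file.
#' @return list with elements `bins` (a [genome_bins]) and `matrices` (named
#'   list of [contact_matrix], one per chromosome) — one replicate of one
#'   condition.
#' @export
read_hicpro <- function(matrix_path, bed_path) {
  for (p in c(matrix_path, bed_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bed <- data.table::fread(bed_path, header = FALSE,
                           col.names = c("chrom", "start", "end", "bin_id"),
                           colClasses = list(character = 1))
  bins <- bed_to_bins(bed)
  mat <- if (file.size(matrix_path) == 0)
    data.table::data.table(id1 = integer(), id2 = integer(),
                           count = numeric())
  else tryCatch(
    data.table::fread(matrix_path, header = FALSE,
                      col.names = c("id1", "id2", "count")),
    error = function(e) stop("malformed triplet file ", matrix_path, ": ",
                             conditionMessage(e)))
  if (nrow(mat) && (!is.numeric(mat$id1) || !is.numeric(mat$id2)))
    stop("malformed triplet file ", matrix_path)
  if (any(mat$count < 0)) stop("negative count in ", matrix_path)
  id_chrom <- bed$chrom[match(mat$id1, bed$bin_id)]
  id_chrom2 <- bed$chrom[match(mat$id2, bed$bin_id)]
  if (anyNA(id_chrom) || anyNA(id_chrom2))
    stop("triplet bin ID absent from bed file: ",
         paste(utils::head(unique(c(mat$id1[is.na(id_chrom)],
                                    mat$id2[is.na(id_chrom2)])), 5),
               collapse = ","))
  inter <- id_chrom != id_chrom2
  if (any(inter))
    message("dropped ", sum(inter), " inter-chromosomal pixel(s)")
  mat <- mat[!inter]
  id_chrom <- id_chrom[!inter]
  # genome-wide 1-based IDs -> chromosome-local 1-based indices
  first_id <- bed$bin_id[match(bins$chrom_names, bed$chrom)]
  names(first_id) <- bins$chrom_names
  matrices <- lapply(bins$chrom_names, function(chrom) {
    sel <- id_chrom == chrom
    contact_matrix(chrom, bins$n_bins[[chrom]],
                   bin1 = mat$id1[sel] - first_id[[chrom]] + 1L,
                   bin2 = mat$id2[sel] - first_id[[chrom]] + 1L,
                   count = mat$count[sel])
  })
  names(matrices) <- bins$chrom_names
  list(bins = bins, matrices = matrices)
}

# Build genome_bins from a HiC-Pro/cooler style bin table; enforces uniform
# widths except possibly the terminal bin of each chromosome.
bed_to_bins <- function(bed) {
  bed <- as.data.frame(bed)
  widths <- bed$end - bed$start
  if (any(widths <= 0)) stop("bin with non-positive width in bed input")
  bin_size <- max(widths)
  chroms <- unique(bed$chrom)
  for (chrom in chroms) {
    sub <- bed[bed$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    w <- sub$end - sub$start
    if (any(w[-length(w)] != bin_size))
      stop("non-uniform bin width on ", chrom,
           " (only the terminal bin may be short)")
    if (w[length(w)] > bin_size)
      stop("non-uniform bin width on ", chrom)
    if (any(sub$start != (seq_len(nrow(sub)) - 1L) * bin_size))
      stop("bins on ", chrom, " are not contiguous multiples of the bin size")
  }
  lens <- vapply(chroms, function(ch) max(bed$end[bed$chrom == ch]), 0)
  genome_bins(chroms, lens, bin_size)
}

#' Write one replicate in the HiC-Pro triplet dialect
#'
#' @param matrices named list of [contact_matrix] (chromosome order defines
#'   genome-wide bin IDs).
#' @param bins the [genome_bins] of the matrices.
#' @param prefix output path prefix; writes `<prefix>.matrix` and
#'   `<prefix>_abs.bed`.
#' @return invisibly, the two paths written.
#' @export
write_hicpro <- function(matrices, bins, prefix) {
  beds <- lapply(bins$chrom_names, function(chrom) {
    tab <- bin_table(bins, chrom)
    data.table::data.table(chrom = chrom, start = tab$start, end = tab$end,
                           bin_id = seq_len(nrow(tab)) + bins$offset[[chrom]])
  })
  bed <- data.table::rbindlist(beds)
  trips <- lapply(bins$chrom_names, function(chrom) {
    px <- matrices[[chrom]]$pixels
    data.table::data.table(id1 = px$bin1 + bins$offset[[chrom]],
                           id2 = px$bin2 + bins$offset[[chrom]],
                           count = px$count)
  })
  trip <- data.table::rbindlist(trips)
  paths <- c(matrix = paste0(prefix, ".matrix"),
             bed = paste0(prefix, "_abs.bed"))
  data.table::fwrite(trip, paths[["matrix"]], sep = "\t", col.names = FALSE)
  data.table::fwrite(bed, paths[["bed"]], sep = "\t", col.names = FALSE)
  invisible(paths)
}

#' Read a cooler contact store
#'
#' Reads the raw `count` field of a single-resolution cooler (HDF5 container
#' with `bins/{chrom,start,end}` and `pixels/{bin1_id,bin2_id,count}`
#' tables).  A multi-resolution store (`.mcool`) must be addressed with the
#' usual `path::/resolutions/<res>` suffix.
#'
#' @param path path to the `.cool` file, optionally `file::group`.
#' @param bin_size expected bin size in bp; mismatch with the store is an
#'   error, never a silent rebinning.
#' @return same structure as [read_hicpro].
#' @export
read_cool <- function(path, bin_size) {
  parts <- strsplit(path, "::", fixed = TRUE)[[1]]
  file <- parts[1]
  group <- if (length(parts) > 1L) sub("^/", "", parts[2]) else ""
  if (!file.exists(file)) stop("file not found: ", file)
  root <- rhdf5::h5ls(file, recursive = 1)
  if (group == "" && !("bins" %in% root$name)) {
    if ("resolutions" %in% root$name)
      stop("multi-resolution store: select a resolution with ",
           "'", file, "::/resolutions/<bin_size>'")
    stop("no bins table found in ", file)
  }
  gp <- function(x) if (group == "") x else paste0(group, "/", x)
  chrom <- as.character(rhdf5::h5read(file, gp("bins/chrom")))
  start <- as.numeric(rhdf5::h5read(file, gp("bins/start")))
  end <- as.numeric(rhdf5::h5read(file, gp("bins/end")))
  bed <- data.table::data.table(chrom = chrom, start = start, end = end,
                                bin_id = seq_along(chrom))
  bins <- bed_to_bins(bed)
  if (bins$bin_size != bin_size)
    stop(sprintf("bin size mismatch: store is %d bp, requested %d bp",
                 bins$bin_size, as.integer(bin_size)))
  b1 <- as.numeric(rhdf5::h5read(file, gp("pixels/bin1_id")))  # 0-based
  b2 <- as.numeric(rhdf5::h5read(file, gp("pixels/bin2_id")))
  count <- as.numeric(rhdf5::h5read(file, gp("pixels/count")))
  if (any(count < 0)) stop("negative count in ", file)
  c1 <- chrom[b1 + 1]; c2 <- chrom[b2 + 1]
  inter <- c1 != c2
  if (any(inter))
    message("dropped ", sum(inter), " inter-chromosomal pixel(s)")
  keep <- !inter
  matrices <- lapply(bins$chrom_names, function(ch) {
    sel <- keep & c1 == ch
    contact_matrix(ch, bins$n_bins[[ch]],
                   bin1 = b1[sel] - bins$offset[[ch]] + 1L,
                   bin2 = b2[sel] - bins$offset[[ch]] + 1L,
                   count = count[sel])
  })
  names(matrices) <- bins$chrom_names
  list(bins = bins, matrices = matrices)
}

#' Write one replicate as a minimal single-resolution cooler store
#'
#' @inheritParams write_hicpro
#' @param path output `.cool` path (overwritten).
#' @return invisibly, `path`.
#' @export
write_cool <- function(matrices, bins, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5createGroup(path, "pixels")
  bed <- data.table::rbindlist(lapply(bins$chrom_names, function(chrom) {
    tab <- bin_table(bins, chrom)
    data.table::data.table(chrom = chrom, start = tab$start, end = tab$end)
  }))
  rhdf5::h5write(bed$chrom, path, "bins/chrom")
  rhdf5::h5write(as.integer(bed$start), path, "bins/start")
  rhdf5::h5write(as.integer(bed$end), path, "bins/end")
  trip <- data.table::rbindlist(lapply(bins$chrom_names, function(chrom) {
    px <- matrices[[chrom]]$pixels
    data.table::data.table(
      bin1_id = px$bin1 + bins$offset[[chrom]] - 1L,  # cooler is 0-based
      bin2_id = px$bin2 + bins$offset[[chrom]] - 1L,
      count = px$count)
  }))
  rhdf5::h5write(as.integer(trip$bin1_id), path, "pixels/bin1_id")
  rhdf5::h5write(as.integer(trip$bin2_id), path, "pixels/bin2_id")
  rhdf5::h5write(trip$count, path, "pixels/count")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.integer(bins$bin_size), fid, "bin-size")
  rhdf5::h5writeAttribute("HDF5::Cooler", fid, "format")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Assemble a sample set from per-replicate files
#'
#' Convenience wrapper used by the pipeline: reads each replicate with the
#' dialect-appropriate reader and checks all replicates share one binning.
#'
#' @param paths character vector of replicate inputs.  For `file_type =
#'   "hicpro"` each entry is `"<matrix>,<bed>"` (comma-separated pair).
#' @param file_type `"hicpro"`, `"cool"` or `"hic"`.
#' @param condition `"treatment"` or `"control"`.
#' @param bin_size bin size in bp (required for `cool` and `hic`).
#' @return a [sample_set].
#' @export
read_sample_set <- function(paths, file_type = c("hicpro", "cool", "hic"),
                            condition, bin_size = NULL) {
  file_type <- match.arg(file_type)
  reps <- lapply(paths, function(p) {
    switch(file_type,
      hicpro = {
        pair <- strsplit(p, ",", fixed = TRUE)[[1]]
        if (length(pair) != 2L)
          stop("hicpro replicate must be '<matrix>,<bed>': ", p)
        read_hicpro(pair[1], pair[2])
      },
      cool = read_cool(p, bin_size),
      hic = read_juicer_hic(p, bin_size))
  })
  bins <- reps[[1]]$bins
  for (r in reps[-1])
    if (!same_bins(bins, r$bins))
      stop("replicates of the ", condition, " set use different binnings")
  sample_set(condition, lapply(reps, `[[`, "matrices"), bins)
}
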