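# Minimal pure-R support for the Juicer .hic binary contact-map format
# (version 7/8 layout, BP unit, raw observed counts only).  The reader covers
# exactly what the pipeline needs — header, master index, per-chromosome
# matrix records and zlib block decoding; no normalization vectors, no
# fragment resolutions.  The writer emits small version-8 files for fixtures
# and round-trip tests (single block per chromosome, list-of-rows encoding).

# --- little-endian cursor over a raw vector -------------------------------

hic_cursor <- function(raw, pos = 1L) {
  env <- new.env(parent = emptyenv())
  env$raw <- raw
  env$pos <- pos
  env
}

cur_take <- function(cur, n) {
  if (cur$pos + n - 1L > length(cur$raw)) stop("unexpected end of .hic file")
  out <- cur$raw[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + n
  out
}

cur_i32 <- function(cur, n = 1L)
  readBin(cur_take(cur, 4L * n), "integer", n = n, size = 4L,
          endian = "little")

cur_i16 <- function(cur, n = 1L)
  readBin(cur_take(cur, 2L * n), "integer", n = n, size = 2L, signed = TRUE,
          endian = "little")

cur_f32 <- function(cur, n = 1L)
  readBin(cur_take(cur, 4L * n), "numeric", n = n, size = 4L,
          endian = "little")

cur_i64 <- function(cur) {
  lo <- cur_i32(cur)
  hi <- cur_i32(cur)
  if (lo < 0) lo <- lo + 2^32
  hi * 2^32 + lo
}

cur_byte <- function(cur) as.integer(cur_take(cur, 1L))

cur_string <- function(cur) {
  start <- cur$pos
  nul <- start
  while (cur$raw[nul] != as.raw(0L)) {
    nul <- nul + 1L
    if (nul > length(cur$raw)) stop("unterminated string in .hic file")
  }
  out <- if (nul > start) rawToChar(cur$raw[start:(nul - 1L)]) else ""
  cur$pos <- nul + 1L
  out
}

# --- reader ----------------------------------------------------------------

#' Read raw observed counts from a Juicer .hic file
#'
#' Parses the binary .hic container directly (format versions 7 and 8, BP
#' resolutions): header, footer master index, and the zlib-compressed contact
#' blocks of every intra-chromosomal matrix, returning unnormalized observed
#' counts.  The whole-genome `ALL` pseudo-chromosome and any fragment
#' resolutions are ignored.
#'
#' @param path path to the `.hic` file.
#' @param bin_size requested BP resolution; must be one of the file's
#'   resolutions (the error lists what is available).
#' @return same structure as [read_hicpro].
#' @export
read_juicer_hic <- function(path, bin_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  cur <- hic_cursor(raw)
  if (cur_string(cur) != "HIC") stop("not a .hic file (bad magic): ", path)
  version <- cur_i32(cur)
  if (!version %in% c(7L, 8L))
    stop("unsupported .hic format version ", version,
         " (versions 7 and 8 are supported)")
  master_pos <- cur_i64(cur)
  cur_string(cur)                              # genome id, unused
  n_attr <- cur_i32(cur)
  for (k in seq_len(n_attr)) { cur_string(cur); cur_string(cur) }
  n_chr <- cur_i32(cur)
  chr_names <- character(n_chr)
  chr_lens <- numeric(n_chr)
  for (k in seq_len(n_chr)) {
    chr_names[k] <- cur_string(cur)
    chr_lens[k] <- cur_i32(cur)
  }
  n_res <- cur_i32(cur)
  resolutions <- cur_i32(cur, n_res)
  bin_size <- as.integer(bin_size)
  if (!bin_size %in% resolutions)
    stop("resolution ", bin_size, " bp not in file; available: ",
         paste(sort(resolutions), collapse = ", "))

  # footer: master index of matrix records, keyed "<chr1Idx>_<chr2Idx>"
  fcur <- hic_cursor(raw, pos = as.integer(master_pos) + 1L)
  cur_i32(fcur)                                # footer byte count, unused
  n_entries <- cur_i32(fcur)
  index <- new.env(parent = emptyenv())
  for (k in seq_len(n_entries)) {
    key <- cur_string(fcur)
    posn <- cur_i64(fcur)
    cur_i32(fcur)                              # record size, unused
    assign(key, posn, envir = index)
  }

  keep <- which(toupper(chr_names) != "ALL")
  bins <- genome_bins(chr_names[keep], chr_lens[keep], bin_size)
  matrices <- list()
  for (k in keep) {
    chrom <- chr_names[k]
    key <- paste0(k - 1L, "_", k - 1L)         # header indices are 0-based
    n <- bins$n_bins[[chrom]]
    if (!exists(key, envir = index)) {
      matrices[[chrom]] <- contact_matrix(chrom, n)
      next
    }
    px <- read_hic_matrix_record(raw, get(key, envir = index), bin_size)
    matrices[[chrom]] <- contact_matrix(chrom, n, px$x + 1L, px$y + 1L,
                                        px$count)
  }
  list(bins = bins, matrices = matrices[bins$chrom_names])
}

# Parse one matrix record (all zoom levels of one chromosome pair) and
# decode the blocks of the requested BP resolution into 0-based pixels.
read_hic_matrix_record <- function(raw, pos, bin_size) {
  cur <- hic_cursor(raw, pos = as.integer(pos) + 1L)
  cur_i32(cur, 2L)                             # chr indices, unused
  n_zoom <- cur_i32(cur)
  for (z in seq_len(n_zoom)) {
    unit <- cur_string(cur)
    cur_i32(cur)                               # zoom index
    cur_f32(cur, 4L)                           # sum/occupied/stdev/p95
    res <- cur_i32(cur)
    cur_i32(cur, 2L)                           # blockBinCount, blockColumnCount
    n_blocks <- cur_i32(cur)
    block_pos <- numeric(n_blocks)
    block_size <- integer(n_blocks)
    for (b in seq_len(n_blocks)) {
      cur_i32(cur)                             # block number
      block_pos[b] <- cur_i64(cur)
      block_size[b] <- cur_i32(cur)
    }
    if (unit == "BP" && res == bin_size) {
      px <- lapply(seq_len(n_blocks), function(b) {
        comp <- raw[(block_pos[b] + 1):(block_pos[b] + block_size[b])]
        read_hic_block(memDecompress(comp, type = "gzip"))
      })
      return(data.table::rbindlist(px))
    }
  }
  stop("matrix record lacks the requested BP resolution")
}

read_hic_block <- function(buf) {
  cur <- hic_cursor(buf)
  n_rec <- cur_i32(cur)
  x_off <- cur_i32(cur)
  y_off <- cur_i32(cur)
  use_short <- cur_byte(cur) == 1L
  type <- cur_byte(cur)
  x <- integer(n_rec); y <- integer(n_rec); val <- numeric(n_rec)
  if (type == 1L) {                            # list of rows
    i <- 0L
    row_count <- cur_i16(cur)
    for (r in seq_len(row_count)) {
      row_y <- y_off + cur_i16(cur)
      cnt <- cur_i16(cur)
      for (cidx in seq_len(cnt)) {
        i <- i + 1L
        x[i] <- x_off + cur_i16(cur)
        y[i] <- row_y
        val[i] <- if (use_short) cur_i16(cur) else cur_f32(cur)
      }
    }
  } else if (type == 2L) {                     # dense window
    n_pts <- cur_i32(cur)
    w <- cur_i16(cur)
    i <- 0L
    for (p in seq_len(n_pts)) {
      v <- if (use_short) cur_i16(cur) else cur_f32(cur)
      if ((use_short && v == -32768) || (!use_short && is.nan(v))) next
      i <- i + 1L
      row <- (p - 1L) %/% w
      col <- (p - 1L) - row * w
      x[i] <- x_off + col
      y[i] <- y_off + row
      val[i] <- v
    }
    length(x) <- i; length(y) <- i; length(val) <- i
  } else stop("unknown .hic block representation: ", type)
  data.table::data.table(x = x, y = y, count = val)
}

# --- writer ----------------------------------------------------------------

w_i32 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                   endian = "little")
w_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                   endian = "little")
w_i64 <- function(con, x) {
  stopifnot(x >= 0, x < 2^31)                  # fixture files are small
  w_i32(con, c(as.integer(x), 0L))
}
w_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4L,
                                   endian = "little")
w_byte <- function(con, x) writeBin(as.raw(x), con)
w_string <- function(con, s) writeBin(c(charToRaw(s), as.raw(0L)), con)

#' Write contact matrices as a minimal Juicer .hic file
#'
#' Produces a small format-version-8 file with a single BP resolution and one
#' contact block per chromosome, sufficient for cross-dialect fixtures.  The
#' standard `ALL` pseudo-chromosome heads the chromosome list.  Chromosomes
#' over 32 000 bins are refused (the single-block row encoding stores local
#' offsets as 16-bit integers).
#'
#' @inheritParams write_hicpro
#' @param path output `.hic` path (overwritten).
#' @param genome_id genome label stored in the header.
#' @return invisibly, `path`.
#' @export
write_juicer_hic <- function(matrices, bins, path, genome_id = "synthetic") {
  if (any(bins$n_bins > 32000L))
    stop("write_juicer_hic supports chromosomes up to 32000 bins")
  blocks <- lapply(bins$chrom_names, function(chrom)
    hic_encode_block(matrices[[chrom]]))

  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con), add = TRUE)
  w_string(con, "HIC")
  w_i32(con, 8L)
  master_pos_at <- seek(con)
  w_i64(con, 0L)                               # master index pos, patched later
  w_string(con, genome_id)
  w_i32(con, 0L)                               # no attributes
  w_i32(con, length(bins$chrom_names) + 1L)
  w_string(con, "ALL")
  w_i32(con, as.integer(ceiling(sum(bins$chrom_lengths) / 1000)))
  for (chrom in bins$chrom_names) {
    w_string(con, chrom)
    w_i32(con, as.integer(bins$chrom_lengths[[chrom]]))
  }
  w_i32(con, 1L)                               # one BP resolution
  w_i32(con, bins$bin_size)
  w_i32(con, 0L)                               # no fragment resolutions

  # body: one matrix record per chromosome (header index i, 0-based, ALL = 0)
  keys <- character(); positions <- numeric(); sizes <- integer()
  for (k in seq_along(bins$chrom_names)) {
    chrom <- bins$chrom_names[k]
    px <- matrices[[chrom]]$pixels
    rec_start <- seek(con)
    w_i32(con, c(k, k))                        # chr1Idx, chr2Idx
    w_i32(con, 1L)                             # one zoom level
    w_string(con, "BP")
    w_i32(con, 0L)                             # zoom index
    w_f32(con, c(sum(px$count), nrow(px), 0, 0))
    w_i32(con, bins$bin_size)
    w_i32(con, c(bins$n_bins[[chrom]], 1L))    # blockBinCount, blockColumnCount
    w_i32(con, 1L)                             # one block
    w_i32(con, 0L)                             # block number
    block_pos_at <- seek(con)
    w_i64(con, 0L)                             # block position, patched later
    w_i32(con, length(blocks[[k]]))
    block_start <- seek(con)
    writeBin(blocks[[k]], con)
    rec_end <- seek(con)
    seek(con, block_pos_at)
    w_i64(con, block_start)
    seek(con, rec_end)
    keys <- c(keys, paste0(k, "_", k))
    positions <- c(positions, rec_start)
    sizes <- c(sizes, as.integer(block_start - rec_start))
  }

  master_pos <- seek(con)
  fcon <- rawConnection(raw(0L), "wb")
  w_i32(fcon, length(keys))
  for (k in seq_along(keys)) {
    w_string(fcon, keys[k])
    w_i64(fcon, positions[k])
    w_i32(fcon, sizes[k])
  }
  w_i32(fcon, 0L)                              # no expected value vectors
  footer <- rawConnectionValue(fcon)
  close(fcon)
  w_i32(con, length(footer))
  writeBin(footer, con)
  seek(con, master_pos_at)
  w_i64(con, master_pos)
  out <- rawConnectionValue(con)
  writeBin(out, path)
  invisible(path)
}

# zlib-compressed list-of-rows block for one chromosome's pixels
hic_encode_block <- function(cm) {
  px <- cm$pixels
  use_short <- nrow(px) == 0L ||
    (all(px$count == round(px$count)) && all(px$count < 32768))
  bcon <- rawConnection(raw(0L), "wb")
  on.exit(close(bcon), add = TRUE)
  w_i32(bcon, nrow(px))
  w_i32(bcon, c(0L, 0L))                       # binX/binY offsets
  w_byte(bcon, if (use_short) 1L else 0L)
  w_byte(bcon, 1L)                             # list-of-rows representation
  rows <- split(px, px$bin2)                   # y = larger bin, 0-based on disk
  w_i16(bcon, length(rows))
  for (row in rows) {
    w_i16(bcon, row$bin2[1] - 1L)
    w_i16(bcon, nrow(row))
    for (r in seq_len(nrow(row))) {
      w_i16(bcon, row$bin1[r] - 1L)
      if (use_short) w_i16(bcon, row$count[r]) else w_f32(bcon, row$count[r])
    }
  }
  memCompress(rawConnectionValue(bcon), type = "gzip")
}
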