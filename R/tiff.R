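# Minimal multi-page TIFF codec (baseline, uncompressed, single sample per
# pixel). No TIFF package is available in the supported dependency set, so
# the subset of the format needed for microscopy volumes is implemented
# here: grayscale pages of 8/16-bit unsigned integers or 32-bit floats,
# strip storage, little- or big-endian, no compression. Voxel spacing is
# carried in the ImageDescription tag as plain "spacing_x=..." lines (full
# decimal precision), with an ImageJ-style "spacing=" line also understood
# for the z step on read.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

#' Read a multi-page TIFF as a volume
#'
#' Page `k` becomes the z-slice `k`; page pixel (row `j`, column `i`) maps
#' to voxel `(i, j, k)`, so a stack of `h x w` pages yields extents
#' `(w, h, n_pages)`.
#'
#' @param path TIFF file path.
#' @param spacing optional length-3 numeric override `(sx, sy, sz)` in um.
#'   When `NULL` the spacing is taken from the file's ImageDescription; if
#'   absent there, 1 um isotropic is assumed with a warning.
#' @param as_label reinterpret strictly binary data (`{0, 1}` or `{0, v}`)
#'   as a [label_volume()]; errors on non-binary data.
#' @param object_id,channel_name identifiers attached to the result.
#' @return An [intensity_volume()] or, when `as_label`, a [label_volume()].
#' @export
read_volume <- function(path, spacing = NULL, as_label = FALSE,
                        object_id = "", channel_name = "") {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: '", path, "'")
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF file: '", path, "'"))
  if (rd_u16(raw, 2, endian) != 42) stop("not a TIFF file: '", path, "'")

  pages <- list()
  desc <- NULL
  off <- rd_u32(raw, 4, endian)
  while (off != 0) {
    ifd <- rd_ifd(raw, off, endian)
    pages[[length(pages) + 1]] <- ifd
    if (is.null(desc) && !is.null(ifd$tags[["270"]]))
      desc <- ifd$tags[["270"]]$char
    off <- ifd$next_off
  }
  if (length(pages) == 0) stop("TIFF contains no pages")

  dims <- vapply(pages, function(p) c(tag_num(p, 256), tag_num(p, 257)),
                 numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have unequal size")
  nx <- dims[1, 1]; ny <- dims[2, 1]; nz <- length(pages)

  data <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- rd_page(raw, pages[[k]], endian)

  if (is.null(spacing)) {
    spacing <- parse_spacing_desc(desc)
    if (is.null(spacing)) {
      warning("no voxel spacing in '", basename(path),
              "'; assuming 1 um isotropic")
      spacing <- c(1, 1, 1)
    }
  }
  vol <- intensity_volume(data, spacing, channel_name = channel_name)
  if (as_label) as_label_volume(vol, object_id = object_id) else vol
}

#' Write a volume as a multi-page TIFF
#'
#' Integer-valued data round-trips exactly (8- or 16-bit unsigned pages);
#' anything else is stored as 32-bit floats. Spacing is persisted in the
#' ImageDescription tag at full decimal precision.
#'
#' @param vol an [intensity_volume()], [label_volume()] or
#'   [signal_volume()].
#' @param path output file path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  v <- as.vector(data)
  integral <- all(v == floor(v)) && min(v) >= 0 && max(v) <= 65535
  if (integral) {
    bits <- if (max(v) <= 255) 8L else 16L
    fmt <- 1L
  } else {
    bits <- 32L
    fmt <- 3L
  }
  bytes_px <- bits / 8L
  desc <- sprintf("morphatlas\nspacing_x=%.17g\nspacing_y=%.17g\nspacing_z=%.17g\nunit=micron\n",
                  vol$spacing[1], vol$spacing[2], vol$spacing[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_bytes <- nx * ny * bytes_px
  # layout: header(8) | desc | page data ... | IFDs
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  ifd0_off <- data_off + nz * page_bytes
  if (ifd0_off %% 2 == 1) ifd0_off <- ifd0_off + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  wr_u16(con, 42); wr_u32(con, ifd0_off)
  writeBin(desc_raw, con)
  for (k in seq_len(nz)) {
    pix <- as.vector(data[, , k])
    if (bits == 8) {
      writeBin(as.raw(pix), con)
    } else if (bits == 16) {
      iv <- as.integer(pix)
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
      writeBin(iv, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(pix), con, size = 4, endian = "little")
    }
  }
  if ((data_off + nz * page_bytes) %% 2 == 1) writeBin(as.raw(0), con)
  for (k in seq_len(nz)) {
    wr_u16(con, n_entries)
    wr_entry(con, 256, 3, 1, nx)                       # ImageWidth
    wr_entry(con, 257, 3, 1, ny)                       # ImageLength
    wr_entry(con, 258, 3, 1, bits)                     # BitsPerSample
    wr_entry(con, 259, 3, 1, 1)                        # Compression: none
    wr_entry(con, 262, 3, 1, 1)                        # Photometric: min-is-black
    wr_entry(con, 270, 2, length(desc_raw), desc_off)  # ImageDescription
    wr_entry(con, 273, 4, 1, data_off + (k - 1) * page_bytes)  # StripOffsets
    wr_entry(con, 278, 3, 1, ny)                       # RowsPerStrip
    wr_entry(con, 279, 4, 1, page_bytes)               # StripByteCounts
    wr_entry(con, 339, 3, 1, fmt)                      # SampleFormat
    wr_u32(con, if (k < nz) ifd0_off + k * ifd_size else 0)
  }
  invisible(path)
}

# --- low-level helpers -------------------------------------------------

rd_u16 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 2)], "integer", 1, size = 2,
               signed = FALSE, endian = endian)
  v
}

rd_u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", 1, size = 4,
               endian = endian)
  if (v < 0) v <- v + 4294967296
  v
}

rd_ifd <- function(raw, off, endian) {
  n <- rd_u16(raw, off, endian)
  tags <- list()
  for (e in seq_len(n)) {
    base <- off + 2 + (e - 1) * 12
    tag <- rd_u16(raw, base, endian)
    type <- rd_u16(raw, base + 2, endian)
    count <- rd_u32(raw, base + 4, endian)
    size <- TIFF_TYPE_SIZES[min(type, length(TIFF_TYPE_SIZES))] * count
    voff <- if (size <= 4) base + 8 else rd_u32(raw, base + 8, endian)
    vals <- NULL; chars <- NULL
    if (type %in% c(3)) {
      vals <- vapply(seq_len(count), function(i)
        rd_u16(raw, voff + (i - 1) * 2, endian), numeric(1))
    } else if (type %in% c(4)) {
      vals <- vapply(seq_len(count), function(i)
        rd_u32(raw, voff + (i - 1) * 4, endian), numeric(1))
    } else if (type == 1) {
      vals <- as.numeric(raw[(voff + 1):(voff + count)])
    } else if (type == 2) {
      bytes <- raw[(voff + 1):(voff + count)]
      bytes <- bytes[bytes != as.raw(0)]
      chars <- rawToChar(bytes)
    } else if (type == 5) {  # RATIONAL
      vals <- vapply(seq_len(count), function(i) {
        num <- rd_u32(raw, voff + (i - 1) * 8, endian)
        den <- rd_u32(raw, voff + (i - 1) * 8 + 4, endian)
        if (den == 0) NA_real_ else num / den
      }, numeric(1))
    }
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      num = vals, char = chars, off = voff)
  }
  list(tags = tags, next_off = rd_u32(raw, off + 2 + n * 12, endian))
}

tag_num <- function(ifd, tag, default = NULL) {
  t <- ifd$tags[[as.character(tag)]]
  if (is.null(t) || is.null(t$num)) {
    if (is.null(default)) stop("missing required TIFF tag ", tag)
    return(default)
  }
  t$num[1]
}

rd_page <- function(raw, ifd, endian) {
  nx <- tag_num(ifd, 256); ny <- tag_num(ifd, 257)
  bits <- tag_num(ifd, 258, 1)
  comp <- tag_num(ifd, 259, 1)
  if (comp != 1) stop("compressed TIFF not supported (compression ", comp, ")")
  spp <- tag_num(ifd, 277, 1)
  if (spp != 1) stop("only single-sample (grayscale) TIFF supported")
  fmt <- tag_num(ifd, 339, 1)
  offs <- ifd$tags[["273"]]$num
  cnts <- ifd$tags[["279"]]$num
  if (is.null(offs)) stop("missing strip offsets")
  if (is.null(cnts)) cnts <- rep(nx * ny * bits / 8 / length(offs), length(offs))
  bytes <- do.call(c, lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + cnts[i])]))
  n <- nx * ny
  px <- if (bits == 8 && fmt %in% c(1, 2)) {
    as.numeric(bytes[seq_len(n)])
  } else if (bits == 16 && fmt %in% c(1, 2)) {
    readBin(bytes, "integer", n, size = 2, signed = FALSE, endian = endian)
  } else if (bits == 32 && fmt == 3) {
    readBin(bytes, "double", n, size = 4, endian = endian)
  } else {
    stop("unsupported TIFF pixel format: ", bits, "-bit, sample format ", fmt)
  }
  matrix(px, nrow = nx, ncol = ny)
}

parse_spacing_desc <- function(desc) {
  if (is.null(desc)) return(NULL)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  grab <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^", key, "="), "", hit[1])))
  }
  sx <- grab("spacing_x"); sy <- grab("spacing_y"); sz <- grab("spacing_z")
  if (!any(is.na(c(sx, sy, sz)))) return(c(sx, sy, sz))
  szj <- grab("spacing")  # ImageJ convention: z step only
  if (!is.na(szj)) return(c(1, 1, szj))
  NULL
}

wr_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2,
                                    endian = "little")

wr_u32 <- function(con, v) {
  v <- as.numeric(v)
  lo <- v %% 65536
  hi <- (v - lo) / 65536
  wr_u16(con, lo); wr_u16(con, hi)
}

wr_entry <- function(con, tag, type, count, value) {
  wr_u16(con, tag); wr_u16(con, type); wr_u32(con, count)
  if (type == 3 && count == 1) {
    wr_u16(con, value); wr_u16(con, 0)
  } else {
    wr_u32(con, value)
  }
}
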