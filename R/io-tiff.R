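# Minimal baseline TIFF codec for grayscale microscopy stacks.
#
# No TIFF package exists in the supported dependency set, so the subset of
# baseline TIFF needed here is implemented directly: uncompressed 8- or
# 16-bit single-sample grayscale, multi-page, little- or big-endian on read,
# little-endian single-strip on write. Anything fancier (compression, tiles,
# palettes, RGB) is rejected with a clear error.

.tiff_tag <- function(con, tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in 4 bytes for every tag we write
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a grayscale (multi-page) TIFF
#'
#' Uncompressed baseline TIFF, one strip per page, little-endian.
#'
#' @param frames A numeric matrix or a list of matrices (gray levels,
#'   `0..255` for 8-bit, `0..65535` for 16-bit); values are rounded and
#'   clamped.
#' @param path Output file path.
#' @param bits Bits per sample: 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(frames, path, bits = 8L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop_invalid_input("no frames to write")
  if (!bits %in% c(8L, 16L)) stop_invalid_input("`bits` must be 8 or 16")
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD comes right after the header + all pixel data
  bytes_pp <- vapply(frames, function(f) length(f) * (bits / 8), numeric(1))
  data_off <- 8 + c(0, cumsum(bytes_pp))[seq_along(frames)]
  first_ifd <- 8 + sum(bytes_pp)
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (f in frames) {
    v <- as.integer(pmin(pmax(round(t(f)), 0), maxval)) # row-major scan lines
    writeBin(v, con, size = bits / 8, endian = "little")
  }
  n_tags <- 9L
  ifd_size <- 2 + n_tags * 12 + 4
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    writeBin(n_tags, con, size = 2, endian = "little")
    .tiff_tag(con, 256L, 4L, 1L, ncol(f))              # ImageWidth
    .tiff_tag(con, 257L, 4L, 1L, nrow(f))              # ImageLength
    .tiff_tag(con, 258L, 3L, 1L, bits)                 # BitsPerSample
    .tiff_tag(con, 259L, 3L, 1L, 1L)                   # Compression: none
    .tiff_tag(con, 262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    .tiff_tag(con, 273L, 4L, 1L, data_off[i])          # StripOffsets
    .tiff_tag(con, 277L, 3L, 1L, 1L)                   # SamplesPerPixel
    .tiff_tag(con, 278L, 4L, 1L, nrow(f))              # RowsPerStrip
    .tiff_tag(con, 279L, 4L, 1L, length(f) * bits / 8) # StripByteCounts
    nxt <- if (i < length(frames)) first_ifd + i * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_uint <- function(raw, off, size, endian) {
  # off is 0-based; returns a double (safe for LONG values)
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a grayscale (multi-page) TIFF
#'
#' Supports uncompressed 8/16-bit single-sample grayscale baseline TIFF,
#' both byte orders, multiple strips.
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices (one per page).
#' @export
read_tiff_gray <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop_io(sprintf("'%s' is not a TIFF file", path))
  hdr <- rawToChar(raw[1:2])
  endian <- if (hdr == "II") "little" else if (hdr == "MM") "big" else
    stop_io(sprintf("'%s' is not a TIFF file (bad byte-order mark)", path))
  if (.read_uint(raw, 2, 2, endian) != 42)
    stop_io(sprintf("'%s' is not a TIFF file (bad magic)", path))
  ifd_off <- .read_uint(raw, 4, 4, endian)
  frames <- list()
  while (ifd_off != 0) {
    n_tags <- .read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (k in seq_len(n_tags)) {
      toff <- ifd_off + 2 + (k - 1) * 12
      tag <- .read_uint(raw, toff, 2, endian)
      type <- .read_uint(raw, toff + 2, 2, endian)
      count <- .read_uint(raw, toff + 4, 4, endian)
      tsize <- c(1, 1, 2, 4, 8)[type]
      if (is.na(tsize)) { tags[[as.character(tag)]] <- NULL; next }
      nbytes <- tsize * count
      voff <- if (nbytes <= 4) toff + 8 else .read_uint(raw, toff + 8, 4, endian)
      vals <- vapply(seq_len(count), function(j)
        .read_uint(raw, voff + (j - 1) * tsize, min(tsize, 4), endian), numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop_io("TIFF page missing dimensions")
    bits <- g(258, 8)[1]
    if (!bits %in% c(8, 16)) stop_io(sprintf("unsupported BitsPerSample: %d", bits))
    if (g(259, 1)[1] != 1) stop_io("compressed TIFF not supported")
    if (g(277, 1)[1] != 1) stop_io("multi-sample TIFF not supported")
    offs <- g(273); counts <- g(279)
    if (is.null(offs)) stop_io("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep(width * height * bits / 8 / length(offs), length(offs))
    vals <- numeric(0)
    for (j in seq_along(offs)) {
      npx <- counts[j] / (bits / 8)
      chunk <- readBin(raw[offs[j] + seq_len(counts[j])], "integer",
                       n = npx, size = bits / 8, signed = FALSE,
                       endian = endian)
      vals <- c(vals, chunk)
    }
    if (length(vals) < width * height) stop_io("truncated TIFF strip data")
    frames[[length(frames) + 1L]] <-
      matrix(vals[seq_len(width * height)], nrow = height, ncol = width, byrow = TRUE)
    ifd_off <- .read_uint(raw, ifd_off + 2 + n_tags * 12, 4, endian)
  }
  if (!length(frames)) stop_io(sprintf("no image pages in '%s'", path))
  frames
}

#' Write / read PGM (portable graymap)
#'
#' `write_pgm` writes binary (P5) PGM; `read_pgm` reads P2 (ASCII) and P5.
#' PGM is the plain-text-friendly interchange format used for small
#' fixtures.
#'
#' @param frame Numeric matrix of gray levels.
#' @param path File path.
#' @param maxval Maximum gray value (255 or 65535).
#' @return `write_pgm`: `path` invisibly; `read_pgm`: a numeric matrix.
#' @export
write_pgm <- function(frame, path, maxval = 255L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(frame), nrow(frame), maxval),
            con, eos = NULL)
  v <- as.integer(pmin(pmax(round(t(frame)), 0), maxval))
  size <- if (maxval > 255) 2 else 1
  writeBin(v, con, size = size, endian = "big")
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop_io(sprintf("'%s' is not a PGM file", path))
  # parse header tokens (width, height, maxval), skipping comments
  pos <- 3L
  toks <- integer(0)
  while (length(toks) < 3L && pos <= length(raw)) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") {
      while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      num <- ""
      while (pos <= length(raw) && grepl("[0-9]", rawToChar(raw[pos]))) {
        num <- paste0(num, rawToChar(raw[pos])); pos <- pos + 1L
      }
      toks <- c(toks, as.integer(num))
    } else pos <- pos + 1L
  }
  if (length(toks) < 3L) stop_io("malformed PGM header")
  width <- toks[1]; height <- toks[2]; maxval <- toks[3]
  if (magic == "P2") {
    txt <- rawToChar(raw[pos:length(raw)])
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    size <- if (maxval > 255) 2 else 1
    vals <- readBin(raw[(pos + 1):length(raw)], "integer",
                    n = width * height, size = size, signed = FALSE,
                    endian = "big")
  }
  if (length(vals) < width * height) stop_io("truncated PGM data")
  matrix(vals[seq_len(width * height)], nrow = height, ncol = width, byrow = TRUE)
}

#' Read a frame stack from a file or directory
#'
#' Accepts a multi-page TIFF, a single PGM, or a directory of numbered
#' `.tif`/`.tiff`/`.pgm` files (sorted by name).
#'
#' @param path File or directory.
#' @return List of numeric matrices.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|pgm)$", full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(files)) stop_io(sprintf("no frame files in directory '%s'", path))
    files <- files[order(files)]
    frames <- list()
    for (f in files) {
      frames <- c(frames, if (grepl("\\.pgm$", f, ignore.case = TRUE))
        list(read_pgm(f)) else read_tiff_gray(f))
    }
    return(frames)
  }
  if (!file.exists(path)) stop_io(sprintf("input '%s' does not exist", path))
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(list(read_pgm(path)))
  read_tiff_gray(path)
}
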