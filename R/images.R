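## Built-in grayscale PNG / baseline TIFF codecs.
##
## Images travel through the package as numeric matrices indexed
## [y, x] (row = y downward, column = x rightward, 0-based positions in
## all public coordinates) holding integer grey levels, with a
## `bit_depth` attribute of 8 or 16.  RGBA overlays are h x w x 4 arrays
## of 8-bit values.  The codecs cover exactly what the pipeline emits:
## 8/16-bit grayscale PNG and uncompressed baseline TIFF, plus 8-bit
## RGBA PNG for overlay pyramids.

em_image <- function(pixels, bit_depth = 8L) {
  stopifnot(is.matrix(pixels))
  attr(pixels, "bit_depth") <- as.integer(bit_depth)
  pixels
}

image_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

## ---- PNG ----------------------------------------------------------------

png_sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))

uint32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

be_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(rev(seq_along(bytes)) - 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32_raw(body)))
}

#' Write an image as PNG
#'
#' Grayscale matrices are written as 8- or 16-bit greyscale PNG
#' (per their `bit_depth` attribute); `h x w x 4` arrays as 8-bit RGBA.
#'
#' @param img numeric matrix of grey levels, or an RGBA array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) {
    bd <- image_depth(img)
    h <- nrow(img); w <- ncol(img)
    v <- as.vector(t(quantize(img, bd)))  # row-major
    if (bd == 8L) {
      bytes <- matrix(as.raw(v), nrow = w, ncol = h)
      colour <- 0L
    } else {
      b <- matrix(0, nrow = 2 * w, ncol = h)
      vv <- matrix(v, nrow = w, ncol = h)
      b[seq(1, 2 * w, 2), ] <- vv %/% 256
      b[seq(2, 2 * w, 2), ] <- vv %% 256
      bytes <- matrix(as.raw(b), nrow = 2 * w, ncol = h)
      colour <- 0L
    }
  } else if (length(dim(img)) == 3 && dim(img)[3] == 4) {
    h <- dim(img)[1]; w <- dim(img)[2]; bd <- 8L
    a <- aperm(array(pmin(pmax(round(img), 0), 255), dim = dim(img)),
               c(3, 2, 1))
    bytes <- matrix(as.raw(a), nrow = 4 * w, ncol = h)
    colour <- 6L
  } else {
    stop("write_png: expected a grayscale matrix or an RGBA array")
  }
  scan <- rbind(matrix(as.raw(0), 1, h), bytes)  # filter type 0 per row
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(bd), as.raw(colour),
            as.raw(c(0, 0, 0)))
  out <- c(png_sig,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_deflate(as.vector(scan))),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a PNG image
#'
#' Supports non-interlaced 8/16-bit greyscale and 8-bit RGBA PNG (all
#' five scanline filter types).
#'
#' @param path PNG file path.
#' @return a grey-level matrix with a `bit_depth` attribute, or an
#'   `h x w x 4` RGBA array.
#' @export
read_png <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8 || !identical(raw[1:8], png_sig))
    format_error("not a PNG file: %s", path)
  pos <- 9
  ihdr <- NULL; idat <- list()
  while (pos + 8 <= length(raw)) {
    len <- be_uint(raw[pos:(pos + 3)])
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    if (type == "IDAT") idat[[length(idat) + 1]] <- data
    if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (is.null(ihdr)) format_error("PNG missing IHDR: %s", path)
  w <- be_uint(ihdr[1:4]); h <- be_uint(ihdr[5:8])
  bd <- as.integer(ihdr[9]); colour <- as.integer(ihdr[10])
  if (as.integer(ihdr[13]) != 0L)
    format_error("interlaced PNG not supported: %s", path)
  channels <- switch(as.character(colour), "0" = 1L, "6" = 4L,
                     format_error("PNG colour type %d not supported", colour))
  if (!(bd %in% c(8L, 16L)) || (colour == 6L && bd != 8L))
    format_error("PNG bit depth %d not supported here", bd)
  bpp <- channels * bd %/% 8L
  rowbytes <- w * bpp
  stream <- zlib_inflate(do.call(c, idat), h * (rowbytes + 1))
  bytes <- png_unfilter(stream, h, rowbytes, bpp)
  v <- as.integer(bytes)
  if (colour == 0L) {
    if (bd == 8L) {
      img <- t(matrix(v, nrow = w, ncol = h))
    } else {
      m <- matrix(v, nrow = 2 * w, ncol = h)
      img <- t(m[seq(1, 2 * w, 2), , drop = FALSE] * 256 +
               m[seq(2, 2 * w, 2), , drop = FALSE])
    }
    em_image(img, bd)
  } else {
    a <- array(v, dim = c(4, w, h))
    aperm(a, c(3, 2, 1))
  }
}

## ---- Baseline TIFF ------------------------------------------------------

tiff_ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
  val <- if (type == 3L) {
    c(value %% 256, value %/% 256, 0, 0)
  } else {
    c(value %% 256, value %/% 256 %% 256,
      value %/% 65536 %% 256, value %/% 16777216 %% 256)
  }
  as.raw(c(tag %% 256, tag %/% 256, type %% 256, type %/% 256,
           count %% 256, count %/% 256 %% 256,
           count %/% 65536 %% 256, count %/% 16777216 %% 256, val))
}

#' Write a grayscale image as uncompressed baseline TIFF
#'
#' @inheritParams write_png
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  bd <- image_depth(img)
  h <- nrow(img); w <- ncol(img)
  v <- as.vector(t(quantize(img, bd)))  # row-major
  if (bd == 8L) {
    data <- as.raw(v)
  } else {
    b <- matrix(0, nrow = 2, ncol = length(v))
    b[1, ] <- v %% 256   # little-endian samples
    b[2, ] <- v %/% 256
    data <- as.raw(b)
  }
  datalen <- length(data)
  if (datalen %% 2 == 1) data <- c(data, as.raw(0))
  ifd_off <- 8 + length(data)
  entries <- list(
    tiff_ifd_entry(256L, 4L, 1L, w),
    tiff_ifd_entry(257L, 4L, 1L, h),
    tiff_ifd_entry(258L, 3L, 1L, bd),
    tiff_ifd_entry(259L, 3L, 1L, 1L),       # no compression
    tiff_ifd_entry(262L, 3L, 1L, 1L),       # BlackIsZero
    tiff_ifd_entry(273L, 4L, 1L, 8L),       # strip offset
    tiff_ifd_entry(277L, 3L, 1L, 1L),
    tiff_ifd_entry(278L, 4L, 1L, h),
    tiff_ifd_entry(279L, 4L, 1L, datalen))
  n <- length(entries)
  header <- c(charToRaw("II"), as.raw(c(42, 0)),
              as.raw(c(ifd_off %% 256, ifd_off %/% 256 %% 256,
                       ifd_off %/% 65536 %% 256, ifd_off %/% 16777216 %% 256)))
  ifd <- c(as.raw(c(n %% 256, n %/% 256)), do.call(c, entries),
           as.raw(c(0, 0, 0, 0)))
  writeBin(c(header, data, ifd), path)
  invisible(path)
}

le_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

#' Read an uncompressed grayscale TIFF
#'
#' Baseline reader for single-image, strip-organised, uncompressed 8- or
#' 16-bit grayscale TIFF in either byte order.
#'
#' @param path TIFF file path.
#' @return grey-level matrix with a `bit_depth` attribute.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) format_error("not a TIFF file: %s", path)
  order <- rawToChar(raw[1:2])
  if (!order %in% c("II", "MM")) format_error("not a TIFF file: %s", path)
  rd <- if (order == "II") le_uint else be_uint
  if (rd(raw[3:4]) != 42) format_error("bad TIFF magic in %s", path)
  ifd_off <- rd(raw[5:8])
  n <- rd(raw[(ifd_off + 1):(ifd_off + 2)])
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(raw[(e + 1):(e + 2)])
    type <- rd(raw[(e + 3):(e + 4)])
    count <- rd(raw[(e + 5):(e + 8)])
    vfield <- raw[(e + 9):(e + 12)]
    size <- c(1, 1, 2, 4)[type]  # BYTE/ASCII/SHORT/LONG
    if (is.na(size)) next
    values <- if (count * size <= 4) {
      vapply(seq_len(count), function(k)
        rd(vfield[((k - 1) * size + 1):(k * size)]), numeric(1))
    } else {
      off <- rd(vfield)
      vapply(seq_len(count), function(k)
        rd(raw[(off + (k - 1) * size + 1):(off + k * size)]), numeric(1))
    }
    tags[[as.character(tag)]] <- values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) format_error("TIFF tag %d missing in %s", tag, path)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bd <- need(258, 8)[1]
  if (need(259, 1) != 1) format_error("compressed TIFF not supported: %s", path)
  offsets <- need(273); counts <- need(279, w * h * bd / 8)
  data <- do.call(c, lapply(seq_along(offsets), function(k)
    raw[(offsets[k] + 1):(offsets[k] + counts[k])]))
  if (bd == 8) {
    v <- as.integer(data)
  } else {
    m <- matrix(as.integer(data), nrow = 2)
    v <- if (order == "II") m[1, ] + 256 * m[2, ] else m[2, ] + 256 * m[1, ]
  }
  em_image(t(matrix(v, nrow = w, ncol = h)), as.integer(bd))
}

## ---- dispatch -----------------------------------------------------------

#' Read an image file (PNG or TIFF, by extension)
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return image matrix (or RGBA array for colour PNG).
#' @export
read_image <- function(path) {
  switch(tolower(tools::file_ext(path)),
         png = read_png(path),
         tif = ,
         tiff = read_tiff(path),
         format_error("unsupported image extension: %s", path))
}

#' Write an image file (PNG or TIFF, by extension)
#' @inheritParams write_png
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  switch(tolower(tools::file_ext(path)),
         png = write_png(img, path),
         tif = ,
         tiff = write_tiff(img, path),
         format_error("unsupported image extension: %s", path))
}
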