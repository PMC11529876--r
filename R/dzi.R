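## Deep Zoom Image (dzi) tile pyramids.
##
## A dzi pyramid is an XML descriptor (`NAME.dzi`) plus a folder tree
## (`NAME_files/<level>/<col>_<row>.<fmt>`).  Level `max_level` is the
## full-resolution image, each level below is a 2x downsample, level 0
## is 1x1.  Geometry uses ceiling division throughout, and neighbouring
## tiles share `overlap` border pixels (none added on the left/top edge
## of edge tiles) -- the conventions standard deep-zoom viewers resolve.

dz_ns <- "http://schemas.microsoft.com/deepzoom/2008"

#' Construct a Deep Zoom pyramid descriptor
#'
#' @param width,height full-resolution mosaic dimensions in pixels.
#' @param tile_size tile edge length (>= 64; need not be a power of two).
#' @param overlap border pixels shared between neighbouring tiles.
#' @param format `"png"` (lossless, default for EM fidelity) or `"jpg"`.
#' @return a `dzi_descriptor` with `max_level = ceiling(log2(max(width,
#'   height)))`.
#' @export
dzi_descriptor <- function(width, height, tile_size = 256L, overlap = 1L,
                           format = c("png", "jpg")) {
  format <- match.arg(format)
  if (!is_count(width) || !is_count(height))
    config_error("pyramid dimensions must be positive integers")
  if (!is_count(tile_size) || tile_size < 64)
    config_error("tile_size must be an integer >= 64")
  if (overlap < 0 || overlap != round(overlap))
    config_error("overlap must be a non-negative integer")
  structure(list(width = as.integer(width), height = as.integer(height),
                 tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), format = format,
                 max_level = as.integer(ceiling(log2(max(width, height))))),
            class = "dzi_descriptor")
}

#' @export
print.dzi_descriptor <- function(x, ...) {
  cat(sprintf("<dzi %dx%d, tile %d, overlap %d, %s, levels 0..%d>\n",
              x$width, x$height, x$tile_size, x$overlap, x$format,
              x$max_level))
  invisible(x)
}

#' Pixel dimensions of a pyramid level
#'
#' @param desc a [dzi_descriptor()].
#' @param level level index, 0 (1x1) to `max_level` (full size).
#' @return integer `c(w, h)` via ceiling halving.
#' @export
dzi_level_dims <- function(desc, level) {
  if (level < 0 || level > desc$max_level)
    config_error("level %d outside 0..%d", level, desc$max_level)
  f <- 2^(desc$max_level - level)
  c(w = as.integer(ceiling(desc$width / f)),
    h = as.integer(ceiling(desc$height / f)))
}

#' Tile grid of a pyramid level
#'
#' @inheritParams dzi_level_dims
#' @return integer `c(cols, rows)`.
#' @export
dzi_tile_grid <- function(desc, level) {
  d <- dzi_level_dims(desc, level)
  c(cols = as.integer(ceiling(d[["w"]] / desc$tile_size)),
    rows = as.integer(ceiling(d[["h"]] / desc$tile_size)))
}

# Pixel rectangle of tile (col, row) on a level, including shared
# overlap borders, clipped to the level image.  0-based, end-exclusive.
dzi_tile_rect <- function(desc, level, col, row) {
  d <- dzi_level_dims(desc, level)
  ts <- desc$tile_size; ov <- desc$overlap
  x0 <- max(0L, col * ts - ov)
  y0 <- max(0L, row * ts - ov)
  x1 <- min(d[["w"]], (col + 1) * ts + ov)
  y1 <- min(d[["h"]], (row + 1) * ts + ov)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Serialize a descriptor as Deep Zoom XML
#'
#' @param desc a [dzi_descriptor()].
#' @return UTF-8 XML text with byte-stable attribute order.
#' @export
dzi_write_descriptor <- function(desc) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<Image TileSize="%d" Overlap="%d" Format="%s" xmlns="%s">',
                 desc$tile_size, desc$overlap, desc$format, dz_ns),
         sprintf('<Size Width="%d" Height="%d"/>', desc$width, desc$height),
         '</Image>\n')
}

#' Parse a Deep Zoom XML descriptor
#'
#' Validating reader: missing attributes or a wrong namespace raise a
#' format error naming the offending field.
#'
#' @param xml XML text or a file path ending in `.dzi`/`.xml`.
#' @return a [dzi_descriptor()].
#' @export
dzi_read_descriptor <- function(xml) {
  doc <- xml2::read_xml(xml)
  actual_ns <- unname(unlist(xml2::xml_ns(doc)))
  if (!dz_ns %in% actual_ns)
    format_error("dzi descriptor: missing or wrong xmlns (expected %s)", dz_ns)
  if (xml2::xml_name(doc) != "Image")
    format_error("dzi descriptor: root element must be Image")
  need_attr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) format_error("dzi descriptor: missing attribute %s", name)
    v
  }
  ts <- as.integer(need_attr(doc, "TileSize"))
  ov <- as.integer(need_attr(doc, "Overlap"))
  fmt <- need_attr(doc, "Format")
  size <- xml2::xml_find_first(doc, ".//*[local-name()='Size']")
  if (inherits(size, "xml_missing"))
    format_error("dzi descriptor: missing Size element")
  w <- as.integer(need_attr(size, "Width"))
  h <- as.integer(need_attr(size, "Height"))
  if (anyNA(c(ts, ov, w, h)))
    format_error("dzi descriptor: non-numeric geometry attribute")
  dzi_descriptor(w, h, ts, ov, fmt)
}

# One 2x downsampling step: Gaussian anti-alias pre-blur (sigma = 0.5
# per halving; the 2x2 area mean that follows supplies the rest of the
# smoothing) then area mean with ceiling division (edge blocks average
# the available pixels).  `box = TRUE` skips the pre-blur.
downsample2 <- function(img, box = FALSE) {
  h <- nrow(img); w <- ncol(img)
  if (h == 1 && w == 1) return(img)
  src <- if (box) img else gauss_blur(img, 0.5)
  H <- ceiling(h / 2); W <- ceiling(w / 2)
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (dy in 0:1) for (dx in 0:1) {
    if (1 + dy > h || 1 + dx > w) next
    ys <- seq(1 + dy, h, by = 2); xs <- seq(1 + dx, w, by = 2)
    ry <- (ys + 1) %/% 2; rx <- (xs + 1) %/% 2
    num[ry, rx] <- num[ry, rx] + src[ys, xs, drop = FALSE]
    den[ry, rx] <- den[ry, rx] + 1
  }
  num / den
}

#' Build a Deep Zoom pyramid from a mosaic
#'
#' Writes `<name>.dzi` and `<name>_files/<level>/<col>_<row>.<format>`
#' under `out_dir`.  Each level is the 2x downsample of the one above
#' (Gaussian anti-alias pre-blur, sigma = 0.5, then 2x2 area mean;
#' `box = TRUE` for a plain box filter).  On I/O failure partial
#' output is removed.
#'
#' @param mosaic grey-level matrix.
#' @param desc a [dzi_descriptor()] whose dimensions match the mosaic.
#' @param out_dir output directory (created if needed).
#' @param name pyramid name (file stem).
#' @param box use a plain 2x2 box downsample.
#' @return manifest list: `dzi` path, `levels` data.frame (level, w, h,
#'   cols, rows, tiles), `n_files` total tiles written.
#' @export
dzi_build <- function(mosaic, desc, out_dir, name = "mosaic", box = FALSE) {
  stopifnot(inherits(desc, "dzi_descriptor"))
  if (desc$format != "png")
    config_error("the built-in codec writes png pyramids only; use format = \"png\"")
  if (nrow(mosaic) != desc$height || ncol(mosaic) != desc$width)
    config_error("mosaic is %dx%d but descriptor says %dx%d",
                 ncol(mosaic), nrow(mosaic), desc$width, desc$height)
  bd <- image_depth(mosaic)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files_dir <- file.path(out_dir, paste0(name, "_files"))
  ok <- FALSE
  on.exit(if (!ok) unlink(c(files_dir, file.path(out_dir, paste0(name, ".dzi"))),
                          recursive = TRUE), add = TRUE)
  writeLines(dzi_write_descriptor(desc),
             file.path(out_dir, paste0(name, ".dzi")), sep = "")
  levels <- data.frame()
  img <- matrix(as.numeric(mosaic), nrow(mosaic), ncol(mosaic))
  for (level in desc$max_level:0) {
    d <- dzi_level_dims(desc, level)
    stopifnot(nrow(img) == d[["h"]], ncol(img) == d[["w"]])
    g <- dzi_tile_grid(desc, level)
    lvl_dir <- file.path(files_dir, level)
    dir.create(lvl_dir, recursive = TRUE, showWarnings = FALSE)
    qimg <- em_image(quantize(img, bd), bd)
    for (row in 0:(g[["rows"]] - 1)) for (col in 0:(g[["cols"]] - 1)) {
      rc <- dzi_tile_rect(desc, level, col, row)
      tile <- qimg[(rc[["y0"]] + 1):rc[["y1"]],
                   (rc[["x0"]] + 1):rc[["x1"]], drop = FALSE]
      write_png(em_image(tile, bd),
                file.path(lvl_dir, sprintf("%d_%d.%s", col, row,
                                           desc$format)))
    }
    levels <- rbind(levels, data.frame(level = level, w = d[["w"]],
                                       h = d[["h"]], cols = g[["cols"]],
                                       rows = g[["rows"]],
                                       tiles = g[["cols"]] * g[["rows"]]))
    log_msg("info", "dzi level %d: %dx%d px, %d tiles", level,
            d[["w"]], d[["h"]], g[["cols"]] * g[["rows"]])
    if (level > 0) img <- downsample2(img, box = box)
  }
  ok <- TRUE
  levels <- levels[order(levels$level), ]
  rownames(levels) <- NULL
  list(dzi = file.path(out_dir, paste0(name, ".dzi")),
       files_dir = files_dir, levels = levels,
       n_files = sum(levels$tiles))
}

#' Reassemble a pyramid level from its tiles
#'
#' Reads the tiles of one level, crops the shared overlap borders and
#' stitches them back into the level image -- the lossless round-trip
#' check for `format = "png"`.
#'
#' @param desc a [dzi_descriptor()].
#' @param files_dir the `<name>_files` directory.
#' @param level level to reassemble (default `max_level`).
#' @return grey-level matrix of the level image.
#' @export
dzi_reassemble <- function(desc, files_dir, level = desc$max_level) {
  d <- dzi_level_dims(desc, level)
  g <- dzi_tile_grid(desc, level)
  out <- matrix(0, d[["h"]], d[["w"]])
  for (row in 0:(g[["rows"]] - 1)) for (col in 0:(g[["cols"]] - 1)) {
    tile <- read_image(file.path(files_dir, level,
                                 sprintf("%d_%d.%s", col, row, desc$format)))
    rc <- dzi_tile_rect(desc, level, col, row)
    # interior region of this tile (without shared borders)
    ix0 <- col * desc$tile_size; iy0 <- row * desc$tile_size
    ix1 <- min(d[["w"]], (col + 1) * desc$tile_size)
    iy1 <- min(d[["h"]], (row + 1) * desc$tile_size)
    out[(iy0 + 1):iy1, (ix0 + 1):ix1] <-
      tile[(iy0 - rc[["y0"]] + 1):(iy1 - rc[["y0"]]),
           (ix0 - rc[["x0"]] + 1):(ix1 - rc[["x0"]]), drop = FALSE]
  }
  out
}
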