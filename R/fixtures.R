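## Synthetic EM-like montages with known ground truth.
##
## The generator stands in for real transmission-EM mosaics: a textured
## phantom ("specimen") is cut into an overlapping tile grid the way a
## microscope stage would record it, then each tile is corrupted with
## the two artifact classes the pipeline must undo -- a smooth per-tile
## shading field plus a per-tile brightness offset (illumination issue)
## and additive Gaussian noise.  Because the crop origins, the injected
## shading surfaces and the clean crops are all retained, every
## downstream stage can be validated against exact ground truth.

#' Specification of a synthetic EM phantom
#'
#' @param width_px,height_px phantom dimensions in pixels (>= 64).
#' @param n_blobs number of round, darker "organelle" blobs; placed
#'   without overlap so the blob mask has exactly `n_blobs` connected
#'   components.
#' @param membrane_density fraction in `[0, 1]` scaling the number of
#'   curvilinear membrane-like structures.
#' @param texture_sigma standard deviation (grey levels) of the
#'   band-limited background texture.
#' @param bit_depth 8 or 16.
#' @param seed integer RNG seed; the same spec is bit-identical across runs.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(width_px, height_px, n_blobs = 12,
                         membrane_density = 0.3, texture_sigma = 8,
                         bit_depth = 8L, seed = 1L) {
  if (!is_count(width_px) || !is_count(height_px))
    config_error("phantom dimensions must be positive integers")
  if (width_px < 64 || height_px < 64)
    config_error("phantom dimensions must be at least 64 px")
  if (!is_count(n_blobs + 1))  # allow 0
    config_error("n_blobs must be a non-negative integer")
  if (membrane_density < 0 || membrane_density > 1)
    config_error("membrane_density must be in [0, 1]")
  if (texture_sigma < 0) config_error("texture_sigma must be >= 0")
  bit_range(bit_depth)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_blobs = as.integer(n_blobs),
                 membrane_density = membrane_density,
                 texture_sigma = texture_sigma,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur with edge clamping; kernel truncated at 3 sigma.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in -r:r) {  # vertical pass
    rows <- pmin(pmax(seq_len(h) + i, 1L), h)
    out <- out + k[i + r + 1] * img[rows, , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (i in -r:r) {  # horizontal pass
    cols <- pmin(pmax(seq_len(w) + i, 1L), w)
    out2 <- out2 + k[i + r + 1] * out[, cols, drop = FALSE]
  }
  out2
}

#' Generate a synthetic EM phantom image
#'
#' Builds a grayscale image of band-limited texture plus darker round
#' blobs and curvilinear membrane-like structures.  The blob mask and
#' the pure texture layer are attached as attributes (`blob_mask`,
#' `texture`) so tests can compare against them.
#'
#' @param spec a [phantom_spec()].
#' @return grey-level matrix with `bit_depth`, `blob_mask` and `texture`
#'   attributes.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  range <- bit_range(spec$bit_depth)[2]
  with_seed(spec$seed, {
    base <- 0.6 * range
    texture <- matrix(0, h, w)
    if (spec$texture_sigma > 0) {
      texture <- gauss_blur(matrix(rnorm(h * w), h, w), 2)
      texture <- texture * (spec$texture_sigma / sd(texture))
    }
    # non-overlapping blobs: rejection-sampled centres with a >= 3 px gap
    blob_mask <- matrix(FALSE, h, w)
    blob_layer <- matrix(0, h, w)
    if (spec$n_blobs > 0) {
      rmin <- max(3, round(0.02 * min(h, w)))
      rmax <- max(rmin + 1, round(0.045 * min(h, w)))
      cx <- cy <- rr <- numeric(0)
      tries <- 0L
      while (length(cx) < spec$n_blobs && tries < 20000L) {
        tries <- tries + 1L
        r <- runif(1, rmin, rmax)
        x <- runif(1, r + 2, w - r - 1)
        y <- runif(1, r + 2, h - r - 1)
        if (length(cx) == 0 ||
            all(sqrt((cx - x)^2 + (cy - y)^2) >= rr + r + 3)) {
          cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
        }
      }
      if (length(cx) < spec$n_blobs)
        config_error("could not place %d non-overlapping blobs on a %dx%d phantom",
                     spec$n_blobs, w, h)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      ys <- matrix(rep(seq_len(h), w), h, w)
      for (i in seq_along(cx)) {
        d <- sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
        blob_mask <- blob_mask | (d <= rr[i])
        depth <- runif(1, 0.15, 0.35) * range
        # soft-edged profile so blobs look like stained organelles
        blob_layer <- blob_layer - depth * pmax(0, 1 - (d / rr[i])^2)
      }
    }
    # membranes: smooth random walks stamped as thin dark curves
    mem_layer <- matrix(0, h, w)
    n_mem <- round(spec$membrane_density * 16)
    if (n_mem > 0) {
      mem_mask <- matrix(0, h, w)
      for (i in seq_len(n_mem)) {
        len <- round(runif(1, 0.3, 0.8) * min(h, w))
        x <- runif(1, 5, w - 4); y <- runif(1, 5, h - 4)
        ang <- runif(1, 0, 2 * pi)
        dang <- rnorm(len, 0, 0.08)
        for (s in seq_len(len)) {
          ang <- ang + dang[s]
          x <- x + cos(ang); y <- y + sin(ang)
          if (x < 2 || x > w - 1 || y < 2 || y > h - 1) break
          mem_mask[round(y), round(x)] <- 1
        }
      }
      mem_layer <- -0.25 * range * pmin(1, gauss_blur(mem_mask, 0.8) * 2.5)
    }
    img <- quantize(base + texture + blob_layer + mem_layer, spec$bit_depth)
    attr(img, "bit_depth") <- spec$bit_depth
    attr(img, "blob_mask") <- blob_mask
    attr(img, "texture") <- texture
    img
  })
}

#' Specification of how a phantom is sliced into a tile montage
#'
#' @param rows,cols grid shape (positive integers).
#' @param tile_px square tile side length in pixels.
#' @param overlap_fraction nominal overlap between adjacent tiles, in
#'   `(0, 0.9)`; EM montages are typically recorded with ~0.3.
#' @param jitter_px maximum absolute stage-position error per tile.
#'   Offsets are drawn independently and uniformly from the integers
#'   `[-jitter_px, jitter_px]` (or continuously, with bilinear
#'   resampling, when `subpixel = TRUE`).
#' @param shading_amplitude peak-to-peak amplitude of the per-tile
#'   quadratic shading field, as a fraction of the dynamic range.
#' @param brightness_jitter per-tile constant offset drawn uniformly
#'   from `[-b, b]` as a fraction of the dynamic range.
#' @param noise_sigma additive Gaussian noise sigma in grey levels.
#' @param order acquisition order of the returned tile list.
#' @param pixel_size_nm physical pixel size carried on each tile.
#' @param subpixel draw continuous jitter and resample bilinearly.
#' @param seed integer RNG seed.
#' @return a `slice_spec` object.
#' @export
slice_spec <- function(rows, cols, tile_px = 256L, overlap_fraction = 0.3,
                       jitter_px = 0, shading_amplitude = 0,
                       brightness_jitter = 0, noise_sigma = 0,
                       order = c("row-major", "serpentine"),
                       pixel_size_nm = 2, subpixel = FALSE, seed = 1L) {
  order <- match.arg(order)
  if (!is_count(rows) || !is_count(cols))
    config_error("grid rows/cols must be positive integers")
  if (!is_count(tile_px) || tile_px < 16)
    config_error("tile_px must be an integer >= 16")
  if (overlap_fraction <= 0 || overlap_fraction >= 0.9)
    config_error("overlap_fraction must be in (0, 0.9)")
  if (jitter_px < 0) config_error("jitter_px must be >= 0")
  overlap_px <- tile_px - round(tile_px * (1 - overlap_fraction))
  if (2 * jitter_px >= overlap_px)
    config_error("jitter_px (%g) too large for a %g overlap of %d px",
                 jitter_px, overlap_fraction, overlap_px)
  if (pixel_size_nm <= 0) config_error("pixel_size_nm must be > 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tile_px = as.integer(tile_px),
                 overlap_fraction = overlap_fraction,
                 jitter_px = jitter_px,
                 shading_amplitude = shading_amplitude,
                 brightness_jitter = brightness_jitter,
                 noise_sigma = noise_sigma, order = order,
                 pixel_size_nm = pixel_size_nm,
                 subpixel = isTRUE(subpixel), seed = as.integer(seed)),
            class = "slice_spec")
}

# Quadratic shading surface on [-1,1]^2, zero-mean, scaled to the
# requested peak-to-peak amplitude.  Coefficients returned for tests.
random_shading_field <- function(h, w, amplitude, range) {
  if (amplitude <= 0)
    return(list(field = matrix(0, h, w), coef = numeric(6)))
  u <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
  v <- matrix(rep(seq(-1, 1, length.out = h), w), h, w)
  co <- rnorm(6)
  f <- co[1] + co[2] * u + co[3] * v + co[4] * u^2 + co[5] * u * v +
    co[6] * v^2
  f <- f - mean(f)
  pp <- max(f) - min(f)
  if (pp < 1e-12) return(list(field = matrix(0, h, w), coef = numeric(6)))
  s <- amplitude * range / pp
  list(field = f * s, coef = co * s)
}

bilinear_crop <- function(img, y0, x0, h, w) {
  # crop with fractional 0-based origin (y0, x0) via bilinear sampling
  iy <- floor(y0); ix <- floor(x0)
  fy <- y0 - iy; fx <- x0 - ix
  sub <- img[(iy + 1):(iy + h + 1), (ix + 1):(ix + w + 1)]
  a <- sub[1:h, 1:w]; b <- sub[1:h, 2:(w + 1)]
  c <- sub[2:(h + 1), 1:w]; d <- sub[2:(h + 1), 2:(w + 1)]
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c + fx * d)
}

#' Slice a phantom into a corrupted tile montage with ground truth
#'
#' Cuts an overlapping tile grid out of a phantom, applying stage
#' jitter to each crop origin, then corrupts each tile in place:
#' quadratic shading field, constant brightness offset, Gaussian noise,
#' re-quantized to the phantom's bit depth.  The returned ground truth
#' holds the exact crop origins; with all corruption and jitter at 0,
#' compositing the tiles at ground truth reconstructs the phantom
#' bit-exactly.
#'
#' @param phantom image from [make_phantom()] (any grey matrix works).
#' @param spec a [slice_spec()].
#' @return list with `tiles` (list of `em_tile`, in acquisition order)
#'   and `truth` (a `mosaic_layout` of the crop origins).  Each tile
#'   additionally carries `truth$shading`, `truth$brightness` and
#'   `truth$clean` for validation.
#' @export
slice_tiles <- function(phantom, spec) {
  stopifnot(inherits(spec, "slice_spec"))
  bd <- image_depth(phantom)
  range <- bit_range(bd)[2]
  tp <- spec$tile_px
  step <- round(tp * (1 - spec$overlap_fraction))
  j <- spec$jitter_px
  need_w <- (spec$cols - 1) * step + tp + 2 * ceiling(j) + spec$subpixel
  need_h <- (spec$rows - 1) * step + tp + 2 * ceiling(j) + spec$subpixel
  if (ncol(phantom) < need_w || nrow(phantom) < need_h)
    config_error("grid %dx%d of %d px tiles (step %d, jitter %g) needs a %dx%d phantom; got %dx%d",
                 spec$rows, spec$cols, tp, step, j, need_w, need_h,
                 ncol(phantom), nrow(phantom))
  with_seed(spec$seed, {
    n <- spec$rows * spec$cols
    # acquisition order
    idx <- do.call(rbind, lapply(seq_len(spec$rows) - 1L, function(r) {
      cs <- seq_len(spec$cols) - 1L
      if (spec$order == "serpentine" && r %% 2 == 1) cs <- rev(cs)
      cbind(row = r, col = cs)
    }))
    jx <- if (j > 0) {
      if (spec$subpixel) runif(n, -j, j) else sample(-j:j, n, replace = TRUE)
    } else numeric(n)
    jy <- if (j > 0) {
      if (spec$subpixel) runif(n, -j, j) else sample(-j:j, n, replace = TRUE)
    } else numeric(n)
    margin <- ceiling(j)
    tiles <- vector("list", n)
    pos <- matrix(0, n, 2)
    for (k in seq_len(n)) {
      r <- unname(idx[k, "row"]); cc <- unname(idx[k, "col"])
      x0 <- margin + cc * step + jx[k]
      y0 <- margin + r * step + jy[k]
      pos[k, ] <- c(x0, y0)
      clean <- if (spec$subpixel && (jx[k] %% 1 != 0 || jy[k] %% 1 != 0)) {
        bilinear_crop(phantom, y0, x0, tp, tp)
      } else {
        phantom[(y0 + 1):(y0 + tp), (x0 + 1):(x0 + tp)]
      }
      sh <- random_shading_field(tp, tp, spec$shading_amplitude, range)
      off <- if (spec$brightness_jitter > 0)
        runif(1, -spec$brightness_jitter, spec$brightness_jitter) * range
      else 0
      noise <- if (spec$noise_sigma > 0)
        matrix(rnorm(tp * tp, 0, spec$noise_sigma), tp, tp)
      else 0
      pixels <- quantize(clean + sh$field + off + noise, bd)
      tiles[[k]] <- em_tile(pixels, row = r, col = cc,
                            nominal_overlap = spec$overlap_fraction,
                            pixel_size_nm = spec$pixel_size_nm,
                            bit_depth = bd,
                            truth = list(shading = sh$field,
                                         shading_coef = sh$coef,
                                         brightness = off,
                                         clean = clean,
                                         x = x0, y = y0))
    }
    ids <- sprintf("r%d_c%d", idx[, "row"], idx[, "col"])
    truth <- mosaic_layout(data.frame(id = ids, row = idx[, "row"],
                                      col = idx[, "col"],
                                      x = pos[, 1], y = pos[, 2],
                                      stringsAsFactors = FALSE),
                           tile_w = tp, tile_h = tp, normalize = FALSE)
    list(tiles = tiles, truth = truth)
  })
}

#' Write a montage to disk as TIFF tiles plus a ground-truth sidecar
#'
#' Tiles are written as `tile_r{row}_c{col}.tif`; crop origins and the
#' slicing parameters go into `ground_truth.json`.
#'
#' @param montage result of [slice_tiles()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tiles <- function(montage, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in montage$tiles)
    write_tiff(t$pixels, file.path(dir, sprintf("tile_r%d_c%d.tif",
                                                t$row, t$col)))
  sidecar <- list(positions = montage$truth$positions,
                  tile_w = montage$truth$tile_w,
                  tile_h = montage$truth$tile_h,
                  pixel_size_nm = montage$tiles[[1]]$pixel_size_nm,
                  nominal_overlap = montage$tiles[[1]]$nominal_overlap)
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tile montage from a directory
#'
#' Reads `tile_r{row}_c{col}.tif` (or `.png`) files; grid indices come
#' from the filenames.  If a `ground_truth.json` sidecar is present its
#' layout is returned as `truth`.
#'
#' @param dir directory of tile images.
#' @param nominal_overlap,pixel_size_nm metadata used when no sidecar
#'   exists.
#' @return list with `tiles` and (possibly `NULL`) `truth`.
#' @export
read_tiles <- function(dir, nominal_overlap = 0.3, pixel_size_nm = 2) {
  files <- list.files(dir, pattern = "^tile_r\\d+_c\\d+\\.(tif|tiff|png)$")
  if (length(files) == 0) config_error("no tile images found in %s", dir)
  sidecar_path <- file.path(dir, "ground_truth.json")
  truth <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    truth <- mosaic_layout(sc$positions, tile_w = sc$tile_w,
                           tile_h = sc$tile_h, normalize = FALSE)
    nominal_overlap <- sc$nominal_overlap %||% nominal_overlap
    pixel_size_nm <- sc$pixel_size_nm %||% pixel_size_nm
  }
  m <- regmatches(files, regexec("^tile_r(\\d+)_c(\\d+)\\.", files))
  tiles <- lapply(seq_along(files), function(i) {
    img <- read_image(file.path(dir, files[i]))
    em_tile(img, row = as.integer(m[[i]][2]), col = as.integer(m[[i]][3]),
            nominal_overlap = nominal_overlap,
            pixel_size_nm = pixel_size_nm, bit_depth = image_depth(img))
  })
  ord <- order(vapply(tiles, function(t) t$row, 0),
               vapply(tiles, function(t) t$col, 0))
  list(tiles = tiles[ord], truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
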