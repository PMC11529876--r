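## Flat-field (illumination) correction of individual tiles.
##
## Smooth per-tile intensity gradients -- a misaligned beam or an
## uncalibrated detector -- turn into conspicuous repetitive patterns
## once tiles are assembled, so each tile is corrected *before*
## registration and compositing.  Three classic remedies are provided:
## rolling-ball background subtraction, polynomial shading correction,
## and frequency-domain high-pass filtering.  All three operate in
## floating point and re-quantize only on write.

#' Flat-field correction parameters
#'
#' Exactly one method is active.
#'
#' @param method `"rolling_ball"`, `"polynomial"` or `"highpass"`.
#' @param radius_px rolling-ball disk radius (default: tile width / 8,
#'   resolved when applied).
#' @param degree polynomial total degree, 0--4.
#' @param cutoff_fraction Gaussian high-pass cutoff as a fraction of the
#'   sampling frequency, in (0, 0.5).
#' @param preserve_mean restore the original mean intensity so stitched
#'   mosaics keep their grey-level scale (blending compares absolute
#'   intensities); default `TRUE`.
#' @param light_background rolling-ball only: estimate the background
#'   from the inverted image (for bright structures on dark ground).
#' @return a `flatfield_params` object.
#' @export
flatfield_params <- function(method = c("rolling_ball", "polynomial",
                                        "highpass"),
                             radius_px = NULL, degree = 2,
                             cutoff_fraction = 0.02, preserve_mean = TRUE,
                             light_background = FALSE) {
  method <- match.arg(method)
  if (method == "rolling_ball" && !is.null(radius_px) && radius_px < 1)
    config_error("radius_px must be >= 1")
  if (method == "polynomial" &&
      (!is_count(degree + 1) || degree < 0 || degree > 4))
    config_error("polynomial degree must be an integer in [0, 4]")
  if (method == "highpass" &&
      (cutoff_fraction <= 0 || cutoff_fraction >= 0.5))
    config_error("cutoff_fraction must be in (0, 0.5)")
  structure(list(method = method, radius_px = radius_px,
                 degree = as.integer(degree),
                 cutoff_fraction = cutoff_fraction,
                 preserve_mean = isTRUE(preserve_mean),
                 light_background = isTRUE(light_background)),
            class = "flatfield_params")
}

#' Apply a configured flat-field correction
#'
#' @param img grey-level matrix.
#' @param params a [flatfield_params()].
#' @return corrected image, same dimensions and bit depth.
#' @export
apply_flatfield <- function(img, params) {
  stopifnot(inherits(params, "flatfield_params"))
  switch(params$method,
         rolling_ball = rolling_ball(img,
                                     params$radius_px %||%
                                       max(1, round(ncol(img) / 8)),
                                     preserve_mean = params$preserve_mean,
                                     light_background = params$light_background),
         polynomial = polynomial_flatfield(img, params$degree,
                                           preserve_mean = params$preserve_mean),
         highpass = highpass(img, params$cutoff_fraction,
                             preserve_mean = params$preserve_mean))
}

#' Rolling-ball background subtraction
#'
#' The background is the grayscale morphological opening of the image
#' with a flat disk of the given radius (erosion then dilation); the
#' corrected image is `image - background`, plus the original mean when
#' `preserve_mean`.  Structures smaller than the disk survive; smooth
#' illumination gradients whose scale exceeds the radius are removed.
#' With `light_background` the opening is applied to the inverted image
#' (the classic variant for dark structures on a light ground).
#'
#' @param img grey-level matrix.
#' @param radius_px disk radius in pixels (>= 1).
#' @param preserve_mean restore the original mean.
#' @param light_background operate on the inverted image.
#' @return corrected image, clipped to the bit-depth range.
#' @export
rolling_ball <- function(img, radius_px, preserve_mean = TRUE,
                         light_background = FALSE) {
  if (radius_px < 1) config_error("radius_px must be >= 1")
  bd <- image_depth(img)
  radius_px <- round(radius_px)
  if (radius_px > nrow(img) && radius_px > ncol(img)) {
    warning("rolling-ball radius exceeds both image dimensions; ",
            "subtracting the global minimum instead")
    out <- img - min(img)
    if (preserve_mean) out <- out + mean(img) - mean(out)
    return(em_image(clip_range(out, bd), bd))
  }
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  work <- if (light_background) -m else m
  bg <- disk_dilate(disk_erode(work, radius_px), radius_px)
  bg <- if (light_background) -bg else bg
  out <- m - bg
  if (preserve_mean) out <- out + mean(m) - mean(out)
  em_image(clip_range(out, bd), bd)
}

poly_design <- function(h, w, degree) {
  u <- rep(seq(-1, 1, length.out = w), each = h)
  v <- rep(seq(-1, 1, length.out = h), w)
  cols <- list()
  for (d in 0:degree) for (i in 0:d)
    cols[[length(cols) + 1]] <- u^(d - i) * v^i
  do.call(cbind, cols)
}

#' Polynomial shading correction
#'
#' Fits a 2-D polynomial surface of the given total degree to the image
#' by least squares and subtracts it (mean restored when
#' `preserve_mean`).
#'
#' @param img grey-level matrix.
#' @param degree total degree, 0--4.
#' @param preserve_mean restore the original mean.
#' @return corrected image; the fitted surface is attached as the
#'   `surface` attribute for inspection.
#' @export
polynomial_flatfield <- function(img, degree = 2, preserve_mean = TRUE) {
  if (degree < 0 || degree > 4 || degree != round(degree))
    config_error("polynomial degree must be an integer in [0, 4]")
  bd <- image_depth(img)
  h <- nrow(img); w <- ncol(img)
  X <- poly_design(h, w, degree)
  fit <- stats::lm.fit(X, as.vector(img))
  surface <- matrix(X %*% fit$coefficients, h, w)
  out <- img - surface
  if (preserve_mean) out <- out + mean(img) - mean(out)
  out <- em_image(clip_range(out, bd), bd)
  attr(out, "surface") <- surface
  out
}

#' Frequency-domain Gaussian high-pass correction
#'
#' Applies the transfer function `H(f) = 1 - exp(-f^2 / (2 c^2))` in
#' the 2-D Fourier domain, where `f` is the radial frequency in cycles
#' per pixel and `c = cutoff_fraction`.  The DC component (image mean)
#' is restored when `preserve_mean`.
#'
#' @param img grey-level matrix.
#' @param cutoff_fraction normalized cutoff in (0, 0.5).
#' @param preserve_mean restore the mean (DC) after filtering.
#' @return corrected image, clipped to the bit-depth range.
#' @export
highpass <- function(img, cutoff_fraction, preserve_mean = TRUE) {
  if (cutoff_fraction <= 0 || cutoff_fraction >= 0.5)
    config_error("cutoff_fraction must be in (0, 0.5)")
  bd <- image_depth(img)
  h <- nrow(img); w <- ncol(img)
  fy <- (0:(h - 1)) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (0:(w - 1)) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  f2 <- outer(fy^2, fx^2, `+`)
  H <- 1 - exp(-f2 / (2 * cutoff_fraction^2))
  F <- fft(matrix(as.numeric(img), h, w))
  out <- Re(fft(F * H, inverse = TRUE)) / (h * w)
  if (preserve_mean) out <- out + mean(img)
  em_image(clip_range(out, bd), bd)
}

#' Analytic transfer-function value of [highpass()]
#'
#' Gain applied to a pure sinusoid of the given normalized frequency.
#'
#' @param freq radial frequency in cycles per pixel.
#' @param cutoff_fraction as in [highpass()].
#' @return gain in `[0, 1]`.
#' @export
highpass_gain <- function(freq, cutoff_fraction) {
  1 - exp(-freq^2 / (2 * cutoff_fraction^2))
}
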