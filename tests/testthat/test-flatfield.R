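# Texture-only phantom: blob- and membrane-free content keeps the
# low-order image content orthogonal to the injected shading, so the
# correction can be judged against the injection alone.
make_shaded_tile <- function(seed = 4, amplitude = 0.2, tile_px = 192) {
  ph <- make_phantom(phantom_spec(448, 448, n_blobs = 0,
                                  membrane_density = 0, texture_sigma = 8,
                                  seed = 1))
  m <- slice_tiles(ph, slice_spec(2, 2, tile_px = tile_px,
                                  overlap_fraction = 0.3,
                                  shading_amplitude = amplitude,
                                  seed = seed))
  m$tiles[[1]]
}

test_that("rolling ball leaves a constant image constant", {
  img <- emmosaic:::em_image(matrix(120, 64, 64), 8L)
  out <- rolling_ball(img, 8)
  expect_true(all(out == 120))
})

test_that("rolling ball removes a large-scale ramp but keeps texture", {
  # texture + planar ramp whose scale far exceeds the radius: output
  # standard deviation within 10% of the texture-only sd (oracle: the
  # texture layer kept by the fixtures module)
  ph <- test_phantom()
  tex <- attr(ph, "texture")[1:192, 1:192]
  ramp <- outer(seq(0, 60, length.out = 192), rep(1, 192))
  img <- emmosaic:::em_image(round(120 + tex + ramp), 8L)
  out <- rolling_ball(img, 12, light_background = TRUE)
  expect_lt(abs(sd(out) - sd(round(tex))) / sd(round(tex)), 0.10)
})

test_that("rolling ball is idempotent within one grey level", {
  t <- make_shaded_tile()
  once <- rolling_ball(t$pixels, 24)
  twice <- rolling_ball(once, 24)
  expect_lt(max(abs(twice - once)), 1)
})

test_that("oversized rolling-ball radius degrades to minimum subtraction", {
  img <- emmosaic:::em_image(matrix(c(10, 20, 30, 40), 2, 2), 8L)
  expect_warning(out <- rolling_ball(img, 100, preserve_mean = FALSE),
                 "global minimum")
  expect_equal(as.vector(out), c(0, 10, 20, 30))
})

test_that("degree-0 polynomial flatfield subtracts the mean", {
  set.seed(21)
  img <- emmosaic:::em_image(matrix(sample(50:200, 64 * 64, TRUE), 64), 8L)
  out <- polynomial_flatfield(img, 0, preserve_mean = FALSE)
  expect_equal(as.vector(out), as.vector(pmax(img - mean(img), 0)),
               tolerance = 1e-9)
})

test_that("an exact quadratic surface is removed to numerical zero", {
  u <- seq(-1, 1, length.out = 96)
  surf <- 100 + outer(30 * u^2, rep(1, 96)) + outer(u * 20, u)
  img <- emmosaic:::em_image(surf, 8L)
  out <- polynomial_flatfield(img, 2, preserve_mean = FALSE)
  expect_lt(max(abs(out)) / 255, 1e-6)
})

test_that("polynomial flatfield recovers the injected shading surface", {
  t <- make_shaded_tile(seed = 5)
  out <- polynomial_flatfield(t$pixels, 2)
  fitted <- attr(out, "surface") - mean(attr(out, "surface"))
  injected <- t$truth$shading
  # RMS within 2% of the injected peak-to-peak amplitude
  span <- max(injected) - min(injected)
  expect_lt(sqrt(mean((fitted - injected)^2)) / span, 0.02)
})

test_that("highpass passes a constant through and preserves the mean", {
  img <- emmosaic:::em_image(matrix(77, 64, 64), 8L)
  expect_true(all(highpass(img, 0.05) == 77))
  set.seed(22)
  noisy <- emmosaic:::em_image(
    matrix(round(rnorm(64 * 64, 128, 10)), 64), 8L)
  expect_equal(mean(highpass(noisy, 0.05)), mean(noisy), tolerance = 1e-9)
})

test_that("highpass attenuates a low-frequency sinusoid per the analytic gain", {
  n <- 256
  f <- 2 / n  # 2 cycles per image, far below the 0.05 cutoff
  wave <- 40 * sin(2 * pi * f * (0:(n - 1)))
  img <- emmosaic:::em_image(128 + outer(rep(1, n), wave), 8L)
  out <- highpass(img, 0.05)  # preserve_mean keeps values off the clip rails
  measured <- (max(out) - min(out)) / (max(img) - min(img))
  expect_lt(measured, 0.1)  # > 90% attenuation
  expect_equal(measured, highpass_gain(f, 0.05), tolerance = 0.02)
})

test_that("all methods cut shading-band energy >= 80% and keep detail within 10%", {
  t <- make_shaded_tile(seed = 8, amplitude = 0.25)
  corrupted <- matrix(as.numeric(t$pixels), nrow(t$pixels))
  # shading band: below 4 cycles per tile; detail band: above 0.1 c/px
  n <- nrow(corrupted)
  lo <- function(img) radial_band_energy(img, 0, 4 / n)
  hi <- function(img) radial_band_energy(img, 0.1, 0.5)
  methods <- list(
    rolling_ball = function(x) rolling_ball(x, round(n / 8)),
    polynomial = function(x) polynomial_flatfield(x, 2),
    highpass = function(x) highpass(x, 0.02))
  for (nm in names(methods)) {
    corrected <- methods[[nm]](t$pixels)
    expect_lt(lo(corrected) / lo(corrupted), 0.20, label = nm)
    expect_lt(abs(hi(corrected) - hi(corrupted)) / hi(corrupted), 0.10,
              label = nm)
    expect_false(anyNA(corrected))
    expect_identical(dim(corrected), dim(t$pixels))
    expect_true(all(corrected >= 0 & corrected <= 255))
  }
})

test_that("corrections are shift-equivariant away from boundaries", {
  ph <- test_phantom()
  img <- emmosaic:::em_image(ph[1:160, 1:160], 8L)
  # rolling ball is local: interior of f(crop) equals crop of f(image)
  r <- 10
  full <- rolling_ball(img, r, preserve_mean = FALSE)
  crop <- rolling_ball(emmosaic:::em_image(ph[21:140, 21:140], 8L), r,
                       preserve_mean = FALSE)
  inner <- 31:90  # > r away from every crop edge
  expect_equal(full[20 + inner, 20 + inner], crop[inner, inner],
               tolerance = 1e-9, ignore_attr = TRUE)
  # the frequency-domain filter commutes with circular shifts exactly
  sh <- function(m, k) m[c((k + 1):nrow(m), 1:k), c((k + 1):ncol(m), 1:k)]
  hp <- highpass(img, 0.03, preserve_mean = FALSE)
  hp_sh <- highpass(emmosaic:::em_image(sh(ph[1:160, 1:160], 13), 8L),
                    0.03, preserve_mean = FALSE)
  expect_equal(as.vector(sh(matrix(as.numeric(hp), 160), 13)),
               as.vector(hp_sh), tolerance = 1e-6)
})

test_that("flatfield_params validates its method-specific fields", {
  expect_error(flatfield_params("polynomial", degree = 7),
               class = "emmosaic_config_error")
  expect_error(flatfield_params("highpass", cutoff_fraction = 0.7),
               class = "emmosaic_config_error")
  expect_error(flatfield_params("rolling_ball", radius_px = 0),
               class = "emmosaic_config_error")
  p <- flatfield_params("polynomial", degree = 3)
  t <- make_shaded_tile()
  expect_identical(dim(apply_flatfield(t$pixels, p)), dim(t$pixels))
})
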