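two_tile_layout <- function(tile_px = 128, overlap = 0.3) {
  step <- round(tile_px * (1 - overlap))
  mosaic_layout(data.frame(id = c("r0_c0", "r0_c1"), row = c(0L, 0L),
                           col = c(0L, 1L), x = c(0, step), y = c(0, 0)),
                tile_px, tile_px)
}

test_that("seam_path with zero roughness is the straight band midline", {
  sp <- seam_spec(roughness_px = 0, step_px = 4, seed = 1)
  poly <- seam_path(c(90, 0, 128, 128), "vertical", sp)
  expect_true(all(poly[, 1] == 109))
  expect_equal(range(poly[, 2]), c(0, 128))
  expect_true(all(diff(poly[, 2]) > 0))  # monotonic along the axis
})

test_that("seam_path is deterministic per seed", {
  sp <- seam_spec(roughness_px = 8, step_px = 4, seed = 42)
  p1 <- seam_path(c(90, 0, 128, 256), "vertical", sp)
  p2 <- seam_path(c(90, 0, 128, 256), "vertical", sp)
  expect_identical(p1, p2)
  p3 <- seam_path(c(90, 0, 128, 256), "vertical",
                  seam_spec(roughness_px = 8, step_px = 4, seed = 43))
  expect_false(identical(p1, p3))
})

test_that("seam excursions stay within roughness and average out", {
  # empirical check of the bounded reflected walk over many seams
  sp0 <- seam_spec(roughness_px = 10, step_px = 2)
  devs <- unlist(lapply(1:200, function(s) {
    sp <- sp0; sp$seed <- s
    poly <- seam_path(c(50, 0, 150, 400), "vertical", sp)
    poly[, 1] - 100
  }))
  expect_lte(max(abs(devs)), 10)
  expect_lt(abs(mean(devs)), 1)
})

test_that("a too-narrow band degrades to a straight midline with warning", {
  sp <- seam_spec(roughness_px = 20, step_px = 4)
  expect_warning(poly <- seam_path(c(100, 0, 120, 64), "vertical", sp),
                 "too narrow")
  expect_true(all(poly[, 1] == 110))
})

test_that("feathered masks are an exact partition of unity", {
  ph <- test_phantom()
  m <- slice_tiles(ph, slice_spec(2, 2, tile_px = 128,
                                  overlap_fraction = 0.3, jitter_px = 4,
                                  seed = 11))
  seams <- montage_seams(m$truth, seam_spec(roughness_px = 8,
                                            feather_px = 12, seed = 2))
  masks <- feather_masks(m$truth, seams, 12)
  H <- masks$canvas_height; W <- masks$canvas_width
  total <- matrix(0, H, W)
  for (mk in masks$masks) {
    ys <- (mk$y0 + 1):(mk$y0 + nrow(mk$weights))
    xs <- (mk$x0 + 1):(mk$x0 + ncol(mk$weights))
    ky <- ys >= 1 & ys <= H; kx <- xs >= 1 & xs <= W
    total[ys[ky], xs[kx]] <- total[ys[ky], xs[kx]] +
      mk$weights[ky, kx, drop = FALSE]
  }
  set.seed(1)
  covered <- which(total > 0)
  sample_px <- sample(covered, min(10000, length(covered)))
  expect_true(all(abs(total[sample_px] - 1) < 1e-6))
})

test_that("mask ramp follows the signed distance to the seam polyline", {
  # oracle: exact point-to-segment distance scan
  layout <- two_tile_layout()
  sp <- seam_spec(roughness_px = 6, step_px = 4, feather_px = 10,
                  seed = 3)
  seams <- montage_seams(layout, sp)
  masks <- feather_masks(layout, seams, 10)
  seam <- seams[[1]]
  mk <- masks$masks[["r0_c0"]]
  set.seed(2)
  for (i in 1:60) {
    x <- sample(80:120, 1); y <- sample(5:123, 1)  # canvas coords
    d <- oracle_polyline_distance(x, y, seam$poly)
    xs <- approx(seam$poly[, 2], seam$poly[, 1], xout = y, rule = 2,
                 ties = "ordered")$y
    signed <- d * sign(xs - x)
    want <- min(max(0.5 + signed / 20, 0), 1)
    got <- mk$weights[y - mk$y0 + 1, x - mk$x0 + 1]
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("pixel (%d,%d)", x, y))
  }
})

test_that("zero feather gives binary masks with an irregular edge", {
  layout <- two_tile_layout()
  seams <- montage_seams(layout, seam_spec(roughness_px = 6,
                                           feather_px = 0, seed = 4))
  masks <- feather_masks(layout, seams, 0)
  w <- unlist(lapply(masks$masks, `[[`, "weights"))
  expect_true(all(w %in% c(0, 0.5, 1)))
  # irregular: the boundary column varies along the seam
  mk <- masks$masks[["r0_c0"]]
  edge_col <- apply(mk$weights, 1, function(r) sum(r > 0.5))
  expect_gt(length(unique(edge_col)), 1)
})

test_that("composite of a single tile is the tile, bit-exactly", {
  ph <- test_phantom()
  m <- slice_tiles(ph, slice_spec(1, 1, tile_px = 128,
                                  overlap_fraction = 0.3))
  masks <- feather_masks(m$truth, montage_seams(m$truth, seam_spec()), 10)
  out <- composite(m$tiles, m$truth, masks)
  expect_identical(as.vector(out), as.vector(m$tiles[[1]]$pixels))
})

test_that("identical overlap content composites to the shared values", {
  ph <- test_phantom()
  m <- slice_tiles(ph, slice_spec(1, 2, tile_px = 128,
                                  overlap_fraction = 0.3, seed = 5))
  seams <- montage_seams(m$truth, seam_spec(roughness_px = 6,
                                            feather_px = 15, seed = 5))
  masks <- feather_masks(m$truth, seams, 15)
  out <- composite(m$tiles, m$truth, masks)
  expect_identical(as.vector(out),
                   as.vector(ph[1:nrow(out), 1:ncol(out)]))
  hard <- hard_composite(m$tiles, m$truth)
  expect_identical(as.vector(hard), as.vector(out))
})

test_that("feathering bounds the seam gradient of a brightness step", {
  # dI = 20 over feather 40: gradient <= dI/(2*40) + 1 grey level/px
  r <- brightness_mismatch_metrics(delta = 20, feather_px = 40, seed = 7)
  expect_lte(r$feathered, 20 / 80 + 1)
  expect_equal(r$hard, 20)  # the hard composite steps by exactly dI
  expect_lt(r$feathered, r$hard)
})

test_that("hard composite shows the step; feathered conceals it, per seed", {
  for (seed in 1:5) {
    r <- brightness_mismatch_metrics(delta = 20, feather_px = 40,
                                     seed = seed)
    expect_lt(r$feathered, r$hard, label = sprintf("seed %d", seed))
    expect_lte(r$feathered, r$bound, label = sprintf("seed %d", seed))
  }
})

test_that("seam_step_metric is 0 on a constant mosaic", {
  layout <- two_tile_layout()
  seams <- montage_seams(layout, seam_spec(seed = 1))
  expect_equal(seam_step_metric(matrix(57, layout$canvas_height,
                                       layout$canvas_width), seams), 0)
})

test_that("composite fills coverage holes with a warning", {
  t1 <- em_tile(matrix(100, 64, 64), 0, 0, nominal_overlap = 0.3)
  layout <- mosaic_layout(data.frame(id = "r0_c0", row = 0L, col = 0L,
                                     x = 0, y = 0), 80, 80)  # larger canvas
  masks <- structure(list(masks = list(r0_c0 = list(
    weights = matrix(1, 64, 64), x0 = 0, y0 = 0)),
    canvas_width = 80, canvas_height = 80, feather_px = 0),
    class = "alpha_masks")
  expect_warning(out <- composite(list(t1), layout, masks), "uncovered")
  expect_equal(dim(out), c(80, 80))
  expect_equal(out[70, 70], 100)  # background = median tile mean
})

test_that("crop_mosaic trims to the fully covered interior", {
  ph <- test_phantom()
  m <- slice_tiles(ph, slice_spec(2, 2, tile_px = 128,
                                  overlap_fraction = 0.3, jitter_px = 4,
                                  seed = 12))
  seams <- montage_seams(m$truth, seam_spec(feather_px = 10, seed = 1))
  masks <- feather_masks(m$truth, seams, 10)
  out <- suppressWarnings(composite(m$tiles, m$truth, masks))
  cropped <- crop_mosaic(out, m$truth)
  cr <- attr(cropped, "crop")
  p <- m$truth$positions
  expect_gte(cr[["x0"]], 0)
  expect_lte(cr[["x1"]], ncol(out))
  expect_equal(cr[["x0"]], ceiling(max(p$x[p$col == 0])))
})
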