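grid_tiles <- function(phantom, rows, cols, tile_px = 128, jitter = 0,
                       noise = 0, shading = 0, seed = 1) {
  m <- slice_tiles(phantom, slice_spec(rows, cols, tile_px = tile_px,
                                       overlap_fraction = 0.3,
                                       jitter_px = jitter,
                                       shading_amplitude = shading,
                                       noise_sigma = noise, seed = seed))
  m$by_id <- stats::setNames(m$tiles, vapply(m$tiles, function(t) t$id, ""))
  m
}

test_that("a self-copied overlap recovers the nominal offset with score 1", {
  ph <- test_phantom()
  tile_a <- em_tile(ph[1:128, 1:128], 0, 0, nominal_overlap = 0.3)
  step <- round(128 * 0.7)
  tile_b <- em_tile(ph[1:128, (step + 1):(step + 128)], 0, 1,
                    nominal_overlap = 0.3)
  o <- estimate_pair_offset(tile_a, tile_b, "right")
  expect_identical(o$status, "accepted")
  expect_equal(o$dx_px, step)
  expect_equal(o$dy_px, 0)
  expect_equal(o$score, 1, tolerance = 1e-9)
})

test_that("injected integer jitter (+7, -3) is recovered exactly", {
  # oracle: exhaustive NCC over all integer shifts in the search window
  ph <- test_phantom()
  step <- round(128 * 0.7)
  a <- em_tile(ph[101:228, 101:228], 0, 0, nominal_overlap = 0.3)
  # b placed at (step + 7, -3) relative to a
  b <- em_tile(ph[(101 - 3):(228 - 3), (101 + step + 7):(228 + step + 7)],
               0, 1, nominal_overlap = 0.3)
  o <- estimate_pair_offset(a, b, "right", search_px = 12,
                            subpixel = FALSE)
  oracle <- oracle_ncc_argmax(a, b, "right", 12)
  expect_identical(o$status, "accepted")
  expect_equal(c(o$dx_px, o$dy_px), c(step + 7, -3))
  expect_equal(c(oracle$dx, oracle$dy), c(step + 7, -3))
})

test_that("featureless overlaps are rejected with the nominal offset", {
  flat <- em_tile(matrix(100, 128, 128), 0, 0, nominal_overlap = 0.3)
  flat2 <- em_tile(matrix(100, 128, 128), 0, 1, nominal_overlap = 0.3)
  o <- estimate_pair_offset(flat, flat2, "right")
  expect_identical(o$status, "rejected")
  expect_equal(o$dx_px, round(128 * 0.7))
  expect_equal(o$dy_px, 0)
  expect_equal(o$score, 0)
})

test_that("offsets are invariant to a constant intensity shift", {
  ph <- test_phantom()
  m <- grid_tiles(ph, 1, 2, jitter = 4, noise = 3, seed = 5)
  o1 <- estimate_pair_offset(m$by_id$r0_c0, m$by_id$r0_c1, "right")
  shifted <- lapply(m$tiles, function(t) {
    t$pixels <- emmosaic:::em_image(pmin(t$pixels + 30, 255), 8L)
    t
  })
  o2 <- estimate_pair_offset(shifted[[1]], shifted[[2]], "right")
  expect_equal(c(o1$dx_px, o1$dy_px), c(o2$dx_px, o2$dy_px),
               tolerance = 0.05)
})

test_that("phase-correlation integer peak equals exhaustive NCC argmax", {
  # property over seeds on small (<= 64 px) overlap strips
  ph <- test_phantom()
  for (seed in 1:5) {
    m <- grid_tiles(ph[1:260, 1:260], 2, 2, tile_px = 64, jitter = 4,
                    noise = 3, seed = seed)
    for (pr in list(c("r0_c0", "r0_c1", "right"),
                    c("r1_c0", "r1_c1", "right"),
                    c("r0_c0", "r1_c0", "below"),
                    c("r0_c1", "r1_c1", "below"))) {
      pc <- estimate_pair_offset(m$by_id[[pr[1]]], m$by_id[[pr[2]]],
                                 pr[3], search_px = 8, subpixel = FALSE)
      oracle <- oracle_ncc_argmax(m$by_id[[pr[1]]], m$by_id[[pr[2]]],
                                  pr[3], 8)
      expect_equal(c(pc$peak_dx_px, pc$peak_dy_px),
                   c(oracle$dx, oracle$dy),
                   label = sprintf("seed %d pair %s-%s", seed,
                                   pr[1], pr[2]))
    }
  }
})

test_that("solve_layout handles the degenerate single tile", {
  l <- solve_layout(list(), 1, 1, 256, 256)
  expect_equal(l$positions$x, 0)
  expect_equal(l$positions$y, 0)
  expect_equal(c(l$canvas_width, l$canvas_height), c(256, 256))
})

test_that("a consistent offset chain yields cumulative positions", {
  po <- function(a, b, dx, dy, rel) structure(
    list(a = a, b = b, relation = rel, dx_px = dx, dy_px = dy,
         score = 1, status = "accepted"), class = "pair_offset")
  offs <- list(po("r0_c0", "r0_c1", 100, 2, "right"),
               po("r0_c1", "r0_c2", 98, -1, "right"))
  l <- solve_layout(offs, 1, 3, 128, 128)
  expect_equal(l$positions$x, c(0, 100, 198), tolerance = 1e-8)
  expect_equal(l$positions$y - min(l$positions$y), c(0, 2, 1),
               tolerance = 1e-8)
  res <- attr(l, "residuals")
  expect_lt(max(abs(c(res$dx, res$dy))), 1e-8)
})

test_that("2x2 square with one perturbed edge matches the normal equations", {
  # oracle: solve the weighted normal equations of the 4-node system
  po <- function(a, b, dx, dy, rel) structure(
    list(a = a, b = b, relation = rel, dx_px = dx, dy_px = dy,
         score = 1, status = "accepted"), class = "pair_offset")
  offs <- list(po("r0_c0", "r0_c1", 100, 0, "right"),
               po("r1_c0", "r1_c1", 101, 0, "right"),  # +1 px perturbed
               po("r0_c0", "r1_c0", 0, 100, "below"),
               po("r0_c1", "r1_c1", 0, 100, "below"))
  l <- solve_layout(offs, 2, 2, 128, 128)
  # tile index order r0_c0, r0_c1, r1_c0, r1_c1
  edges <- list(list(i = 1, j = 2, d = 100, w = 1),
                list(i = 3, j = 4, d = 101, w = 1),
                list(i = 1, j = 3, d = 0, w = 1),
                list(i = 2, j = 4, d = 0, w = 1))
  expected_x <- oracle_solve_positions(edges, 4)
  expect_equal(l$positions$x, expected_x - min(expected_x),
               tolerance = 1e-6)
  # brute force on the 4-node cycle: the 1 px inconsistency spreads
  # equally over the four equally weighted edges, 0.25 px each
  oracle_res <- max(abs(vapply(edges, function(e)
    expected_x[e$j] - expected_x[e$i] - e$d, 0)))
  expect_equal(oracle_res, 0.25, tolerance = 1e-8)
  res <- attr(l, "residuals")
  expect_equal(max(abs(res$dx)), oracle_res, tolerance = 1e-6)
})

test_that("a disconnected adjacency graph is a configuration error", {
  po <- structure(list(a = "r0_c0", b = "r0_c1", relation = "right",
                       dx_px = 100, dy_px = 0, score = 1,
                       status = "accepted"), class = "pair_offset")
  expect_error(solve_layout(list(po), 1, 3, 128, 128),
               class = "emmosaic_config_error")
})

test_that("zero-jitter montage stitches to the exact nominal grid", {
  ph <- test_phantom()
  m <- grid_tiles(ph, 3, 3, seed = 2)
  r <- stitch(m$tiles)
  step <- round(128 * 0.7)
  expect_equal(r$layout$positions$x, r$layout$positions$col * step,
               tolerance = 1e-6)
  expect_equal(r$layout$positions$y, r$layout$positions$row * step,
               tolerance = 1e-6)
})

test_that("a featureless tile falls back to nominal without crashing", {
  ph <- test_phantom()
  m <- grid_tiles(ph, 2, 2, jitter = 3, seed = 3)
  m$tiles[[4]]$pixels <- emmosaic:::em_image(matrix(128, 128, 128), 8L)
  r <- stitch(m$tiles)
  touching <- Filter(function(o) o$a == "r1_c1" || o$b == "r1_c1",
                     r$offsets)
  expect_true(all(vapply(touching, `[[`, "", "status") == "rejected"))
  expect_equal(nrow(r$layout$positions), 4)
})

test_that("incomplete grids are rejected", {
  ph <- test_phantom()
  m <- grid_tiles(ph, 2, 2)
  expect_error(stitch(m$tiles[1:3]), class = "emmosaic_config_error")
})

test_that("positions are recovered within 0.5 px across seeds", {
  ph <- test_phantom()
  for (seed in 1:3) {
    m <- grid_tiles(ph, 2, 2, jitter = 5, noise = 5, shading = 0.2,
                    seed = seed)
    r <- stitch(m$tiles,
                flatfield = flatfield_params("polynomial", degree = 2))
    expect_lt(layout_error(r$layout, m$truth)$max, 0.5,
              label = sprintf("seed %d", seed))
  }
})

test_that("write_layout emits the plain-text table and JSON positions", {
  ph <- test_phantom()
  m <- grid_tiles(ph, 2, 2)
  r <- stitch(m$tiles)
  base <- file.path(withr::local_tempdir(), "layout")
  write_layout(r$layout, base, r$offsets)
  tab <- read.delim(paste0(base, ".txt"))
  expect_identical(names(tab), c("id", "x", "y", "score"))
  expect_equal(nrow(tab), 4)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$positions$x, r$layout$positions$x, tolerance = 1e-6)
})
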