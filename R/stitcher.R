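## Pairwise translation estimation and global montage layout.
##
## The model is translation-only: each tile has an unknown (x, y) on a
## common canvas, pairwise offsets between grid neighbours are measured
## by windowed phase correlation over the nominal overlap strips, and
## the montage is solved as one weighted linear least-squares problem.
## Inhomogeneous elastic deformation of sections is out of scope and
## delegated to specialist alignment tools.

#' Construct a montage tile
#'
#' @param pixels grey-level matrix.
#' @param row,col 0-based grid indices.
#' @param nominal_overlap nominal overlap fraction between neighbours.
#' @param pixel_size_nm physical pixel size (nm per pixel, > 0).
#' @param bit_depth 8 or 16.
#' @param truth optional ground-truth list (fixtures only).
#' @return an `em_tile` object.
#' @export
em_tile <- function(pixels, row, col, nominal_overlap = 0.3,
                    pixel_size_nm = 2, bit_depth = NULL, truth = NULL) {
  stopifnot(is.matrix(pixels))
  if (pixel_size_nm <= 0) config_error("pixel_size_nm must be > 0")
  if (row < 0 || col < 0) config_error("grid indices are 0-based, >= 0")
  bd <- if (is.null(bit_depth)) image_depth(pixels) else as.integer(bit_depth)
  structure(list(pixels = em_image(pixels, bd),
                 row = as.integer(row), col = as.integer(col),
                 id = sprintf("r%d_c%d", as.integer(row), as.integer(col)),
                 nominal_overlap = nominal_overlap,
                 pixel_size_nm = pixel_size_nm,
                 bit_depth = bd, truth = truth),
            class = "em_tile")
}

#' @export
print.em_tile <- function(x, ...) {
  cat(sprintf("<em_tile %s: %dx%d px, %d-bit, %.3g nm/px>\n",
              x$id, ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              x$pixel_size_nm))
  invisible(x)
}

#' Construct a mosaic layout
#'
#' Holds absolute tile positions (x rightward, y downward, 0-based
#' pixels) on a common canvas.  When `normalize = TRUE` positions are
#' translated so the minimum is (0, 0).
#'
#' @param positions data.frame with columns `id`, `row`, `col`, `x`, `y`.
#' @param tile_w,tile_h tile dimensions in pixels.
#' @param normalize translate so `min(x) = min(y) = 0`.
#' @return a `mosaic_layout` object with `canvas_width`/`canvas_height`
#'   covering all tiles.
#' @export
mosaic_layout <- function(positions, tile_w, tile_h, normalize = TRUE) {
  stopifnot(is.data.frame(positions),
            all(c("id", "x", "y") %in% names(positions)))
  if (normalize) {
    positions$x <- positions$x - min(positions$x)
    positions$y <- positions$y - min(positions$y)
  }
  structure(list(positions = positions,
                 tile_w = as.integer(tile_w), tile_h = as.integer(tile_h),
                 canvas_width = as.integer(ceiling(max(positions$x) + tile_w)),
                 canvas_height = as.integer(ceiling(max(positions$y) + tile_h))),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("<mosaic_layout: %d tiles, canvas %dx%d>\n",
              nrow(x$positions), x$canvas_width, x$canvas_height))
  invisible(x)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

nominal_pair_offset <- function(tile_w, tile_h, overlap, relation) {
  if (relation == "right")
    c(dx = round(tile_w * (1 - overlap)), dy = 0)
  else
    c(dx = 0, dy = round(tile_h * (1 - overlap)))
}

# Overlap strips under the nominal offset.  With the true offset
# (nominal + e), strip B satisfies B[y, x] = A[y + ey, x + ex].
overlap_strips <- function(a, b, relation, nominal) {
  h <- nrow(a); w <- ncol(a)
  if (relation == "right") {
    dxn <- nominal[["dx"]]
    list(A = a[, (dxn + 1):w, drop = FALSE],
         B = b[, 1:(w - dxn), drop = FALSE])
  } else {
    dyn <- nominal[["dy"]]
    list(A = a[(dyn + 1):h, , drop = FALSE],
         B = b[1:(h - dyn), , drop = FALSE])
  }
}

# Pearson correlation of A and B overlapped at integer shift (ex, ey),
# where B[y, x] corresponds to A[y + ey, x + ex].
shift_correlation <- function(A, B, ex, ey) {
  h <- nrow(A); w <- ncol(A)
  ys <- max(1, 1 - ey):min(h, h - ey)
  xs <- max(1, 1 - ex):min(w, w - ex)
  if (length(ys) < 2 || length(xs) < 2) return(NA_real_)
  va <- A[ys + ey, xs + ex, drop = FALSE]
  vb <- B[ys, xs, drop = FALSE]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  stats::cor(as.vector(va), as.vector(vb))
}

#' Estimate the translation between two adjacent tiles
#'
#' Measures the offset of tile `b` relative to tile `a` (x rightward, y
#' downward) by phase correlation of the mean-subtracted, Hann-windowed
#' nominal overlap strips, restricted to `search_px` around the nominal
#' grid offset, with sub-pixel refinement by quadratic interpolation of
#' the correlation peak.  The score is the Pearson correlation of the
#' overlapping pixels at the integer peak, clamped to `[0, 1]`.  Pairs
#' with a low score or an ambiguous peak are rejected and fall back to
#' the nominal offset (featureless overlaps are rejected, never an
#' error).
#'
#' @param a,b `em_tile` objects, `b` the right or bottom neighbour of `a`.
#' @param relation `"right"` or `"below"`.
#' @param search_px maximum deviation from the nominal offset considered.
#' @param score_threshold minimum acceptable correlation score.
#' @param min_peak_ratio minimum ratio between the phase-correlation
#'   peak and the second-highest peak outside its 3x3 neighbourhood.
#' @param subpixel refine the peak to sub-pixel precision.
#' @return a `pair_offset` record: `a`, `b`, `relation`, `dx_px`,
#'   `dy_px` (the offset used downstream; nominal when rejected),
#'   `peak_dx_px`/`peak_dy_px` (the measured integer correlation peak,
#'   kept even for rejected pairs), `score`, `peak_ratio`, `status`
#'   (`"accepted"` or `"rejected"`).
#' @export
estimate_pair_offset <- function(a, b, relation = c("right", "below"),
                                 search_px = 16, score_threshold = 0.3,
                                 min_peak_ratio = 1.5, subpixel = TRUE) {
  relation <- match.arg(relation)
  stopifnot(inherits(a, "em_tile"), inherits(b, "em_tile"))
  nominal <- nominal_pair_offset(ncol(a$pixels), nrow(a$pixels),
                                 a$nominal_overlap, relation)
  strips <- overlap_strips(a$pixels, b$pixels, relation, nominal)
  A <- strips$A; B <- strips$B
  h <- nrow(A); w <- ncol(A)
  reject <- function(score = 0, ratio = NA_real_,
                     peak_ex = NA_real_, peak_ey = NA_real_) {
    structure(list(a = a$id, b = b$id, relation = relation,
                   dx_px = nominal[["dx"]], dy_px = nominal[["dy"]],
                   peak_dx_px = nominal[["dx"]] + peak_ex,
                   peak_dy_px = nominal[["dy"]] + peak_ey,
                   score = score, peak_ratio = ratio, status = "rejected"),
              class = "pair_offset")
  }
  if (sd(A) == 0 || sd(B) == 0) return(reject())
  win <- outer(hann_window(h), hann_window(w))
  FA <- fft((A - mean(A)) * win)
  FB <- fft((B - mean(B)) * win)
  R <- FA * Conj(FB)
  R <- R / pmax(Mod(R), 1e-12)
  corr <- Re(fft(R, inverse = TRUE)) / (h * w)
  # re-order the circular surface into shift space -s..s and smooth it
  # slightly: under noise the whitened peak splits across neighbouring
  # pixels, and smoothing makes the true peak dominate the ratio test
  s <- min(search_px, floor((min(h, w) - 1) / 2))
  shifts <- -s:s
  sub <- corr[(shifts %% h) + 1, (shifts %% w) + 1, drop = FALSE]
  sub <- gauss_blur(sub, 0.8)
  n <- length(shifts)
  # candidate starts: the strongest local maxima of the phase surface
  # plus the nominal offset; ties broken toward smaller displacement
  disp <- outer(abs(shifts), abs(shifts), `+`)
  ord <- order(-as.vector(sub), as.vector(disp))
  cand <- list(c(0, 0))
  for (idx in ord) {
    iy <- ((idx - 1) %% n) + 1; ix <- ((idx - 1) %/% n) + 1
    e <- c(shifts[ix], shifts[iy])
    if (!any(vapply(cand, function(q) max(abs(q - e)) <= 2, TRUE)))
      cand[[length(cand) + 1]] <- e
    if (length(cand) >= 6) break
  }
  # the phase peaks locate basins; the reported offset maximizes the
  # normalized cross-correlation, found by a hill climb from each start
  ncc_at <- local({
    cache <- new.env(parent = emptyenv())
    function(ex, ey) {
      key <- paste(ex, ey)
      if (is.null(cache[[key]]))
        cache[[key]] <- shift_correlation(A, B, ex, ey)
      cache[[key]]
    }
  })
  climb <- function(start) {
    cur <- start; curv <- ncc_at(cur[1], cur[2])
    if (is.na(curv)) return(NULL)
    for (iter in 1:40) {
      moved <- FALSE
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                     c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
        e2 <- cur + d
        if (max(abs(e2)) > s) next
        v <- ncc_at(e2[1], e2[2])
        if (!is.na(v) && v > curv) { curv <- v; cur <- e2; moved <- TRUE }
      }
      if (!moved) break
    }
    list(e = cur, v = curv)
  }
  basins <- Filter(Negate(is.null), lapply(cand, climb))
  if (length(basins) == 0) return(reject())
  # merge converged basins (within 2 px Chebyshev), keep distinct ones
  vs <- vapply(basins, `[[`, 0, "v")
  basins <- basins[order(-vs, vapply(basins, function(b)
    sum(abs(b$e)), 0))]
  distinct <- list(basins[[1]])
  for (bs in basins[-1]) {
    if (!any(vapply(distinct, function(q) max(abs(q$e - bs$e)) <= 2, TRUE)))
      distinct[[length(distinct) + 1]] <- bs
  }
  ex <- distinct[[1]]$e[1]; ey <- distinct[[1]]$e[2]
  curv <- distinct[[1]]$v
  # ambiguity ratio on the phase surface: dominant peak against the
  # runner-up outside a 5x5 exclusion zone (periodic patterns fail it)
  pbest <- which.max(sub)
  py <- ((pbest - 1) %% n) + 1; px <- ((pbest - 1) %/% n) + 1
  excl <- abs(outer(shifts, rep(1, n)) - shifts[py]) <= 2 &
    abs(outer(rep(1, n), shifts) - shifts[px]) <= 2
  second <- suppressWarnings(max(sub[!excl]))
  ratio <- if (!is.finite(second) || second <= 1e-12) Inf
  else max(sub) / second
  score <- min(max(curv, 0), 1)
  if (score < score_threshold || ratio < min_peak_ratio)
    return(reject(score, ratio, peak_ex = ex, peak_ey = ey))
  fx <- fy <- 0
  if (subpixel) {
    # quadratic interpolation of the NCC surface around its maximum
    cxm <- if (abs(ex - 1) <= s) ncc_at(ex - 1, ey) else NA
    cxp <- if (abs(ex + 1) <= s) ncc_at(ex + 1, ey) else NA
    cym <- if (abs(ey - 1) <= s) ncc_at(ex, ey - 1) else NA
    cyp <- if (abs(ey + 1) <= s) ncc_at(ex, ey + 1) else NA
    if (!anyNA(c(cxm, cxp))) {
      den <- cxm - 2 * curv + cxp
      if (den < 0) fx <- 0.5 * (cxm - cxp) / den
    }
    if (!anyNA(c(cym, cyp))) {
      den <- cym - 2 * curv + cyp
      if (den < 0) fy <- 0.5 * (cym - cyp) / den
    }
    fx <- min(max(fx, -0.5), 0.5); fy <- min(max(fy, -0.5), 0.5)
  }
  structure(list(a = a$id, b = b$id, relation = relation,
                 dx_px = nominal[["dx"]] + ex + fx,
                 dy_px = nominal[["dy"]] + ey + fy,
                 peak_dx_px = nominal[["dx"]] + ex,
                 peak_dy_px = nominal[["dy"]] + ey,
                 score = score, peak_ratio = ratio, status = "accepted"),
            class = "pair_offset")
}

#' Exhaustive normalized-cross-correlation offset (independent route)
#'
#' Scans every integer shift within the search window and returns the
#' NCC argmax.  This is the slow, direct counterpart of
#' [estimate_pair_offset()]'s frequency-domain path; the two must agree
#' at the integer peak on well-conditioned overlaps, which the self-test
#' asserts.
#'
#' @inheritParams estimate_pair_offset
#' @return list with `dx_px`, `dy_px` (integers) and `score`.
#' @export
ncc_offset <- function(a, b, relation = c("right", "below"),
                       search_px = 16) {
  relation <- match.arg(relation)
  nominal <- nominal_pair_offset(ncol(a$pixels), nrow(a$pixels),
                                 a$nominal_overlap, relation)
  strips <- overlap_strips(a$pixels, b$pixels, relation, nominal)
  s <- min(search_px, floor((min(dim(strips$A)) - 1) / 2))
  best <- c(NA, NA); best_v <- -Inf; best_disp <- Inf
  for (ey in -s:s) for (ex in -s:s) {
    v <- shift_correlation(strips$A, strips$B, ex, ey)
    if (is.na(v)) next
    d <- abs(ex) + abs(ey)
    if (v > best_v + 1e-12 ||
        (abs(v - best_v) <= 1e-12 && d < best_disp)) {
      best_v <- v; best <- c(ex, ey); best_disp <- d
    }
  }
  if (!is.finite(best_v))
    return(list(dx_px = nominal[["dx"]], dy_px = nominal[["dy"]],
                score = 0, status = "rejected"))
  list(dx_px = nominal[["dx"]] + best[1], dy_px = nominal[["dy"]] + best[2],
       score = min(max(best_v, 0), 1), status = "accepted")
}

#' Solve globally consistent tile positions from pairwise offsets
#'
#' Weighted linear least squares over per-tile positions: each offset
#' contributes the equation `pos(b) - pos(a) = (dx, dy)` with weight
#' equal to its score (rejected pairs get a small epsilon weight and
#' their nominal offset).  The gauge is fixed by anchoring tile (0,0)
#' at the origin; positions are then translated so the minimum is (0,0).
#'
#' @param offsets list of `pair_offset` records.
#' @param rows,cols grid shape.
#' @param tile_w,tile_h tile dimensions in pixels.
#' @param epsilon weight assigned to rejected pairs.
#' @return a `mosaic_layout`; per-edge residuals are attached as the
#'   `residuals` attribute.
#' @export
solve_layout <- function(offsets, rows, cols, tile_w, tile_h,
                         epsilon = 1e-3) {
  n <- rows * cols
  ids <- as.vector(t(outer(0:(rows - 1), 0:(cols - 1),
                           function(r, c) sprintf("r%d_c%d", r, c))))
  grid <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))[, c(2, 1)]
  if (n == 1) {
    return(mosaic_layout(data.frame(id = ids, row = 0L, col = 0L,
                                    x = 0, y = 0),
                         tile_w, tile_h))
  }
  index <- stats::setNames(seq_len(n), ids)
  m <- length(offsets)
  if (m == 0) config_error("no pairwise offsets supplied")
  # connectivity over all edges (rejected ones fall back to nominal)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (o in offsets) {
    i <- index[o$a]; k <- index[o$b]
    if (is.na(i) || is.na(k))
      config_error("offset references unknown tile %s/%s", o$a, o$b)
    adj[[i]] <- c(adj[[i]], k); adj[[k]] <- c(adj[[k]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  if (!all(seen))
    config_error("tile adjacency graph is disconnected (%d of %d reachable)",
                 sum(seen), n)
  A <- matrix(0, m + 1, n)
  bx <- by <- numeric(m + 1)
  wts <- numeric(m + 1)
  for (e in seq_len(m)) {
    o <- offsets[[e]]
    A[e, index[o$a]] <- -1
    A[e, index[o$b]] <- 1
    bx[e] <- o$dx_px; by[e] <- o$dy_px
    wts[e] <- if (identical(o$status, "accepted"))
      max(o$score, epsilon) else epsilon
  }
  A[m + 1, 1] <- 1; wts[m + 1] <- 1e6  # anchor tile (0,0) at the origin
  sw <- sqrt(wts)
  qrA <- qr(A * sw)
  x <- qr.coef(qrA, bx * sw)
  y <- qr.coef(qrA, by * sw)
  res <- data.frame(
    a = vapply(offsets, `[[`, "", "a"),
    b = vapply(offsets, `[[`, "", "b"),
    dx = (A[seq_len(m), , drop = FALSE] %*% x)[, 1] - bx[seq_len(m)],
    dy = (A[seq_len(m), , drop = FALSE] %*% y)[, 1] - by[seq_len(m)])
  layout <- mosaic_layout(data.frame(id = ids, row = grid$row,
                                     col = grid$col, x = x, y = y,
                                     stringsAsFactors = FALSE),
                          tile_w, tile_h)
  attr(layout, "residuals") <- res
  layout
}

#' Stitch a complete tile grid
#'
#' Optionally flat-field corrects every tile, measures every horizontal
#' and vertical adjacency with [estimate_pair_offset()] (logging one
#' record per pair), and solves the global layout.
#'
#' @param tiles list of `em_tile` covering a complete grid.
#' @param flatfield `NULL` or a [flatfield_params()] applied to every
#'   tile before registration (shading biases correlation, so
#'   correction comes first).
#' @param search_px,score_threshold,min_peak_ratio,subpixel passed to
#'   [estimate_pair_offset()].
#' @return list with `layout` (`mosaic_layout`), `offsets` (list of
#'   `pair_offset`) and `tiles` (the corrected tiles actually
#'   registered, for downstream compositing).
#' @export
stitch <- function(tiles, flatfield = NULL, search_px = 16,
                   score_threshold = 0.3, min_peak_ratio = 1.5,
                   subpixel = TRUE) {
  stopifnot(length(tiles) >= 1, all(vapply(tiles, inherits, TRUE, "em_tile")))
  rows <- max(vapply(tiles, function(t) t$row, 0L)) + 1L
  cols <- max(vapply(tiles, function(t) t$col, 0L)) + 1L
  key <- vapply(tiles, function(t) t$id, "")
  want <- as.vector(outer(0:(rows - 1), 0:(cols - 1),
                          function(r, c) sprintf("r%d_c%d", r, c)))
  if (!setequal(key, want) || anyDuplicated(key))
    config_error("incomplete or duplicated tile grid (expected %dx%d)",
                 rows, cols)
  if (!is.null(flatfield)) {
    tiles <- lapply(tiles, function(t) {
      t$pixels <- apply_flatfield(t$pixels, flatfield)
      t
    })
  }
  by_id <- stats::setNames(tiles, key)
  tw <- ncol(tiles[[1]]$pixels); th <- nrow(tiles[[1]]$pixels)
  offsets <- list()
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    a <- by_id[[sprintf("r%d_c%d", r, c)]]
    if (c + 1 < cols) {
      o <- estimate_pair_offset(a, by_id[[sprintf("r%d_c%d", r, c + 1)]],
                                "right", search_px, score_threshold,
                                min_peak_ratio, subpixel)
      offsets[[length(offsets) + 1]] <- o
      log_msg("info", "pair %s->%s [right]: dx=%.2f dy=%.2f score=%.3f %s",
              o$a, o$b, o$dx_px, o$dy_px, o$score, o$status)
    }
    if (r + 1 < rows) {
      o <- estimate_pair_offset(a, by_id[[sprintf("r%d_c%d", r + 1, c)]],
                                "below", search_px, score_threshold,
                                min_peak_ratio, subpixel)
      offsets[[length(offsets) + 1]] <- o
      log_msg("info", "pair %s->%s [below]: dx=%.2f dy=%.2f score=%.3f %s",
              o$a, o$b, o$dx_px, o$dy_px, o$score, o$status)
    }
  }
  layout <- if (length(offsets) == 0)
    solve_layout(list(), rows, cols, tw, th)
  else solve_layout(offsets, rows, cols, tw, th)
  list(layout = layout, offsets = offsets, tiles = by_id[want])
}

#' Position error of a recovered layout against ground truth
#'
#' Both layouts are reduced to positions relative to their own mean
#' (registration can only recover relative placement), matched by tile
#' id, and compared.
#'
#' @param layout recovered `mosaic_layout`.
#' @param truth ground-truth `mosaic_layout`.
#' @return list with `per_tile` (data.frame of dx, dy, err), `mean`,
#'   `max` absolute position error in pixels.
#' @export
layout_error <- function(layout, truth) {
  p <- layout$positions; q <- truth$positions
  q <- q[match(p$id, q$id), ]
  stopifnot(!anyNA(q$id))
  dx <- (p$x - mean(p$x)) - (q$x - mean(q$x))
  dy <- (p$y - mean(p$y)) - (q$y - mean(q$y))
  err <- sqrt(dx^2 + dy^2)
  list(per_tile = data.frame(id = p$id, dx = dx, dy = dy, err = err),
       mean = mean(err), max = max(err))
}

#' Write a layout as a plain-text table plus machine-readable JSON
#'
#' @param layout a `mosaic_layout`.
#' @param path base output path; writes `<path>.txt` (columns id, x, y
#'   and, when offsets are given, the mean score of the edges touching
#'   each tile) and `<path>.json`.
#' @param offsets optional list of `pair_offset` records.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path, offsets = NULL) {
  p <- layout$positions
  score <- rep(NA_real_, nrow(p))
  if (!is.null(offsets) && length(offsets)) {
    for (i in seq_len(nrow(p))) {
      touching <- vapply(offsets, function(o)
        o$a == p$id[i] || o$b == p$id[i], TRUE)
      if (any(touching))
        score[i] <- mean(vapply(offsets[touching], `[[`, 0, "score"))
    }
  }
  tab <- data.frame(id = p$id, x = round(p$x, 3), y = round(p$y, 3),
                    score = round(score, 4))
  utils::write.table(tab, paste0(path, ".txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(positions = p, tile_w = layout$tile_w,
                            tile_h = layout$tile_h,
                            canvas_width = layout$canvas_width,
                            canvas_height = layout$canvas_height),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
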