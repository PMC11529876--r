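# Independent oracles used by the DERIVED-value tests.  These
# deliberately re-derive results by brute force / direct definitions and
# must stay independent of the package code paths they check.

emma_log_level("quiet")

# Connected-component count of a logical mask (4-connected flood fill).
flood_fill_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[p]) next
      seen[p] <- TRUE
      y <- ((p - 1) %% h) + 1; x <- ((p - 1) %/% h) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) {
          q <- (xx - 1) * h + yy
          if (mask[q] && !seen[q]) stack <- c(stack, q)
        }
      }
    }
  }
  count
}

# Direct Pearson NCC of two tiles' overlap at an integer shift, written
# against the same geometric convention as the stitcher but with plain
# loops over the full exhaustive search window.
oracle_ncc_argmax <- function(a, b, relation, search_px) {
  tw <- ncol(a$pixels); th <- nrow(a$pixels)
  ov <- a$nominal_overlap
  if (relation == "right") {
    dxn <- round(tw * (1 - ov)); dyn <- 0
    A <- a$pixels[, (dxn + 1):tw]; B <- b$pixels[, 1:(tw - dxn)]
  } else {
    dxn <- 0; dyn <- round(th * (1 - ov))
    A <- a$pixels[(dyn + 1):th, ]; B <- b$pixels[1:(th - dyn), ]
  }
  h <- nrow(A); w <- ncol(A)
  best <- NULL; bestv <- -Inf
  for (ey in -search_px:search_px) for (ex in -search_px:search_px) {
    ys <- max(1, 1 - ey):min(h, h - ey)
    xs <- max(1, 1 - ex):min(w, w - ex)
    if (length(ys) < 2 || length(xs) < 2) next
    va <- as.vector(A[ys + ey, xs + ex]); vb <- as.vector(B[ys, xs])
    if (sd(va) == 0 || sd(vb) == 0) next
    v <- cor(va, vb)
    if (v > bestv) { bestv <- v; best <- c(dxn + ex, dyn + ey) }
  }
  list(dx = best[1], dy = best[2], value = bestv)
}

# Exact point-to-polyline Euclidean distance (per-vertex segment scan).
oracle_polyline_distance <- function(px, py, poly) {
  best <- Inf
  for (i in seq_len(nrow(poly) - 1)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1, 1]; by <- poly[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else
      min(max(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    best <- min(best, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
  }
  best
}

# Plain 2x2 box downsample with ceiling division (edge blocks average
# the available pixels) -- the independent pyramid-level oracle.
oracle_box_downsample <- function(img) {
  h <- nrow(img); w <- ncol(img)
  H <- ceiling(h / 2); W <- ceiling(w / 2)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ys <- (2 * r - 1):min(2 * r, h)
    xs <- (2 * c - 1):min(2 * c, w)
    out[r, c] <- mean(img[ys, xs])
  }
  out
}

# Least-squares tile positions for a small offset set, solved directly
# from the normal equations with an anchored first tile.
oracle_solve_positions <- function(edges, n) {
  # edges: list of list(i, j, d, w) meaning pos[j] - pos[i] = d
  A <- matrix(0, length(edges) + 1, n)
  b <- numeric(length(edges) + 1)
  wts <- numeric(length(edges) + 1)
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    A[k, e$i] <- -1; A[k, e$j] <- 1; b[k] <- e$d; wts[k] <- e$w
  }
  A[length(edges) + 1, 1] <- 1; wts[length(edges) + 1] <- 1e6
  W <- diag(wts)
  solve(t(A) %*% W %*% A, t(A) %*% W %*% b)[, 1]
}

# Small shared fixtures ---------------------------------------------------

test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_phantom(phantom_spec(512, 512, n_blobs = 12,
                                          membrane_density = 0.4,
                                          texture_sigma = 8, seed = 42))
    cache
  }
})

# Band energy of the Hann-windowed spectrum; without the window the
# non-periodic shading trend leaks into every band and confounds the
# high-frequency comparison.
radial_band_energy <- function(img, f_lo, f_hi) {
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  h <- nrow(img); w <- ncol(img)
  hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  win <- outer(hann(h), hann(w))
  fy <- (0:(h - 1)) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (0:(w - 1)) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  f <- sqrt(outer(fy^2, fx^2, `+`))
  P <- Mod(fft((img - mean(img)) * win))^2
  sum(P[f > f_lo & f <= f_hi])
}
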