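# Independent brute-force oracles used to validate the closed-form /
# histogram-based implementations. These deliberately take the slow, obvious
# route.

# eigenvalues of a symmetric 2x2 matrix via the characteristic polynomial,
# returned ordered by absolute value
eig2_brute <- function(a, b, c) {
  tr <- a + c
  det <- a * c - b * b
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  ev <- c(tr / 2 + disc, tr / 2 - disc)
  ev[order(abs(ev))]
}

# exhaustive Otsu: split the raw pixel values at every candidate bin edge
# and minimize the weighted within-class variance computed on the raw values
otsu_brute <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  cand <- breaks[2:n_bins]
  wcv <- vapply(cand, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * mean((lo - mean(lo))^2) +
       length(hi) * mean((hi - mean(hi))^2)) / length(v)
  }, 0)
  cand[which.min(wcv)]   # which.min takes the first (lowest) minimizer
}

# polygon area by rasterization: even-odd point-in-polygon test on a fine
# grid of cell centers
raster_area <- function(xy, n_grid = 600L) {
  xr <- range(xy[, 1L]); yr <- range(xy[, 2L])
  pad <- 0.01 * max(diff(xr), diff(yr))
  gx <- seq(xr[1L] - pad, xr[2L] + pad, length.out = n_grid)
  gy <- seq(yr[1L] - pad, yr[2L] + pad, length.out = n_grid)
  cell <- (gx[2L] - gx[1L]) * (gy[2L] - gy[1L])
  px <- rep(gx, times = n_grid)
  py <- rep(gy, each = n_grid)
  inside <- rep(FALSE, length(px))
  n <- nrow(xy)
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1L]; yi <- xy[i, 2L]
    xj <- xy[j, 1L]; yj <- xy[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * cell
}

# exact Mann-Whitney p by direct enumeration over index subsets, written
# independently of the package internals
mwu_brute_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- utils::combn(n, n_a)
  us <- apply(idx, 2L, function(ii) sum(r[ii]) - n_a * (n_a + 1) / 2)
  mu <- n_a * length(b) / 2
  sum(abs(us - mu) >= abs(u_obs - mu) - 1e-9) / ncol(idx)
}

# standard small scene: one straight full-span tube through the center
one_tube_scene <- function(angle, s = 2, size = 96, amplitude = 0.8,
                           background = 0.1, noise_sd = 0, seed = 1L) {
  render_scene(scene_spec(size = size,
                          tubes = list(tube(angle, s = s,
                                            amplitude = amplitude)),
                          background = background, noise_sd = noise_sd,
                          seed = seed))
}
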