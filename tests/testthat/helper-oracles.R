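# Independent oracles and tiny fixture builders used across the suite.

# Brute-force Euclidean distance transform: all-pairs nearest background.
brute_distance_map <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(mask == 0, arr.ind = TRUE)
  fg <- which(mask == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    out[p[1], p[2]] <- sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
  }
  out
}

# Brute-force two-sample KS statistic: max ECDF gap over pooled points.
brute_ks_d <- function(x, y) {
  pts <- sort(c(x, y))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Kolmogorov CDF via the Jacobi-theta series — an independent closed form
# for the asymptotic p-value (1 - CDF).
theta_kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  1 - sqrt(2 * pi) / lambda * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
}

# Binary disc mask (pixel centers within r of the given center).
disc_mask <- function(H, W, cr, cc, r) {
  ij <- expand.grid(r = seq_len(H), c = seq_len(W))
  matrix(as.integer((ij$r - cr)^2 + (ij$c - cc)^2 <= r^2), H, W)
}

# Flat-colored RGB frame with optional discs drawn on it, via HSV spec
# (H 0-180, S/V 0-255). Independent of the scene generator.
flat_frame <- function(H, W, bg_hsv = c(100, 10, 45),
                       discs = list()) {
  hm <- matrix(bg_hsv[1], H, W)
  sm <- matrix(bg_hsv[2], H, W)
  vm <- matrix(bg_hsv[3], H, W)
  for (d in discs) {
    sel <- disc_mask(H, W, d$cr, d$cc, d$r) == 1
    hm[sel] <- d$hsv[1]; sm[sel] <- d$hsv[2]; vm[sel] <- d$hsv[3]
  }
  # HSV -> RGB through grDevices, the reference conversion
  col <- grDevices::hsv(pmin(hm / 180, 1) * (360 / 360), sm / 255, vm / 255)
  rgb <- grDevices::col2rgb(col)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- matrix(rgb[1, ], H, W)
  px[, , 2] <- matrix(rgb[2, ], H, W)
  px[, , 3] <- matrix(rgb[3, ], H, W)
  new_frame(px)
}

# HSV array builder for threshold tests.
hsv_array <- function(H, S, V) {
  a <- array(0, c(length(H), 1, 3))
  a[, 1, 1] <- H; a[, 1, 2] <- S; a[, 1, 3] <- V
  a
}

expect_binary_mask <- function(m, frame_dim) {
  expect_true(is.matrix(m))
  expect_identical(dim(m), frame_dim)
  expect_true(all(m %in% c(0L, 1L)))
}
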