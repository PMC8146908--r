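# Minimum enclosing circle of a 2-D point set (Welzl's incremental
# algorithm on the convex hull). Deterministic: instead of a random
# shuffle, hull points are visited in a fixed stride permutation, which
# breaks the adversarial convex ordering equally well and keeps the
# pipeline bit-reproducible.
min_enclosing_circle <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  if (n > 3) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
    n <- nrow(pts)
  }
  perm <- order((seq_len(n) * 7919L) %% n, seq_len(n))
  pts <- pts[perm, , drop = FALSE]

  eps <- 1e-9
  inside <- function(p, c) {
    sqrt((p[1] - c$center[1])^2 + (p[2] - c$center[2])^2) <= c$radius + eps
  }
  circ2 <- function(a, b) {
    ctr <- (a + b) / 2
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  circ3 <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: fall back to the widest pair
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
  }

  cir <- list(center = pts[1, ], radius = 0)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    if (inside(p, cir)) next
    cir <- list(center = p, radius = 0)
    for (j in seq_len(i - 1)) {
      q <- pts[j, ]
      if (inside(q, cir)) next
      cir <- circ2(p, q)
      for (k in seq_len(j - 1)) {
        r <- pts[k, ]
        if (!inside(r, cir)) cir <- circ3(p, q, r)
      }
    }
  }
  cir
}
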