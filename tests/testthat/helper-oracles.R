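# Independent oracles used to pin expected values; kept deliberately naive
# and separate from the package's own code paths.

# quartile tiers by explicit sorting and linear interpolation (type-7 rule
# written out by hand)
oracle_tiers <- function(v) {
  s <- sort(v)
  n <- length(s)
  qs <- vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }, numeric(1))
  list(tiers = (v > qs[1]) + (v > qs[2]) + (v > qs[3]), thresholds = qs)
}

# gift-wrapping (Jarvis march) convex hull; returns point indices in order
gift_wrap <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur || j == cand) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2))) {
        cand <- j
      }
    }
    cur <- cand
    if (cur == start) break
  }
  hull
}

# ray-casting point-in-polygon with boundary tolerance
oracle_in_polygon <- function(p, poly, tol = 1e-9) {
  nv <- nrow(poly)
  px <- p[1]; py <- p[2]
  for (k in seq_len(nv)) {
    a <- poly[k, ]; b <- poly[if (k == nv) 1 else k + 1, ]
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      max(0, min(1, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / sum(ab^2)))
    if (sqrt((px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2) <= tol) return(TRUE)
  }
  inside <- FALSE
  j <- nv
  for (k in seq_len(nv)) {
    if ((poly[k, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[k, 1] + (py - poly[k, 2]) / (poly[j, 2] - poly[k, 2]) *
        (poly[j, 1] - poly[k, 1])
      if (px < xint) inside <- !inside
    }
    j <- k
  }
  inside
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
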