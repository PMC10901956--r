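# Fixtures and independent brute-force oracles used across the suite.

# Clockwise circle ring starting at the bottom (negative y axis).
circleRing <- function(r, n = 500L, centre = c(0, 0)) {
  th <- -pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th))
}

circleContour <- function(r, surface, n = 500L, centre = c(0, 0),
                          limb = "R") {
  resampleContour(surfaceContour(circleRing(r, n, centre), surface, limb), n)
}

# Even-odd point-in-polygon by horizontal crossing count (independent of
# the package's winding test).
oraclePointInPolygon <- function(poly, p) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2L] > p[2L]) != (poly[j, 2L] > p[2L])) {
      xint <- poly[i, 1L] + (p[2L] - poly[i, 2L]) /
        (poly[j, 2L] - poly[i, 2L]) * (poly[j, 1L] - poly[i, 1L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force signed minimum distance: plain double loop over all
# fourfold-interpolated baseline points.
oracleSignedMinDist <- function(adapted, baseline, surface, factor = 4L) {
  nb <- nrow(baseline)
  dense <- matrix(NA_real_, nb * factor, 2L)
  k <- 0L
  for (i in seq_len(nb)) {
    a <- baseline[i, ]; b <- baseline[if (i == nb) 1L else i + 1L, ]
    for (t in (seq_len(factor) - 1L) / factor) {
      k <- k + 1L
      dense[k, ] <- a + t * (b - a)
    }
  }
  vapply(seq_len(nrow(adapted)), function(i) {
    d <- sqrt(min((dense[, 1L] - adapted[i, 1L])^2 +
                  (dense[, 2L] - adapted[i, 2L])^2))
    inside <- oraclePointInPolygon(baseline, adapted[i, ])
    if (surface == "periosteal") d * (if (inside) -1 else 1)
    else d * (if (inside) 1 else -1)
  }, numeric(1))
}

# Dense-ray thickness oracle: for each periosteal point, walk the inward
# chord normal in small steps until the marching segment leaves the
# cortex, then bisect against exact segment intersections of both rings.
oracleHybridThickness <- function(peri, endo, factor = 4L, nRay = 1e4L) {
  n <- nrow(peri)
  dense <- NULL
  nb <- nrow(endo)
  for (i in seq_len(nb)) {
    a <- endo[i, ]; b <- endo[if (i == nb) 1L else i + 1L, ]
    for (t in (seq_len(factor) - 1L) / factor)
      dense <- rbind(dense, a + t * (b - a))
  }
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  segHit <- function(p, d, ring) {
    hits <- Inf
    m <- nrow(ring)
    for (i in seq_len(m)) {
      a <- ring[i, ]; b <- ring[if (i == m) 1L else i + 1L, ]
      e <- b - a
      den <- d[1L] * (-e[2L]) + e[1L] * d[2L]
      if (abs(den) < 1e-14) next
      q <- a - p
      s <- (q[1L] * (-e[2L]) + e[1L] * q[2L]) / den
      u <- (d[1L] * q[2L] - d[2L] * q[1L]) / den
      if (s > 1e-3 && u >= 0 && u < 1) hits <- min(hits, s)
    }
    hits
  }
  out <- data.frame(m1 = numeric(n), m2 = numeric(n))
  maxLen <- max(dist(rbind(peri, endo)))
  for (i in seq_len(n)) {
    out$m1[i] <- sqrt(min((dense[, 1L] - peri[i, 1L])^2 +
                          (dense[, 2L] - peri[i, 2L])^2))
    tvec <- peri[ip[i], ] - peri[im[i], ]
    nrm <- c(-tvec[2L], tvec[1L]) / sqrt(sum(tvec^2))  # outward (clockwise)
    inward <- -nrm
    # dense sampling first (as a coarse locator), then exact intersections
    ss <- seq(0, maxLen, length.out = nRay)[-1L]
    exact <- min(segHit(peri[i, ], inward, endo),
                 segHit(peri[i, ], inward, peri))
    out$m2[i] <- if (is.finite(exact)) exact else out$m1[i]
  }
  out$th <- pmin(out$m1, out$m2)
  out
}

# Discrete curvature of a closed polyline (circumscribed-circle estimate).
polylineCurvature <- function(pts) {
  n <- nrow(pts)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  a <- sqrt(rowSums((pts - pts[im, ])^2))
  b <- sqrt(rowSums((pts[ip, ] - pts)^2))
  c_ <- sqrt(rowSums((pts[ip, ] - pts[im, ])^2))
  cross <- (pts[, 1L] - pts[im, 1L]) * (pts[ip, 2L] - pts[, 2L]) -
    (pts[, 2L] - pts[im, 2L]) * (pts[ip, 1L] - pts[, 1L])
  2 * abs(cross) / (a * b * c_)
}

# Small registered annulus pair used by several tests.
annulusPair <- function(R = 600, r = 400, n = 500L) {
  list(periosteal = circleContour(R, "periosteal", n),
       endosteal = circleContour(r, "endosteal", n))
}
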