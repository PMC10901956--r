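# Internal polygon / polyline geometry helpers.
#
# All coordinates are in micrometres in a y-up frame. Closed polygons are
# stored as n x 2 matrices WITHOUT a repeated first vertex; edges run
# i -> i+1 cyclically. "Clockwise" means decreasing mathematical angle in
# the y-up frame, i.e. negative shoelace signed area.

.closeRing <- function(pts) rbind(pts, pts[1L, , drop = FALSE])

.signedArea <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

.ensureClockwise <- function(pts) {
  if (.signedArea(pts) > 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

.polygonCentroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Raw (origin-referenced) area integrals of one simple polygon, normalised
# to positive orientation: A, first moments Sx = int x dA, Sy = int y dA,
# and second moments about the ORIGIN: Ixx = int y^2 dA, Iyy = int x^2 dA,
# Ixy = int xy dA.
.polygonIntegrals <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  s <- if (a < 0) -1 else 1
  list(
    A   = s * a,
    Sx  = s * sum((x + xn) * cr) / 6,
    Sy  = s * sum((y + yn) * cr) / 6,
    Ixx = s * sum((y * y + y * yn + yn * yn) * cr) / 12,
    Iyy = s * sum((x * x + x * xn + xn * xn) * cr) / 12,
    Ixy = s * sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  )
}

.pointsInPolygon <- function(poly, pts) {
  mgcv::in.out(.closeRing(poly), pts)
}

# Arc-length positions of polygon vertices plus total perimeter.
.arcLengths <- function(pts) {
  d <- sqrt(rowSums((rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts)^2))
  list(seg = d, cum = c(0, cumsum(d)), total = sum(d))
}

# Locate the crossing of the ray x = 0, y < 0 on a closed polyline, i.e. the
# anatomical P = 0 origin. Returns list(edge index, interpolation t, point).
# When several edges cross the negative y axis the most negative y wins.
.negYCrossing <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cand <- which(x * xn <= 0 & !(x == 0 & xn == 0))
  if (length(cand) == 0L) stop("contour never crosses the y axis")
  t <- ifelse(x[cand] == xn[cand], 0, x[cand] / (x[cand] - xn[cand]))
  ycr <- y[cand] + t * (yn[cand] - y[cand])
  neg <- ycr < 0
  if (!any(neg)) stop("contour does not cross the negative y axis")
  k <- which(neg)[which.min(ycr[neg])]
  list(edge = cand[k], t = t[k], point = c(0, ycr[k]))
}

# Resample a closed polyline to n points at uniform arc length, starting at
# the negative-y-axis crossing, preserving the input orientation.
.resampleRing <- function(pts, n) {
  cr <- .negYCrossing(pts)
  m <- nrow(pts)
  idx <- if (cr$edge == m) seq_len(m) else c((cr$edge + 1L):m, seq_len(cr$edge))
  px <- c(cr$point[1L], pts[idx, 1L], cr$point[1L])
  py <- c(cr$point[2L], pts[idx, 2L], cr$point[2L])
  len <- length(px)
  seg <- sqrt((px[-1L] - px[-len])^2 + (py[-1L] - py[-len])^2)
  pos <- seg > 0                     # drop duplicate vertices (t = 0/1 crossings)
  if (!all(pos)) {
    keep <- c(TRUE, pos)
    px <- px[keep]; py <- py[keep]; seg <- seg[pos]
  }
  s <- c(0, cumsum(seg))
  target <- s[length(s)] * (seq_len(n) - 1) / n
  j <- findInterval(target, s, rightmost.closed = TRUE)
  w <- (target - s[j]) / seg[j]
  cbind(px[j] + w * (px[j + 1L] - px[j]), py[j] + w * (py[j + 1L] - py[j]))
}

# Linear densification of a closed polyline: insert `factor - 1` evenly
# spaced points on every edge.
.densifyRing <- function(pts, factor = 4L) {
  n <- nrow(pts)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  t <- (seq_len(factor) - 1L) / factor
  x <- outer(pts[, 1L], rep(1, factor)) + outer(nxt[, 1L] - pts[, 1L], t)
  y <- outer(pts[, 2L], rep(1, factor)) + outer(nxt[, 2L] - pts[, 2L], t)
  cbind(as.vector(t(x)), as.vector(t(y)))
}

# Minimum distance from each query point to a point set, vectorised.
.minDistToSet <- function(query, set) {
  nq <- nrow(query); ns <- nrow(set)
  d2 <- matrix(rowSums(query^2), nq, ns) +
    matrix(rowSums(set^2), nq, ns, byrow = TRUE) -
    2 * tcrossprod(query, set)
  j <- max.col(-d2, ties.method = "first")
  # the Gram expansion above cancels catastrophically near zero distance;
  # recompute the winning pair directly
  sqrt((query[, 1L] - set[j, 1L])^2 + (query[, 2L] - set[j, 2L])^2)
}

.rotationMatrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

.rotatePts <- function(pts, theta, centre = c(0, 0)) {
  sweep(sweep(pts, 2L, centre) %*% t(.rotationMatrix(theta)), 2L, centre, `+`)
}

# First intersection of the ray p + s*dir (s > 0) with a closed polygon.
# Returns the smallest positive s, or Inf when the ray misses.
.rayPolygonHit <- function(p, dir, poly, sMin = 1e-9) {
  a <- poly
  b <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  det <- dir[1L] * (-ey) - dir[2L] * (-ex)
  qx <- a[, 1L] - p[1L]; qy <- a[, 2L] - p[2L]
  ok <- abs(det) > 1e-14
  s <- (qx * (-ey) + ex * qy) / det
  u <- (dir[1L] * qy - dir[2L] * qx) / det
  hit <- ok & s > sMin & u >= 0 & u < 1
  if (!any(hit)) return(Inf)
  min(s[hit])
}
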