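# Pre-processing of binary cross-section slices into registered,
# normalised periosteal/endosteal contours.

#' Otsu binarisation of a grayscale slice
#'
#' Thresholds a grayscale raster at the level maximising between-class
#' variance; the brighter (mineralised) class becomes bone.
#'
#' @param gray numeric matrix of intensities (any range); rows index x,
#'   columns index y.
#' @param pixelSize,origin geometry of the raster, see [binarySlice()].
#' @return a [BinarySlice-class].
#' @export
binarizeOtsu <- function(gray, pixelSize = 9.56, origin = c(0, 0)) {
  rng <- range(gray)
  if (diff(rng) == 0) stop("image is uniform; Otsu threshold undefined")
  g <- (gray - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  binarySlice(g > thr, pixelSize = pixelSize, origin = origin)
}

#' Fill intracortical cavities
#'
#' Sets every background component to bone except the exterior and the
#' largest interior component (the marrow cavity), removing small voids
#' such as vascular canals. After filling, the background has exactly two
#' connected components.
#'
#' @param slice a [BinarySlice-class] whose bone forms one connected
#'   component.
#' @return a filled [BinarySlice-class].
#' @export
fillCavities <- function(slice) {
  g <- sliceGrid(slice)
  lab <- EBImage::bwlabel(!g)
  nx <- nrow(g); ny <- ncol(g)
  border <- unique(c(lab[1L, ], lab[nx, ], lab[, 1L], lab[, ny]))
  border <- setdiff(border, 0L)
  interior <- setdiff(setdiff(unique(as.vector(lab)), 0L), border)
  if (length(interior) == 0L) {
    warning("no interior cavity found; slice returned unchanged")
    return(slice)
  }
  sizes <- vapply(interior, function(k) sum(lab == k), numeric(1))
  marrow <- interior[which.max(sizes)]
  fill <- lab != 0L & !(lab %in% border) & lab != marrow
  g[fill] <- TRUE
  binarySlice(g, pixelSize = pixelSize(slice), origin = slice@origin)
}

#' Extract periosteal and endosteal contours from a binary slice
#'
#' Traces the 0.5-level isocontours of the binary raster (marching squares,
#' sub-pixel linear interpolation between pixel centres). The largest loop
#' is the periosteal envelope, the marrow boundary the endosteal one.
#'
#' @param slice a cavity-filled [BinarySlice-class].
#' @param limb limb label attached to the contours.
#' @return list with elements `periosteal` and `endosteal`
#'   ([SurfaceContour-class]).
#' @export
extractContours <- function(slice, limb = "R") {
  g <- sliceGrid(slice)
  ncomp <- max(EBImage::bwlabel(g))
  if (ncomp != 1L) stop("expected exactly one bone component, found ", ncomp)
  ps <- pixelSize(slice)
  xs <- slice@origin[1L] + (seq_len(nrow(g)) - 1) * ps
  ys <- slice@origin[2L] + (seq_len(ncol(g)) - 1) * ps
  cl <- grDevices::contourLines(xs, ys, g + 0, levels = 0.5)
  if (length(cl) < 2L)
    stop("expected an outer and a marrow boundary; found ", length(cl))
  areas <- vapply(cl, function(c_) abs(.signedArea(cbind(c_$x, c_$y))), numeric(1))
  ord <- order(areas, decreasing = TRUE)
  outer <- cl[[ord[1L]]]; inner <- cl[[ord[2L]]]
  list(
    periosteal = surfaceContour(cbind(outer$x, outer$y), "periosteal", limb),
    endosteal  = surfaceContour(cbind(inner$x, inner$y), "endosteal", limb))
}

# Internal registration core on plain vertex matrices; returns the
# registered matrices plus the transform applied.
.registerCore <- function(peri, endo) {
  marrow <- .polygonCentroid(endo)
  peri <- sweep(peri, 2L, marrow)
  endo <- sweep(endo, 2L, marrow)
  p <- .sectionPropsCore(peri, endo)
  # second moments in axis-spread form: J = [[int x^2, int xy], [int xy, int y^2]]
  J <- matrix(c(p$Iyy, p$Ixy, p$Ixy, p$Ixx), 2L, 2L)
  if (abs(p$Ixx - p$Iyy) < 1e-3 * max(p$Ixx, p$Iyy))
    warning("principal axes nearly degenerate; rotation is ill-conditioned")
  ev <- eigen(J, symmetric = TRUE)
  long <- ev$vectors[, 1L]              # direction of minimal bending inertia
  theta <- pi / 2 - atan2(long[2L], long[1L])
  periR <- .rotatePts(peri, theta)
  endoR <- .rotatePts(endo, theta)
  # resolve the 180-degree ambiguity: put the thickest-cortex arc (ridge
  # surrogate for the posterior side) in the y < 0 half-plane
  th <- .minDistToSet(periR, endoR)
  ridge <- colMeans(periR[th >= stats::quantile(th, 0.8), , drop = FALSE])
  if (ridge[2L] > 0) {
    theta <- theta + pi
    periR <- -periR
    endoR <- -endoR
  }
  list(periosteal = periR, endosteal = endoR,
       rotation = theta, translation = -marrow)
}

#' Register a contour pair on the principal bending axis
#'
#' Translates the marrow (endosteal) centroid to the origin and rotates the
#' section so that the principal axis of minimal second moment of area lies
#' along y (making `Ixy` of the cortical section vanish). The 180-degree
#' ambiguity of the principal axis is resolved by placing the centroid of
#' the thickest-cortex arc, a geometric surrogate for the posterior ridge,
#' in the lower half-plane.
#'
#' @param periosteal,endosteal a [SurfaceContour-class] pair.
#' @return list with the registered `periosteal` and `endosteal` contours
#'   and `transform` (rotation in degrees, translation in um, mirror flag).
#' @export
registerSection <- function(periosteal, endosteal) {
  reg <- .registerCore(contourCoords(periosteal), contourCoords(endosteal))
  list(
    periosteal = surfaceContour(reg$periosteal, "periosteal",
                                limbLabel(periosteal)),
    endosteal  = surfaceContour(reg$endosteal, "endosteal",
                                limbLabel(endosteal)),
    transform  = list(rotation_deg = reg$rotation * 180 / pi,
                      translation_um = reg$translation, mirrored = FALSE))
}

#' Mirror a control-limb object horizontally
#'
#' Reflects x to -x about the registration origin so that left-limb data
#' can be compared with the loaded right limb. Contours are re-oriented to
#' remain clockwise. Mirroring is an involution.
#'
#' @param x a [SurfaceContour-class], [BinarySlice-class], or a list of
#'   them.
#' @return the mirrored object, with limb label switched.
#' @export
mirrorControl <- function(x) {
  if (is.list(x)) return(lapply(x, mirrorControl))
  if (is(x, "SurfaceContour")) {
    pts <- contourCoords(x)
    pts[, 1L] <- -pts[, 1L]
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    return(surfaceContour(pts, surfaceLabel(x),
                          if (limbLabel(x) == "L") "R" else "L"))
  }
  if (is(x, "BinarySlice")) {
    g <- sliceGrid(x)[rev(seq_len(nrow(sliceGrid(x)))), , drop = FALSE]
    ox <- -(x@origin[1L] + (nrow(g) - 1) * pixelSize(x))
    return(binarySlice(g, pixelSize(x), c(ox, x@origin[2L])))
  }
  stop("cannot mirror object of class ", class(x)[1L])
}

# Internal: polar radius samples of a star-shaped polygon about the origin,
# interpolated onto the angles `phi`.
.polarRadius <- function(pts, phi) {
  th <- atan2(pts[, 2L], pts[, 1L])
  r <- sqrt(rowSums(pts^2))
  o <- order(th)
  th <- th[o]; r <- r[o]
  th <- c(th[length(th)] - 2 * pi, th, th[1L] + 2 * pi)
  r <- c(r[length(r)], r, r[1L])
  stats::approx(th, r, xout = phi)$y
}

# Symmetric-difference area between two cortical annuli, both star-shaped
# about the origin, via dense polar sampling.
.symmDiffArea <- function(periA, endoA, periB, endoB, nPhi = 1024L) {
  phi <- seq(-pi, pi, length.out = nPhi + 1L)[-(nPhi + 1L)]
  dphi <- 2 * pi / nPhi
  f <- function(lo, hi) pmax(hi^2 - lo^2, 0) / 2
  a1 <- .polarRadius(endoA, phi); b1 <- .polarRadius(periA, phi)
  a2 <- .polarRadius(endoB, phi); b2 <- .polarRadius(periB, phi)
  inter <- f(pmax(a1, a2), pmin(b1, b2)) * (pmax(a1, a2) < pmin(b1, b2))
  sum((f(a1, b1) + f(a2, b2) - 2 * inter) * dphi)
}

#' Fine rotational alignment of control to loaded section
#'
#' Searches a small rotation about the marrow centroid (the registration
#' origin) that minimises the symmetric-difference area between the control
#' and loaded cortical regions, replacing the manual 1-5 degree adjustment
#' of the original imaging protocol with a reproducible optimiser over the
#' same window. Both sections are assumed star-shaped about the origin
#' (true for tibia-like annuli), so the overlap is evaluated in polar form.
#'
#' @param control,loaded lists with registered `periosteal` and `endosteal`
#'   contours (as returned by [registerSection()]).
#' @param searchDeg half-width of the search window in degrees.
#' @return list with `angleDeg` (rotation applied to the control),
#'   `control` (the rotated pair) and `objective` (residual
#'   symmetric-difference area, um^2).
#' @export
fineAlign <- function(control, loaded, searchDeg = 5) {
  pc <- contourCoords(control$periosteal)
  ec <- contourCoords(control$endosteal)
  pl <- contourCoords(loaded$periosteal)
  el <- contourCoords(loaded$endosteal)
  obj <- function(deg) {
    th <- deg * pi / 180
    .symmDiffArea(pl, el, .rotatePts(pc, th), .rotatePts(ec, th))
  }
  grid <- seq(-searchDeg, searchDeg, by = 0.25)
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
  ang <- opt$minimum; val <- opt$objective
  if (vals[k] < val) { ang <- grid[k]; val <- vals[k] }
  if (obj(0) <= val) { ang <- 0; val <- obj(0) }
  if (abs(abs(ang) - searchDeg) < 1e-3)
    warning("fine alignment hit the search bound")
  th <- ang * pi / 180
  list(angleDeg = ang,
       control = list(
         periosteal = surfaceContour(.rotatePts(pc, th), "periosteal",
                                     limbLabel(control$periosteal)),
         endosteal = surfaceContour(.rotatePts(ec, th), "endosteal",
                                    limbLabel(control$endosteal))),
       objective = val)
}

#' Resample a contour to uniform arc length
#'
#' Places `n` points at uniform arc-length spacing, with the first point
#' (P = 0) at the crossing of the negative y axis and positions increasing
#' clockwise, following the posterior-start convention of the registered
#' frame.
#'
#' @param contour a [SurfaceContour-class].
#' @param n number of points (default 500).
#' @return the resampled [SurfaceContour-class] with its `P` slot filled.
#' @export
resampleContour <- function(contour, n = 500L) {
  if (n < 8L) stop("n must be at least 8")
  pts <- .resampleRing(contourCoords(contour), n)
  new("SurfaceContour", coords = pts, surface = surfaceLabel(contour),
      limb = limbLabel(contour), P = (seq_len(n) - 1) / n)
}
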