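# Local adaptation measures: surface movement, cortical thickness, and
# group statistics.

# Internal signed minimum-distance field between an adapted and a baseline
# ring (plain vertex matrices). Sign convention: positive = formation =
# cortex thickening, i.e. adapted point outside the baseline polygon for
# the periosteum and inside it (marrow side) for the endosteum.
.signedMinDist <- function(adapted, baseline, surface, factor = 4L) {
  dense <- .densifyRing(baseline, factor)
  d <- .minDistToSet(adapted, dense)
  inside <- .pointsInPolygon(baseline, adapted)
  s <- if (surface == "periosteal") ifelse(inside, -1, 1)
       else ifelse(inside, 1, -1)
  d * s
}

#' Signed surface adaptation field
#'
#' For each point of the adapted contour, the minimum Euclidean distance to
#' the baseline contour after the baseline has been densified fourfold by
#' linear interpolation along arc length. The distance is signed positive
#' when the adapted point lies on the formation side of the baseline
#' (outside it for the periosteum, on the marrow side for the endosteum),
#' so positive values mean cortex thickening on both surfaces.
#'
#' @param adapted,baseline resampled [SurfaceContour-class] objects of the
#'   same surface, registered to a common frame.
#' @param factor densification factor for the baseline (default 4).
#' @return data frame with columns `P` and `delta` (um).
#' @export
surfaceAdaptation <- function(adapted, baseline, factor = 4L) {
  if (surfaceLabel(adapted) != surfaceLabel(baseline))
    stop("contours are from different surfaces")
  if (!length(positionGrid(adapted)))
    stop("adapted contour must be resampled first")
  delta <- .signedMinDist(contourCoords(adapted), contourCoords(baseline),
                          surfaceLabel(adapted), factor)
  data.frame(P = positionGrid(adapted), delta = delta)
}

# Internal hybrid thickness on plain matrices; returns list(th, m1, m2,
# fallback).
.hybridThicknessCore <- function(peri, endo, factor = 4L) {
  m1 <- .minDistToSet(peri, .densifyRing(endo, factor))
  inward <- -.formationNormals(peri, "periosteal")
  n <- nrow(peri)
  m2 <- numeric(n)
  for (i in seq_len(n)) {
    m2[i] <- min(.rayPolygonHit(peri[i, ], inward[i, ], endo, sMin = 1e-3),
                 .rayPolygonHit(peri[i, ], inward[i, ], peri, sMin = 1e-3))
  }
  fallback <- !is.finite(m2)
  m2[fallback] <- m1[fallback]
  list(th = pmin(m1, m2), m1 = m1, m2 = m2, fallback = fallback)
}

#' Hybrid cortical thickness
#'
#' Cortical thickness at every periosteal point by the hybrid rule: the
#' smaller of (1) the minimum distance to the fourfold-densified endosteal
#' contour and (2) the distance along the inward surface normal to the
#' first crossing of either cortical boundary. The normal-ray measurement
#' guards the minimum-distance one against shortcuts across irregular,
#' ridged geometries; where the inward ray escapes without crossing (open
#' geometry) the point falls back to the minimum-distance measure and is
#' flagged.
#'
#' @param periosteal,endosteal a registered, resampled
#'   [SurfaceContour-class] pair.
#' @param factor densification factor for the endosteal contour.
#' @return data frame with columns `P`, `thickness`, `minDist`, `normalRay`
#'   and `fallback`.
#' @export
hybridThickness <- function(periosteal, endosteal, factor = 4L) {
  h <- .hybridThicknessCore(contourCoords(periosteal),
                            contourCoords(endosteal), factor)
  data.frame(P = positionGrid(periosteal), thickness = h$th,
             minDist = h$m1, normalRay = h$m2, fallback = h$fallback)
}

#' Cortical thickness change between loaded and control sections
#'
#' Per-point difference of hybrid thickness, loaded minus control, at
#' matched normalised positions.
#'
#' @param loaded,control lists with registered, resampled `periosteal` and
#'   `endosteal` [SurfaceContour-class] entries.
#' @return data frame with columns `P` and `delta` (um).
#' @export
thicknessChange <- function(loaded, control) {
  tl <- hybridThickness(loaded$periosteal, loaded$endosteal)
  tc <- hybridThickness(control$periosteal, control$endosteal)
  if (nrow(tl) != nrow(tc) || max(abs(tl$P - tc$P)) > 1e-12)
    stop("loaded and control thickness fields are on different P grids")
  data.frame(P = tl$P, delta = tl$thickness - tc$thickness)
}

#' Group statistics of a per-animal adaptation field
#'
#' Per-point group mean, standard deviation and a two-sided one-sample
#' Student t test of the measurement against zero with n - 1 degrees of
#' freedom, uncorrected for multiple comparisons. With a single animal only
#' the mean is reported. Degenerate points with zero spread are declared
#' significant when the common value is nonzero.
#'
#' @param perMouse animals x points matrix of per-animal measurements (um).
#' @param P shared normalised-position grid.
#' @param measure label, one of `"deltaEtaP"`, `"deltaEtaE"`, `"deltaCtTh"`.
#' @param alpha significance level (default 0.05).
#' @return an [AdaptationMeasurement-class].
#' @export
groupStats <- function(perMouse, P, measure = "deltaEtaP", alpha = 0.05) {
  perMouse <- as.matrix(perMouse)
  n <- nrow(perMouse)
  if (ncol(perMouse) != length(P)) stop("perMouse does not match the P grid")
  m <- colMeans(perMouse)
  if (n < 2L) {
    return(new("AdaptationMeasurement", measure = measure, P = P,
               perMouse = perMouse, mean = m,
               sd = rep(NA_real_, length(P)), p = rep(NA_real_, length(P)),
               significant = rep(NA, length(P)), alpha = alpha))
  }
  sd <- sqrt(colSums(sweep(perMouse, 2L, m)^2) / (n - 1))
  t <- ifelse(sd > 0, m / (sd / sqrt(n)), ifelse(m == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  new("AdaptationMeasurement", measure = measure, P = P,
      perMouse = perMouse, mean = m, sd = unname(sd), p = unname(p),
      significant = unname(p < alpha), alpha = alpha)
}

#' Measure adaptation between a control and a loaded slice
#'
#' Full measurement pipeline for one animal: cavity filling, contour
#' extraction, horizontal mirroring of the control limb, principal-axis
#' registration of both pairs, fine rotational alignment of the control to
#' the loaded section, uniform resampling, and the three local adaptation
#' measures.
#'
#' @param left control-limb [BinarySlice-class] (left tibia).
#' @param right loaded-limb [BinarySlice-class].
#' @param n resampled points per surface.
#' @param searchDeg fine-alignment window in degrees.
#' @return list with numeric fields `deltaEtaP`, `deltaEtaE`, `deltaCtTh`,
#'   the shared grid `P`, and the fine-alignment angle.
#' @export
measureSlicePair <- function(left, right, n = 500L, searchDeg = 5) {
  ctrl <- extractContours(fillCavities(left), limb = "L")
  load <- extractContours(fillCavities(right), limb = "R")
  ctrl <- lapply(ctrl, mirrorControl)
  ctrl <- registerSection(ctrl$periosteal, ctrl$endosteal)
  load <- registerSection(load$periosteal, load$endosteal)
  fa <- fineAlign(ctrl, load, searchDeg = searchDeg)
  ctrlR <- lapply(fa$control, resampleContour, n = n)
  loadR <- lapply(load[c("periosteal", "endosteal")], resampleContour, n = n)
  dP <- surfaceAdaptation(loadR$periosteal, ctrlR$periosteal)
  dE <- surfaceAdaptation(loadR$endosteal, ctrlR$endosteal)
  dT <- thicknessChange(loadR, ctrlR)
  list(deltaEtaP = dP$delta, deltaEtaE = dE$delta, deltaCtTh = dT$delta,
       P = dP$P, alignDeg = fa$angleDeg)
}

#' Group-level adaptation measurement for one load group
#'
#' Applies [measureSlicePair()] to every animal of a loading group and
#' summarises the three adaptation measures with [groupStats()].
#'
#' @param pairs list of animals, each a list with `left` and `right`
#'   [BinarySlice-class] slices.
#' @param n resampled points per surface.
#' @param alpha significance level.
#' @return list of three [AdaptationMeasurement-class] objects named
#'   `deltaEtaP`, `deltaEtaE`, `deltaCtTh`.
#' @export
measureGroup <- function(pairs, n = 500L, alpha = 0.05) {
  per <- lapply(pairs, function(pr) measureSlicePair(pr$left, pr$right, n = n))
  P <- per[[1L]]$P
  mk <- function(field, lab)
    groupStats(do.call(rbind, lapply(per, `[[`, field)), P, lab, alpha)
  list(deltaEtaP = mk("deltaEtaP", "deltaEtaP"),
       deltaEtaE = mk("deltaEtaE", "deltaEtaE"),
       deltaCtTh = mk("deltaCtTh", "deltaCtTh"))
}
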