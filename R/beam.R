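# Beam-theory strain analysis of the cortical cross section.

# Internal: properties of the annular region between two vertex matrices.
.sectionPropsCore <- function(outer, inner = NULL) {
  po <- .polygonIntegrals(outer)
  if (is.null(inner)) {
    pi_ <- list(A = 0, Sx = 0, Sy = 0, Ixx = 0, Iyy = 0, Ixy = 0)
  } else {
    pi_ <- .polygonIntegrals(inner)
  }
  A <- po$A - pi_$A
  xc <- (po$Sx - pi_$Sx) / A
  yc <- (po$Sy - pi_$Sy) / A
  # parallel-axis shift of the origin-referenced integrals to the centroid
  list(A = A, xc = xc, yc = yc,
       Ixx = (po$Ixx - pi_$Ixx) - A * yc^2,
       Iyy = (po$Iyy - pi_$Iyy) - A * xc^2,
       Ixy = (po$Ixy - pi_$Ixy) - A * xc * yc)
}

#' Cross-sectional properties of the cortical annulus
#'
#' Computes area, centroid and centroidal second moments of area of the
#' region enclosed by the periosteal contour minus the endosteal (marrow)
#' contour, using exact closed polygon integrals.
#'
#' @param periosteal,endosteal [SurfaceContour-class] objects; `endosteal`
#'   may be `NULL` for a solid section.
#' @return a [SectionProperties-class].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 501)[-501]
#' peri <- surfaceContour(500 * cbind(cos(th), sin(th)), "periosteal")
#' endo <- surfaceContour(300 * cbind(cos(th), sin(th)), "endosteal")
#' sectionProperties(peri, endo)
#' @export
sectionProperties <- function(periosteal, endosteal = NULL) {
  outer <- contourCoords(periosteal)
  inner <- if (is.null(endosteal)) NULL else contourCoords(endosteal)
  if (!is.null(inner)) {
    if (any(!.pointsInPolygon(outer, inner)))
      stop("endosteal contour is not strictly inside the periosteal contour")
  }
  p <- .sectionPropsCore(outer, inner)
  new("SectionProperties", A = p$A, centroid = c(p$xc, p$yc),
      Ixx = p$Ixx, Iyy = p$Iyy, Ixy = p$Ixy)
}

# Internal: bending moments (Mx, My) in N.um of the eccentric axial load
# about the section centroid. The compressive load -F z acting at the load
# point p_F is statically equivalent to the same force at the centroid plus
# the couple M = (p_F - p_c) x (-0.9 F z), giving
#   Mx = -0.9 F (yF - yc),  My = +0.9 F (xF - xc).
# With these signs the flexure formula places extra compression on the
# load-offset side of the section.
.bendingMomentsCore <- function(F, share, loadPoint, centroid) {
  r <- loadPoint - centroid
  c(Mx = -share * F * r[2L], My = share * F * r[1L])
}

#' Bending moments from the eccentric axial load
#'
#' The in-plane offset between the load point and the section centroid turns
#' the axial tibial load into a couple, `M = 0.9 F x (p_c - p_F)`.
#'
#' @param load a [LoadCase-class].
#' @param props the [SectionProperties-class] of the current section.
#' @return named numeric `c(Mx, My)` in N um.
#' @export
bendingMoments <- function(load, props) {
  .bendingMomentsCore(load@peakLoad, load@tibialShare, load@loadPoint,
                      sectionCentroid(props))
}

# Internal vectorised flexure evaluation; pts is an n x 2 matrix in um.
# Units: forces in N, lengths in um, E in Pa = N/m^2. Stress is assembled
# in N/um^2 and converted; the result is dimensionless strain.
.flexureCore <- function(pts, props, F, share, loadPoint, E) {
  if (F == 0) return(rep(0, nrow(pts)))
  M <- .bendingMomentsCore(F, share, loadPoint, c(props$xc, props$yc))
  den <- props$Ixx * props$Iyy - props$Ixy^2
  if (den <= 0) stop("singular second-moment tensor")
  cx <- pts[, 1L] - props$xc
  cy <- pts[, 2L] - props$yc
  sigma <- -share * F / props$A +
    ((M["Mx"] * props$Iyy + M["My"] * props$Ixy) / den) * cy -
    ((M["My"] * props$Ixx + M["Mx"] * props$Ixy) / den) * cx
  # sigma is in N/um^2; 1 N/um^2 = 1e12 Pa
  unname(sigma * 1e12 / E)
}

#' Longitudinal strain from the generalised flexure formula
#'
#' Evaluates the Euler-Bernoulli generalised flexure formula at each contour
#' point: a uniform compressive axial term `-0.9 F / (E A)` plus the
#' asymmetric bending terms driven by the load-point offset. Strain is
#' linear in the centroid-referenced coordinates, so its zero set is the
#' neutral axis.
#'
#' @param props a [SectionProperties-class].
#' @param load a [LoadCase-class]; the applied compressive load is a
#'   positive magnitude and enters the axial term negated.
#' @param contours a [SurfaceContour-class] or list of them.
#' @return a data frame with columns `surface`, `P`, `x`, `y` and `strain`
#'   (in microstrain; negative = compression).
#' @export
flexureStrain <- function(props, load, contours) {
  if (is(contours, "SurfaceContour")) contours <- list(contours)
  p <- list(A = sectionArea(props),
            xc = sectionCentroid(props)[1L], yc = sectionCentroid(props)[2L],
            Ixx = secondMoments(props)["Ixx"],
            Iyy = secondMoments(props)["Iyy"],
            Ixy = secondMoments(props)["Ixy"])
  p <- lapply(p, unname)
  do.call(rbind, lapply(contours, function(ct) {
    pts <- contourCoords(ct)
    eps <- .flexureCore(pts, p, load@peakLoad, load@tibialShare,
                        load@loadPoint, load@youngsModulus)
    data.frame(surface = surfaceLabel(ct),
               P = if (length(positionGrid(ct))) positionGrid(ct) else NA_real_,
               x = pts[, 1L], y = pts[, 2L], strain = eps * 1e6)
  }))
}
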