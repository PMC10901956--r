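# Synthetic tibia-like cross-section cohorts with known ground truth.

#' Geometry specification for a synthetic midshaft section
#'
#' Describes a tibia-like annular cross section as a pair of star-shaped
#' contours: a base circle per surface modulated by low-order Fourier
#' harmonics of the radius, plus one localised Gaussian bump on the outer
#' contour emulating the posterior tibial ridge. The geometry is generic
#' rather than a digitised tibia: what matters to the downstream
#' algorithms is asymmetry, a ridge, and an eccentric marrow cavity.
#'
#' @param outerRadius,innerRadius base radii in micrometres.
#' @param outerHarmonics,innerHarmonics data frames with columns `order`,
#'   `amplitude` (um) and `phase` (rad) describing radius modulations
#'   `amplitude * cos(order * theta + phase)`.
#' @param ridgeAmplitude,ridgeCenter,ridgeWidth Gaussian ridge bump on the
#'   outer contour: height (um), angular centre and width (rad).
#' @param pixelSize raster resolution in micrometres (default 9.56).
#' @return a list of class `GeometrySpec`.
#' @export
geometrySpec <- function(outerRadius = 600, innerRadius = 400,
                         outerHarmonics = data.frame(
                           order = c(2, 3), amplitude = c(40, 15),
                           phase = c(0.35, 1.1)),
                         innerHarmonics = data.frame(
                           order = c(1, 2), amplitude = c(30, 25),
                           phase = c(0.9, 0.35)),
                         ridgeAmplitude = 60, ridgeCenter = -pi / 2,
                         ridgeWidth = 0.4, pixelSize = 9.56) {
  if (outerRadius <= 0 || innerRadius <= 0) stop("radii must be positive")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  structure(list(outerRadius = outerRadius, innerRadius = innerRadius,
                 outerHarmonics = outerHarmonics,
                 innerHarmonics = innerHarmonics,
                 ridgeAmplitude = ridgeAmplitude, ridgeCenter = ridgeCenter,
                 ridgeWidth = ridgeWidth, pixelSize = pixelSize),
            class = "GeometrySpec")
}

# Radius function of one surface at angles theta.
.radiusAt <- function(theta, base, harmonics, ridgeAmp = 0,
                      ridgeCenter = 0, ridgeWidth = 1) {
  r <- rep(base, length(theta))
  if (nrow(harmonics)) {
    for (k in seq_len(nrow(harmonics)))
      r <- r + harmonics$amplitude[k] *
        cos(harmonics$order[k] * theta + harmonics$phase[k])
  }
  if (ridgeAmp != 0) {
    d <- atan2(sin(theta - ridgeCenter), cos(theta - ridgeCenter))
    r <- r + ridgeAmp * exp(-0.5 * (d / ridgeWidth)^2)
  }
  r
}

.applyJitter <- function(spec, jitter) {
  if (is.null(jitter)) return(spec)
  s <- spec
  if (!is.null(jitter$outerRadius)) s$outerRadius <- s$outerRadius + jitter$outerRadius
  if (!is.null(jitter$innerRadius)) s$innerRadius <- s$innerRadius + jitter$innerRadius
  if (!is.null(jitter$outerAmp))
    s$outerHarmonics$amplitude <- s$outerHarmonics$amplitude + jitter$outerAmp
  if (!is.null(jitter$innerAmp))
    s$innerHarmonics$amplitude <- s$innerHarmonics$amplitude + jitter$innerAmp
  if (!is.null(jitter$outerPhase))
    s$outerHarmonics$phase <- s$outerHarmonics$phase + jitter$outerPhase
  if (!is.null(jitter$innerPhase))
    s$innerHarmonics$phase <- s$innerHarmonics$phase + jitter$innerPhase
  s
}

#' Generate a baseline contour pair from a geometry specification
#'
#' Samples both radius functions clockwise from the negative y axis and,
#' by default, registers the section into the canonical frame (marrow
#' centroid at the origin, minimal-inertia axis along y, ridge in the
#' lower half-plane). Deterministic given the jitter.
#'
#' @param spec a [geometrySpec()].
#' @param jitter optional per-animal perturbation: a list with any of
#'   `outerRadius`, `innerRadius`, `outerAmp`, `innerAmp`, `outerPhase`,
#'   `innerPhase` (amplitudes in um, phases in rad).
#' @param n points per contour.
#' @param register register into the canonical frame (default TRUE).
#' @return list with `periosteal` and `endosteal` [SurfaceContour-class]
#'   objects.
#' @export
makeBaselineGeometry <- function(spec, jitter = NULL, n = 500L,
                                 register = TRUE) {
  s <- .applyJitter(spec, jitter)
  theta <- -pi / 2 - 2 * pi * (seq_len(n) - 1) / n   # clockwise from bottom
  rOut <- .radiusAt(theta, s$outerRadius, s$outerHarmonics,
                    s$ridgeAmplitude, s$ridgeCenter, s$ridgeWidth)
  rIn <- .radiusAt(theta, s$innerRadius, s$innerHarmonics)
  if (any(rIn <= 0) || any(rOut <= 0))
    stop("invalid geometry: negative radius after perturbation")
  if (any(rOut - rIn <= 5 * s$pixelSize))
    stop("invalid geometry: cortical thickness below 5 pixels")
  peri <- cbind(rOut * cos(theta), rOut * sin(theta))
  endo <- cbind(rIn * cos(theta), rIn * sin(theta))
  if (register) {
    reg <- .registerCore(peri, endo)
    # uniform arc-length spacing anchored at the registered P = 0 origin,
    # so that forward simulations from this baseline stay point-matched
    peri <- .resampleRing(reg$periosteal, n)
    endo <- .resampleRing(reg$endosteal, n)
    P <- (seq_len(n) - 1) / n
    return(list(
      periosteal = new("SurfaceContour", coords = peri,
                       surface = "periosteal", limb = "R", P = P),
      endosteal = new("SurfaceContour", coords = endo,
                      surface = "endosteal", limb = "R", P = P)))
  }
  list(periosteal = surfaceContour(peri, "periosteal", "R"),
       endosteal = surfaceContour(endo, "endosteal", "R"))
}

#' Rasterise a contour pair into a binary slice
#'
#' Pixels are bone exactly when their centre lies inside the periosteal
#' and outside the endosteal contour. Pixel centres sit at integer
#' multiples of the pixel size.
#'
#' @param periosteal,endosteal [SurfaceContour-class] pair.
#' @param pixelSize pixel size in micrometres.
#' @param margin margin around the bounding box, in pixels.
#' @return a [BinarySlice-class].
#' @export
rasterizeSection <- function(periosteal, endosteal, pixelSize = 9.56,
                             margin = 3L) {
  peri <- contourCoords(periosteal)
  endo <- contourCoords(endosteal)
  bb <- apply(peri, 2L, range)
  if (all(bb[2L, ] - bb[1L, ] < pixelSize))
    stop("contour fits inside a single pixel; resolution too coarse")
  i0 <- floor(bb[1L, ] / pixelSize) - margin
  i1 <- ceiling(bb[2L, ] / pixelSize) + margin
  xs <- (i0[1L]:i1[1L]) * pixelSize
  ys <- (i0[2L]:i1[2L]) * pixelSize
  centres <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  bone <- .pointsInPolygon(peri, centres) & !.pointsInPolygon(endo, centres)
  if (min(.minDistToSet(peri, endo)) < 2 * pixelSize)
    warning("cortex thinner than 2 pixels; measurements may be unreliable")
  binarySlice(matrix(bone, nrow = length(xs)), pixelSize,
              origin = c(xs[1L], ys[1L]))
}

#' Cohort specification for synthetic loading groups
#'
#' Study-design parameters of a synthetic endpoint-imaging experiment:
#' group size, peak-load levels, biological shape variation, measurement
#' roughness, the ground-truth mechanostat, and the loading schedule.
#' Defaults mirror the emulated study: groups of 6 animals at peak loads
#' 0-12 N, a 5 + 14 + 2 day protocol, and the four-rate mechanostat with
#' its surface thresholds and disuse resorption as ground truth.
#'
#' @param nMice animals per loading group (>= 2).
#' @param loadLevels peak loads in newtons.
#' @param shapeJitterSD per-animal SD of base radii and Fourier amplitudes
#'   (um).
#' @param phaseJitterSD per-animal SD of harmonic phases (rad).
#' @param contourNoiseSD point-wise radial roughness added to each limb's
#'   contours before rasterisation (um).
#' @param rotationJitterSD per-limb pose jitter (degrees).
#' @param seed integer seed; the cohort is a pure function of this spec.
#' @param truthParams ground-truth [MechanostatParams-class].
#' @param geometry a [geometrySpec()].
#' @param loadPoint in-plane load position (um) in the canonical frame.
#' @param nPoints contour points per surface.
#' @param snPre,loadingDays,snPost,dt schedule phases (days).
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(nMice = 6L, loadLevels = c(0, 2, 4, 6, 8, 10, 12),
                       shapeJitterSD = 5, phaseJitterSD = 0.05,
                       contourNoiseSD = 2, rotationJitterSD = 2,
                       seed = 1L,
                       truthParams = mechanostatParams(
                         "M4", kPT = 2.148, kPC = 0.981,
                         kET = 7.055, kEC = 0.794),
                       geometry = geometrySpec(),
                       loadPoint = c(0, -1000), nPoints = 500L,
                       snPre = 5, loadingDays = 14, snPost = 2, dt = 1) {
  if (nMice < 2L) stop("nMice must be at least 2")
  if (any(c(shapeJitterSD, phaseJitterSD, contourNoiseSD,
            rotationJitterSD) < 0))
    stop("noise SDs must be >= 0")
  structure(list(nMice = as.integer(nMice), loadLevels = loadLevels,
                 shapeJitterSD = shapeJitterSD,
                 phaseJitterSD = phaseJitterSD,
                 contourNoiseSD = contourNoiseSD,
                 rotationJitterSD = rotationJitterSD,
                 seed = as.integer(seed), truthParams = truthParams,
                 geometry = geometry, loadPoint = loadPoint,
                 nPoints = as.integer(nPoints), snPre = snPre,
                 loadingDays = loadingDays, snPost = snPost, dt = dt),
            class = "CohortSpec")
}

# Point-wise radial roughness about the marrow-centroid origin.
.radialNoise <- function(pts, sd) {
  if (sd == 0) return(pts)
  r <- sqrt(rowSums(pts^2))
  pts * (1 + stats::rnorm(nrow(pts), 0, sd) / r)
}

#' Generate a synthetic cohort with known ground truth
#'
#' For every animal of every loading group: a jittered baseline geometry is
#' generated in the canonical frame; the loaded (right) limb endpoint is
#' the forward mechanostat simulation of that baseline under the
#' ground-truth parameters and schedule; the control (left) limb is the
#' baseline mirrored horizontally. Ground-truth per-point adaptation fields
#' are measured on the exact endpoint contours before contour roughness,
#' pose jitter and rasterisation are applied. Animals whose simulation
#' fails are flagged and returned without slices.
#'
#' @param spec a [cohortSpec()].
#' @return list with the `spec` and `groups`; each group holds its peak
#'   load and a list of `mice`, each with `left`/`right`
#'   [BinarySlice-class] slices, the exact `baseline` and `endpoint`
#'   contour pairs, the `truth` adaptation fields, and a `flagged` status.
#' @export
makeCohort <- function(spec) {
  set.seed(spec$seed)
  groups <- lapply(spec$loadLevels, function(F) {
    sched <- simulationSchedule(
      loadCase(F, loadPoint = spec$loadPoint),
      snPre = spec$snPre, loadingDays = spec$loadingDays,
      snPost = spec$snPost, dt = spec$dt)
    mice <- lapply(seq_len(spec$nMice), function(m) {
      jit <- list(
        outerRadius = stats::rnorm(1, 0, spec$shapeJitterSD),
        innerRadius = stats::rnorm(1, 0, spec$shapeJitterSD),
        outerAmp = stats::rnorm(nrow(spec$geometry$outerHarmonics), 0,
                                spec$shapeJitterSD),
        innerAmp = stats::rnorm(nrow(spec$geometry$innerHarmonics), 0,
                                spec$shapeJitterSD),
        outerPhase = stats::rnorm(nrow(spec$geometry$outerHarmonics), 0,
                                  spec$phaseJitterSD),
        innerPhase = stats::rnorm(nrow(spec$geometry$innerHarmonics), 0,
                                  spec$phaseJitterSD))
      base <- makeBaselineGeometry(spec$geometry, jit, n = spec$nPoints)
      end <- tryCatch(
        simulateAdaptation(base$periosteal, base$endosteal,
                           spec$truthParams, sched, n = spec$nPoints,
                           audit = FALSE),
        error = function(e) NULL)
      if (is.null(end)) {
        return(list(flagged = TRUE, baseline = base))
      }
      P <- (seq_len(spec$nPoints) - 1) / spec$nPoints
      truth <- list(
        P = P,
        deltaEtaP = .signedMinDist(contourCoords(end$periosteal),
                                   contourCoords(base$periosteal),
                                   "periosteal"),
        deltaEtaE = .signedMinDist(contourCoords(end$endosteal),
                                   contourCoords(base$endosteal),
                                   "endosteal"))
      ps <- spec$geometry$pixelSize
      noisy <- function(pair, rotDeg) {
        th <- rotDeg * pi / 180
        lapply(pair, function(ct) {
          pts <- .radialNoise(contourCoords(ct), spec$contourNoiseSD)
          surfaceContour(.rotatePts(pts, th), surfaceLabel(ct), limbLabel(ct))
        })
      }
      rightC <- noisy(list(periosteal = end$periosteal,
                           endosteal = end$endosteal),
                      stats::rnorm(1, 0, spec$rotationJitterSD))
      leftC <- noisy(lapply(base, mirrorControl),
                     stats::rnorm(1, 0, spec$rotationJitterSD))
      list(flagged = FALSE,
           baseline = base, endpoint = end[c("periosteal", "endosteal")],
           truth = truth,
           left = rasterizeSection(leftC$periosteal, leftC$endosteal, ps),
           right = rasterizeSection(rightC$periosteal, rightC$endosteal, ps))
    })
    list(load = F, mice = mice)
  })
  names(groups) <- paste0("F", spec$loadLevels)
  list(spec = spec, groups = groups)
}
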