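# Constructors, accessors and show methods.

#' Create a BinarySlice
#'
#' @param grid logical (or coercible) matrix of bone pixels; rows index x,
#'   columns index y.
#' @param pixelSize isotropic pixel size in micrometres (default 9.56, the
#'   working resolution of the down-sampled scans this package emulates).
#' @param origin (x, y) in micrometres of the centre of pixel (1, 1).
#' @return a [BinarySlice-class].
#' @export
binarySlice <- function(grid, pixelSize = 9.56, origin = c(0, 0)) {
  storage.mode(grid) <- "logical"
  new("BinarySlice", grid = grid, pixelSize = pixelSize,
      origin = as.numeric(origin))
}

#' Create a SurfaceContour
#'
#' Orientation is normalised to clockwise (y-up frame) on construction.
#'
#' @param coords n x 2 matrix of (x, y) in micrometres (first vertex not
#'   repeated).
#' @param surface `"periosteal"` or `"endosteal"`.
#' @param limb `"R"` or `"L"`.
#' @param P optional normalised positions; usually left empty and filled by
#'   [resampleContour()].
#' @return a [SurfaceContour-class].
#' @export
surfaceContour <- function(coords, surface, limb = "R", P = numeric()) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (n > 1 && all(coords[1L, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  new("SurfaceContour", coords = .ensureClockwise(coords),
      surface = surface, limb = limb, P = P)
}

#' Create a LoadCase
#'
#' @param peakLoad peak compressive load F in newtons.
#' @param loadPoint (x, y) load application point in micrometres, in the
#'   registered section frame (marrow centroid at the origin).
#' @param tibialShare fraction of F carried by the tibia.
#' @param youngsModulus Young's modulus in Pa.
#' @return a [LoadCase-class].
#' @export
loadCase <- function(peakLoad, loadPoint = c(0, -1000),
                     tibialShare = 0.9, youngsModulus = 14.8e9) {
  new("LoadCase", peakLoad = peakLoad, loadPoint = as.numeric(loadPoint),
      tibialShare = tibialShare, youngsModulus = youngsModulus)
}

#' Create MechanostatParams
#'
#' Rates that a model class ties together may be given once; the remaining
#' ones are filled in. For example `mechanostatParams("M1", kPT = 0.5)`
#' sets all four rates to 0.5 and uses the single 1100 microstrain
#' threshold.
#'
#' @param modelId one of "M1", "M2", "M3", "M4".
#' @param kPT,kPC,kET,kEC formation rates (um/day per unit normalised
#'   strain). Omitted rates default to the value of their tied partner, or 0.
#' @param epsHomP,epsHomE strain thresholds in microstrain; defaults are the
#'   single 1100 threshold for M1/M2 and the surface-specific 2785/1100 pair
#'   for M3/M4.
#' @param kSN endosteal disuse resorption rate in um/day (default 1.398).
#' @return a [MechanostatParams-class].
#' @export
mechanostatParams <- function(modelId = "M4", kPT = NULL, kPC = NULL,
                              kET = NULL, kEC = NULL,
                              epsHomP = NULL, epsHomE = NULL, kSN = 1.398) {
  if (is.null(epsHomE)) epsHomE <- 1100
  if (is.null(epsHomP)) epsHomP <- switch(modelId, M1 = , M2 = epsHomE, 2785)
  fill <- function(a, b) if (is.null(a)) b else a
  if (modelId == "M1") {
    kPT <- fill(kPT, fill(kPC, fill(kET, fill(kEC, 0))))
    kPC <- kET <- kEC <- kPT
  } else if (modelId == "M2") {
    kPT <- fill(kPT, fill(kET, 0)); kET <- kPT
    kPC <- fill(kPC, fill(kEC, 0)); kEC <- kPC
  } else if (modelId == "M3") {
    kPT <- fill(kPT, fill(kPC, 0)); kPC <- kPT
    kET <- fill(kET, fill(kEC, 0)); kEC <- kET
  } else {
    kPT <- fill(kPT, 0); kPC <- fill(kPC, 0)
    kET <- fill(kET, 0); kEC <- fill(kEC, 0)
  }
  new("MechanostatParams", modelId = modelId,
      epsHomP = epsHomP, epsHomE = epsHomE,
      kPT = kPT, kPC = kPC, kET = kET, kEC = kEC, kSN = kSN)
}

#' Create a SimulationSchedule
#'
#' @param load the [LoadCase-class] applied on loading days.
#' @param snPre,loadingDays,snPost phase lengths in days (defaults 5, 14, 2).
#' @param dt time step in days.
#' @return a [SimulationSchedule-class].
#' @export
simulationSchedule <- function(load, snPre = 5, loadingDays = 14,
                               snPost = 2, dt = 1) {
  new("SimulationSchedule", dt = dt, snPre = snPre,
      loadingDays = loadingDays, snPost = snPost, load = load)
}

#' @rdname BinarySlice-class
#' @export
setMethod("pixelSize", "BinarySlice", function(object) object@pixelSize)

#' @rdname BinarySlice-class
#' @export
setMethod("sliceGrid", "BinarySlice", function(object) object@grid)

#' @rdname SurfaceContour-class
#' @export
setMethod("contourCoords", "SurfaceContour", function(object) object@coords)

#' @rdname SurfaceContour-class
#' @export
setMethod("surfaceLabel", "SurfaceContour", function(object) object@surface)

#' @rdname SurfaceContour-class
#' @export
setMethod("limbLabel", "SurfaceContour", function(object) object@limb)

#' @rdname SurfaceContour-class
#' @export
setMethod("positionGrid", "SurfaceContour", function(object) object@P)

#' @rdname AdaptationMeasurement-class
#' @export
setMethod("positionGrid", "AdaptationMeasurement", function(object) object@P)

#' @rdname SectionProperties-class
#' @export
setMethod("sectionArea", "SectionProperties", function(object) object@A)

#' @rdname SectionProperties-class
#' @export
setMethod("sectionCentroid", "SectionProperties", function(object) object@centroid)

#' @rdname SectionProperties-class
#' @export
setMethod("secondMoments", "SectionProperties",
  function(object) c(Ixx = object@Ixx, Iyy = object@Iyy, Ixy = object@Ixy))

#' @rdname MechanostatParams-class
#' @export
setMethod("modelId", "MechanostatParams", function(object) object@modelId)

#' @rdname MechanostatParams-class
#' @export
setMethod("formationRates", "MechanostatParams",
  function(object) c(kPT = object@kPT, kPC = object@kPC,
                     kET = object@kET, kEC = object@kEC))

#' @rdname MechanostatParams-class
#' @export
setMethod("resorptionRate", "MechanostatParams", function(object) object@kSN)

#' @rdname MechanostatParams-class
#' @export
setMethod("strainThresholds", "MechanostatParams",
  function(object) c(epsHomP = object@epsHomP, epsHomE = object@epsHomE))

#' @rdname AdaptationMeasurement-class
#' @export
setMethod("fieldMean", "AdaptationMeasurement", function(object) object@mean)

#' @rdname AdaptationMeasurement-class
#' @export
setMethod("fieldSD", "AdaptationMeasurement", function(object) object@sd)

#' @rdname AdaptationMeasurement-class
#' @export
setMethod("pValues", "AdaptationMeasurement", function(object) object@p)

#' @rdname MechanostatFit-class
#' @export
setMethod("bestParams", "MechanostatFit", function(object) object@params)

#' @rdname MechanostatFit-class
#' @export
setMethod("rmsErrors", "MechanostatFit", function(object) object@rms)

#' @rdname MechanostatFit-class
#' @export
setMethod("searchLog", "MechanostatFit", function(object) object@log)

setMethod("show", "BinarySlice", function(object) {
  cat("BinarySlice:", nrow(object@grid), "x", ncol(object@grid),
      "pixels @", object@pixelSize, "um;",
      sum(object@grid), "bone pixels\n")
})

setMethod("show", "SurfaceContour", function(object) {
  cat("SurfaceContour (", object@surface, ", limb ", object@limb, "): ",
      nrow(object@coords), " points",
      if (length(object@P)) ", resampled" else "", "\n", sep = "")
})

setMethod("show", "SectionProperties", function(object) {
  cat(sprintf(
    "SectionProperties: A = %.1f um^2, centroid = (%.2f, %.2f) um\n",
    object@A, object@centroid[1L], object@centroid[2L]))
  cat(sprintf("  Ixx = %.4g, Iyy = %.4g, Ixy = %.4g um^4\n",
              object@Ixx, object@Iyy, object@Ixy))
})

setMethod("show", "MechanostatParams", function(object) {
  cat("MechanostatParams [", object@modelId, "]\n", sep = "")
  cat(sprintf("  thresholds: periosteal %g, endosteal %g microstrain\n",
              object@epsHomP, object@epsHomE))
  cat(sprintf("  rates (um/day): kPT %g, kPC %g, kET %g, kEC %g; kSN %g\n",
              object@kPT, object@kPC, object@kET, object@kEC, object@kSN))
})

setMethod("show", "SimulationSchedule", function(object) {
  cat(sprintf(
    "SimulationSchedule: %g d SN + %g d loading + %g d SN (dt = %g d), F = %g N\n",
    object@snPre, object@loadingDays, object@snPost, object@dt,
    object@load@peakLoad))
})

setMethod("show", "AdaptationMeasurement", function(object) {
  cat("AdaptationMeasurement [", object@measure, "]: ",
      length(object@P), " points, n = ", nrow(object@perMouse),
      " animals\n", sep = "")
  cat(sprintf("  mean range [%.2f, %.2f] um; %.1f%% of points significant at alpha = %g\n",
              min(object@mean), max(object@mean),
              100 * mean(object@significant), object@alpha))
})

setMethod("show", "MechanostatFit", function(object) {
  cat("MechanostatFit [", object@params@modelId, "]\n", sep = "")
  r <- formationRates(object@params)
  cat(sprintf("  rates: kPT %g, kPC %g, kET %g, kEC %g um/day\n",
              r[1L], r[2L], r[3L], r[4L]))
  cat(sprintf("  RMS: P %.3f, E %.3f, C %.3f um (%d candidates evaluated)\n",
              object@rms["P"], object@rms["E"], object@rms["C"],
              nrow(object@log)))
})
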