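#' @import methods
NULL

#' Binarised cortical cross-section raster
#'
#' A single 2D binary slice of cortical bone. `grid[i, j]` is `TRUE` where
#' the pixel contains bone; row index `i` runs along x and column index `j`
#' along y (y-up frame). The centre of pixel `(i, j)` lies at
#' `origin + (i - 1, j - 1) * pixelSize`, so pixel centres sit at integer
#' multiples of the pixel size when `origin` does.
#'
#' @slot grid logical matrix of bone pixels.
#' @slot pixelSize isotropic pixel size in micrometres.
#' @slot origin (x, y) position in micrometres of the centre of pixel (1, 1).
#' @export
setClass("BinarySlice",
  representation(grid = "matrix", pixelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@grid)) msg <- c(msg, "grid must be a logical matrix")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Ordered closed surface contour
#'
#' A periosteal or endosteal envelope as an ordered, closed polyline in
#' micrometres. Orientation is clockwise in the y-up frame (decreasing
#' mathematical angle). After resampling, the slot `P` holds the normalised
#' position of each point in [0, 1), increasing clockwise from the crossing
#' of the negative y axis (the posterior reference of the registered frame).
#'
#' @slot coords n x 2 matrix of (x, y) coordinates in micrometres; the first
#'   vertex is not repeated at the end.
#' @slot surface `"periosteal"` or `"endosteal"`.
#' @slot limb `"R"` (loaded) or `"L"` (contralateral control).
#' @slot P normalised position per point; empty before resampling.
#' @export
setClass("SurfaceContour",
  representation(coords = "matrix", surface = "character",
                 limb = "character", P = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@coords) != 2L || nrow(object@coords) < 3L)
      msg <- c(msg, "coords must be an n x 2 matrix with n >= 3")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
    if (!object@surface %in% c("periosteal", "endosteal"))
      msg <- c(msg, "surface must be 'periosteal' or 'endosteal'")
    if (!object@limb %in% c("R", "L"))
      msg <- c(msg, "limb must be 'R' or 'L'")
    if (length(object@P) && length(object@P) != nrow(object@coords))
      msg <- c(msg, "P must be empty or match the number of points")
    if (nrow(object@coords) >= 3L && .signedArea(object@coords) >= 0)
      msg <- c(msg, "contour must be oriented clockwise (negative signed area)")
    if (is.null(msg)) TRUE else msg
  })

#' Cross-sectional area properties
#'
#' Area, centroid and centroidal second moments of area of the cortical
#' (annular) cross section, as used by the generalised flexure formula.
#'
#' @slot A cortical area in square micrometres.
#' @slot centroid (x, y) centroid in micrometres.
#' @slot Ixx,Iyy,Ixy second moments of area about the centroid, um^4
#'   (`Ixx = int y^2 dA`, `Iyy = int x^2 dA`, `Ixy = int xy dA`).
#' @export
setClass("SectionProperties",
  representation(A = "numeric", centroid = "numeric",
                 Ixx = "numeric", Iyy = "numeric", Ixy = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@A <= 0) msg <- c(msg, "A must be positive")
    if (object@Ixx <= 0 || object@Iyy <= 0)
      msg <- c(msg, "Ixx and Iyy must be positive")
    if (object@Ixx * object@Iyy - object@Ixy^2 <= 0)
      msg <- c(msg, "inertia tensor must be positive definite")
    if (length(object@centroid) != 2L) msg <- c(msg, "centroid must have length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Axial load case for the tibia cross section
#'
#' Peak compressive load applied at the tibial plateau. The tibia carries a
#' fixed share of the applied load (default 90%, the rest through the
#' fibula); the load point's in-plane offset from the section centroid
#' generates the bending moments.
#'
#' @slot peakLoad applied peak compressive load F in newtons (>= 0).
#' @slot loadPoint (x, y) load position in micrometres.
#' @slot tibialShare fraction of F carried by the tibia (default 0.9).
#' @slot youngsModulus Young's modulus of cortical bone in Pa
#'   (default 14.8e9).
#' @export
setClass("LoadCase",
  representation(peakLoad = "numeric", loadPoint = "numeric",
                 tibialShare = "numeric", youngsModulus = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@peakLoad < 0) msg <- c(msg, "peakLoad must be >= 0")
    if (length(object@loadPoint) != 2L) msg <- c(msg, "loadPoint must have length 2")
    if (object@tibialShare <= 0 || object@tibialShare > 1)
      msg <- c(msg, "tibialShare must be in (0, 1]")
    if (object@youngsModulus <= 0) msg <- c(msg, "youngsModulus must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Mechanostat model parameters
#'
#' Thresholds and rates of the piecewise-linear mechanostat. The four model
#' classes tie the formation rates and thresholds together:
#' \describe{
#'   \item{M1}{one formation rate, one threshold
#'     (`kPT = kPC = kET = kEC`, `epsHomP = epsHomE`).}
#'   \item{M2}{rates split by strain direction
#'     (`kPT = kET`, `kPC = kEC`), one threshold.}
#'   \item{M3}{rates split by surface (`kPT = kPC`, `kET = kEC`),
#'     surface-specific thresholds.}
#'   \item{M4}{all four rates free, surface-specific thresholds.}
#' }
#' `kSN` is the constant endosteal resorption rate induced by sciatic
#' neurectomy; it acts on every simulated day.
#'
#' @slot modelId one of "M1", "M2", "M3", "M4".
#' @slot epsHomP,epsHomE homeostatic (lazy-zone) strain thresholds for the
#'   periosteal and endosteal surface, in microstrain.
#' @slot kPT,kPC,kET,kEC formation rates in um/day per unit normalised
#'   strain, for periosteal/endosteal surfaces under tension/compression.
#' @slot kSN endosteal resorption rate magnitude in um/day.
#' @export
setClass("MechanostatParams",
  representation(modelId = "character",
                 epsHomP = "numeric", epsHomE = "numeric",
                 kPT = "numeric", kPC = "numeric",
                 kET = "numeric", kEC = "numeric",
                 kSN = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@modelId %in% c("M1", "M2", "M3", "M4"))
      msg <- c(msg, "modelId must be one of M1..M4")
    if (object@epsHomP <= 0 || object@epsHomE <= 0)
      msg <- c(msg, "strain thresholds must be positive")
    r <- c(object@kPT, object@kPC, object@kET, object@kEC)
    if (any(r < 0)) msg <- c(msg, "formation rates must be >= 0")
    if (object@kSN < 0) msg <- c(msg, "kSN must be >= 0")
    eq <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-12))
    if (object@modelId == "M1" &&
        !(eq(object@kPT, object@kPC) && eq(object@kPT, object@kET) &&
          eq(object@kPT, object@kEC) && eq(object@epsHomP, object@epsHomE)))
      msg <- c(msg, "M1 requires a single rate and a single threshold")
    if (object@modelId == "M2" &&
        !(eq(object@kPT, object@kET) && eq(object@kPC, object@kEC) &&
          eq(object@epsHomP, object@epsHomE)))
      msg <- c(msg, "M2 requires kPT = kET, kPC = kEC and a single threshold")
    if (object@modelId == "M3" &&
        !(eq(object@kPT, object@kPC) && eq(object@kET, object@kEC)))
      msg <- c(msg, "M3 requires kPT = kPC and kET = kEC")
    if (is.null(msg)) TRUE else msg
  })

#' Day-by-day simulation schedule
#'
#' The loading protocol as simulated: an initial disuse phase with sciatic
#' neurectomy (SN) only, a loading phase in which the mechanostat sees the
#' peak load every day, and a final SN-only phase. Defaults follow the
#' 5 + 14 + 2 = 21 day protocol of the mouse tibia loading experiment.
#'
#' @slot dt time step in days.
#' @slot snPre,loadingDays,snPost phase lengths in days.
#' @slot load the [LoadCase-class] applied on loading days.
#' @export
setClass("SimulationSchedule",
  representation(dt = "numeric", snPre = "numeric",
                 loadingDays = "numeric", snPost = "numeric",
                 load = "LoadCase"),
  validity = function(object) {
    msg <- NULL
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (any(c(object@snPre, object@loadingDays, object@snPost) < 0))
      msg <- c(msg, "phase lengths must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Per-point adaptation measurement with group statistics
#'
#' One adaptation measure (periosteal or endosteal surface movement, or
#' cortical thickness change) on a shared normalised-position grid, with the
#' per-animal values, group mean and SD, and a per-point one-sample t test
#' against zero. Positive values denote bone formation (cortex thickening)
#' on both surfaces.
#'
#' @slot measure one of "deltaEtaP", "deltaEtaE", "deltaCtTh".
#' @slot P shared normalised-position grid.
#' @slot perMouse animals x points matrix of individual measurements (um).
#' @slot mean,sd group mean and standard deviation per point (um).
#' @slot p two-sided p value of the per-point one-sample t test.
#' @slot significant logical flag, `p < alpha`.
#' @slot alpha significance level used.
#' @export
setClass("AdaptationMeasurement",
  representation(measure = "character", P = "numeric", perMouse = "matrix",
                 mean = "numeric", sd = "numeric", p = "numeric",
                 significant = "logical", alpha = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@measure %in% c("deltaEtaP", "deltaEtaE", "deltaCtTh"))
      msg <- c(msg, "unknown measure label")
    k <- length(object@P)
    if (length(object@mean) != k || length(object@sd) != k)
      msg <- c(msg, "mean/sd must match the P grid")
    if (is.null(msg)) TRUE else msg
  })

#' Result of a staged grid-search calibration
#'
#' @slot params best-fitting [MechanostatParams-class].
#' @slot rms named numeric: RMS error (um) on the periosteal ("P") and
#'   endosteal ("E") surfaces and their concatenation ("C"), at the best
#'   candidate.
#' @slot log data frame with one row per evaluated candidate (stage, rates,
#'   RMS errors).
#' @slot stageBest data frame of the winning candidate per stage.
#' @export
setClass("MechanostatFit",
  representation(params = "MechanostatParams", rms = "numeric",
                 log = "data.frame", stageBest = "data.frame"))
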