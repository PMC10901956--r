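# Mechanostat rate laws and forward-Euler surface evolution.

#' Normalised strain difference
#'
#' The super-threshold stimulus `(|eps| - epsHom) / epsHom` that multiplies
#' a formation rate. The magnitude of the strain is used so that
#' super-threshold compression, like super-threshold tension, yields a
#' positive stimulus and hence bone formation. Must only be called outside
#' the lazy zone; the rate law gates sub-threshold strains to zero before
#' this quantity is ever formed.
#'
#' @param eps longitudinal strain in microstrain (signed).
#' @param epsHom homeostatic threshold in microstrain (> 0).
#' @return normalised strain difference (dimensionless, > 0).
#' @export
normalizedStrain <- function(eps, epsHom) {
  if (epsHom <= 0) stop("epsHom must be positive")
  if (any(abs(eps) <= epsHom))
    stop("normalizedStrain called inside the lazy zone; gate with the rate law")
  (abs(eps) - epsHom) / epsHom
}

# Internal vectorised rate laws (um/day). params is a plain list with
# epsHomP, epsHomE, kPT, kPC, kET, kEC, kSN.
.ratePeriosteal <- function(eps, params) {
  out <- numeric(length(eps))
  iT <- eps > params$epsHomP
  iC <- eps < -params$epsHomP
  out[iT] <- (eps[iT] - params$epsHomP) / params$epsHomP * params$kPT
  out[iC] <- (-eps[iC] - params$epsHomP) / params$epsHomP * params$kPC
  out
}

.rateEndosteal <- function(eps, params) {
  out <- rep(-params$kSN, length(eps))
  iT <- eps > params$epsHomE
  iC <- eps < -params$epsHomE
  out[iT] <- out[iT] + (eps[iT] - params$epsHomE) / params$epsHomE * params$kET
  out[iC] <- out[iC] + (-eps[iC] - params$epsHomE) / params$epsHomE * params$kEC
  out
}

.paramsAsList <- function(params) {
  list(epsHomP = params@epsHomP, epsHomE = params@epsHomE,
       kPT = params@kPT, kPC = params@kPC,
       kET = params@kET, kEC = params@kEC, kSN = params@kSN)
}

#' Mechanostat surface rate
#'
#' Piecewise-linear net adaptation rate for one surface: zero (periosteum)
#' or the constant disuse resorption `-kSN` (endosteum) inside the lazy
#' zone, and the normalised strain difference times the direction-specific
#' formation rate beyond it. The threshold itself belongs to the lazy zone.
#'
#' @param eps longitudinal strain in microstrain (vectorised, signed;
#'   negative = compression).
#' @param params a [MechanostatParams-class].
#' @param surface `"periosteal"` or `"endosteal"`.
#' @return net adaptation rate in um/day (positive = formation).
#' @examples
#' p <- mechanostatParams("M4", kPT = 2.148, kPC = 0.981,
#'                        kET = 7.055, kEC = 0.794)
#' surfaceRate(0, p, "endosteal")      # disuse resorption, -1.398
#' surfaceRate(2 * 2785, p, "periosteal")  # = kPT
#' @export
surfaceRate <- function(eps, params, surface = c("periosteal", "endosteal")) {
  surface <- match.arg(surface)
  pl <- .paramsAsList(params)
  if (surface == "periosteal") .ratePeriosteal(eps, pl)
  else .rateEndosteal(eps, pl)
}

# Internal: unit normals in the formation direction for a clockwise vertex
# matrix. Normals are perpendicular to the chord between the two cyclic
# neighbours of each point. For a clockwise ring the outward direction is
# (-ty, tx); the endosteal formation direction points the other way,
# toward the marrow.
.formationNormals <- function(pts, surface) {
  n <- nrow(pts)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  tx <- pts[ip, 1L] - pts[im, 1L]
  ty <- pts[ip, 2L] - pts[im, 2L]
  len <- sqrt(tx^2 + ty^2)
  if (any(len == 0)) stop("coincident neighbouring points; cannot form normal")
  n <- cbind(-ty, tx) / len
  if (surface == "endosteal") -n else n
}

#' Formation-direction unit normals of a contour
#'
#' Per-point unit vectors perpendicular to the chord joining each point's
#' neighbours, oriented in the direction bone formation moves the surface:
#' outward from the bone for the periosteum, toward the marrow for the
#' endosteum.
#'
#' @param contour a resampled [SurfaceContour-class].
#' @return n x 2 matrix of unit vectors.
#' @export
surfaceNormals <- function(contour) {
  .formationNormals(contourCoords(contour), surfaceLabel(contour))
}

# One forward-Euler day. state: list(peri, endo) of clockwise vertex
# matrices. Returns the updated state plus the day's audit row.
.stepCore <- function(state, F, loadPoint, share, E, params, dt, n,
                      check = TRUE) {
  props <- .sectionPropsCore(state$peri, state$endo)
  epsP <- .flexureCore(state$peri, props, F, share, loadPoint, E) * 1e6
  epsE <- .flexureCore(state$endo, props, F, share, loadPoint, E) * 1e6
  MP <- .ratePeriosteal(epsP, params)
  ME <- .rateEndosteal(epsE, params)
  peri <- state$peri + MP * .formationNormals(state$peri, "periosteal") * dt
  endo <- state$endo + ME * .formationNormals(state$endo, "endosteal") * dt
  peri <- .resampleRing(peri, n)
  endo <- .resampleRing(endo, n)
  if (.signedArea(peri) >= 0 || .signedArea(endo) >= 0)
    stop("surface degenerated (non-negative signed area) after update")
  if (check && any(!.pointsInPolygon(peri, endo)))
    stop("surfaces self-intersect or cross after update")
  list(state = list(peri = peri, endo = endo),
       audit = c(A = props$A, Ixx = props$Ixx, Iyy = props$Iyy,
                 Ixy = props$Ixy,
                 epsPmin = min(epsP), epsPmax = max(epsP),
                 epsEmin = min(epsE), epsEmax = max(epsE),
                 Mmax = max(abs(c(MP, ME)))))
}

# Full schedule on plain matrices; loads is the per-day peak load vector.
# With check = "end" the (relatively costly) mutual-containment test runs
# once on the endpoint instead of every day; the cheap per-day degeneracy
# test always runs.
.simulateCore <- function(peri, endo, params, loads, loadPoint, share, E,
                          dt, n, check = TRUE, audit = FALSE) {
  state <- list(peri = .resampleRing(peri, n), endo = .resampleRing(endo, n))
  rows <- if (audit) vector("list", length(loads)) else NULL
  perStep <- isTRUE(check)
  for (d in seq_along(loads)) {
    st <- .stepCore(state, loads[d], loadPoint, share, E, params, dt, n,
                    check = perStep)
    state <- st$state
    if (audit) rows[[d]] <- st$audit
  }
  if (identical(check, "end") && any(!.pointsInPolygon(state$peri, state$endo)))
    stop("surfaces crossed during simulation")
  list(peri = state$peri, endo = state$endo,
       audit = if (audit) as.data.frame(do.call(rbind, rows)) else NULL)
}

.scheduleLoads <- function(schedule) {
  stepsPer <- function(days) round(days / schedule@dt)
  c(rep(0, stepsPer(schedule@snPre)),
    rep(schedule@load@peakLoad, stepsPer(schedule@loadingDays)),
    rep(0, stepsPer(schedule@snPost)))
}

#' One day of the adaptation algorithm
#'
#' Executes the four-stage loop once: section properties, flexure strains,
#' mechanostat rates, and the forward-Euler update of both surfaces along
#' their formation normals, followed by re-resampling to uniform arc
#' length.
#'
#' @param periosteal,endosteal resampled [SurfaceContour-class] pair.
#' @param params a [MechanostatParams-class].
#' @param load the day's [LoadCase-class] (use `peakLoad = 0` for
#'   SN-only days).
#' @param dt time step in days.
#' @param n number of resampled points kept per surface.
#' @return list with the updated `periosteal` and `endosteal` contours and
#'   an `audit` vector of the day's section properties and strain extrema.
#' @export
adaptationStep <- function(periosteal, endosteal, params, load, dt = 1,
                           n = nrow(contourCoords(periosteal))) {
  st <- .stepCore(list(peri = contourCoords(periosteal),
                       endo = contourCoords(endosteal)),
                  load@peakLoad, load@loadPoint, load@tibialShare,
                  load@youngsModulus, .paramsAsList(params), dt, n)
  list(periosteal = new("SurfaceContour", coords = st$state$peri,
                        surface = "periosteal", limb = limbLabel(periosteal),
                        P = (seq_len(n) - 1) / n),
       endosteal = new("SurfaceContour", coords = st$state$endo,
                       surface = "endosteal", limb = limbLabel(endosteal),
                       P = (seq_len(n) - 1) / n),
       audit = st$audit)
}

#' Simulate cortical adaptation over a load schedule
#'
#' Runs the day-by-day adaptation algorithm over the full schedule
#' (disuse-only days, loading days, final disuse days) from a baseline
#' contour pair. The simulation is a deterministic function of its inputs.
#'
#' @param periosteal,endosteal baseline [SurfaceContour-class] pair in the
#'   registered frame.
#' @param params a [MechanostatParams-class].
#' @param schedule a [SimulationSchedule-class].
#' @param n points per surface carried through the simulation.
#' @param audit keep a per-day audit trail of section properties and strain
#'   extrema.
#' @return list with endpoint `periosteal` and `endosteal` contours and the
#'   `audit` data frame (or `NULL`).
#' @export
simulateAdaptation <- function(periosteal, endosteal, params, schedule,
                               n = 500L, audit = TRUE) {
  load <- schedule@load
  res <- .simulateCore(contourCoords(periosteal), contourCoords(endosteal),
                       .paramsAsList(params), .scheduleLoads(schedule),
                       load@loadPoint, load@tibialShare, load@youngsModulus,
                       schedule@dt, n, audit = audit)
  list(periosteal = new("SurfaceContour", coords = res$peri,
                        surface = "periosteal", limb = limbLabel(periosteal),
                        P = (seq_len(n) - 1) / n),
       endosteal = new("SurfaceContour", coords = res$endo,
                       surface = "endosteal", limb = limbLabel(endosteal),
                       P = (seq_len(n) - 1) / n),
       audit = res$audit)
}
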