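# Staged full-factorial grid-search calibration of mechanostat rates.

#' Define one grid-search stage
#'
#' A stage is either absolute (`lo`/`hi` bounds in um/day) or relative
#' (`delta`, a half-width applied around the previous stage's best value).
#'
#' @param stageId label such as "S0".
#' @param lo,hi inclusive absolute bounds (um/day); used when `delta` is
#'   `NULL`.
#' @param delta half-width around the carried-forward best value.
#' @param increment grid increment (um/day, > 0).
#' @return a list of class `GridStage`.
#' @export
gridStage <- function(stageId, lo = NULL, hi = NULL, delta = NULL,
                      increment) {
  if (increment <= 0) stop("increment must be positive")
  if (is.null(delta) && (is.null(lo) || is.null(hi)))
    stop("either absolute bounds or a delta must be given")
  structure(list(stageId = stageId, lo = lo, hi = hi, delta = delta,
                 increment = increment), class = "GridStage")
}

#' The published four-stage optimisation protocol
#'
#' Stage S0 sweeps each free rate from 0 to 20 um/day (0 to 8 um/day for
#' the four-parameter model M4) in 0.5 um/day steps; stages S1-S3 refine
#' around the carried-forward best at +/- 0.5, 0.05 and 0.005 um/day with
#' increments 0.1, 0.01 and 0.001 um/day.
#'
#' @param modelId "M1".."M4".
#' @return list of four [gridStage()] objects.
#' @export
tableStages <- function(modelId) {
  hi0 <- if (modelId == "M4") 8 else 20
  list(S0 = gridStage("S0", lo = 0, hi = hi0, increment = 0.5),
       S1 = gridStage("S1", delta = 0.5, increment = 0.1),
       S2 = gridStage("S2", delta = 0.05, increment = 0.01),
       S3 = gridStage("S3", delta = 0.005, increment = 0.001))
}

#' Budget version of the staged protocol
#'
#' A coarsened absolute S0 sweep (default 0 to 2 um/day in 0.5 um/day
#' steps, i.e. at most 5^4 candidates for M4) followed by the standard
#' S1-S3 refinement stages. Intended for validation studies where truth
#' rates are known to be small; the full [tableStages()] protocol remains
#' the default for calibration.
#'
#' @param modelId "M1".."M4".
#' @param hi upper bound of the coarse sweep (um/day).
#' @param increment coarse increment (um/day).
#' @return list of four [gridStage()] objects.
#' @export
budgetStages <- function(modelId, hi = 2, increment = 0.5) {
  list(S0 = gridStage("S0", lo = 0, hi = hi, increment = increment),
       S1 = gridStage("S1", delta = 0.5, increment = 0.1),
       S2 = gridStage("S2", delta = 0.05, increment = 0.01),
       S3 = gridStage("S3", delta = 0.005, increment = 0.001))
}

.freeNames <- function(modelId) {
  switch(modelId,
         M1 = "k",
         M2 = c("kT", "kC"),
         M3 = c("kP", "kE"),
         M4 = c("kPT", "kPC", "kET", "kEC"))
}

.mapFree <- function(modelId, free) {
  # free: matrix with one column per free parameter
  switch(modelId,
    M1 = cbind(kPT = free[, 1L], kPC = free[, 1L],
               kET = free[, 1L], kEC = free[, 1L]),
    M2 = cbind(kPT = free[, 1L], kPC = free[, 2L],
               kET = free[, 1L], kEC = free[, 2L]),
    M3 = cbind(kPT = free[, 1L], kPC = free[, 1L],
               kET = free[, 2L], kEC = free[, 2L]),
    M4 = cbind(kPT = free[, 1L], kPC = free[, 2L],
               kET = free[, 3L], kEC = free[, 4L]))
}

#' Enumerate the candidate rate combinations of a stage
#'
#' Builds the full-factorial grid over the model's free parameters; tied
#' parameters are swept in tandem. Relative stages are centred on
#' `centre`; candidate values below zero are dropped (rates are
#' non-negative).
#'
#' @param modelId "M1".."M4".
#' @param stage a [gridStage()].
#' @param centre named numeric of free-parameter values carried forward
#'   from the previous stage (required for relative stages).
#' @return data frame with the four mapped rate columns `kPT`, `kPC`,
#'   `kET`, `kEC`; the free-parameter values are kept in the attribute
#'   `"free"`.
#' @export
enumerateStage <- function(modelId, stage, centre = NULL) {
  fn <- .freeNames(modelId)
  valsFor <- function(f) {
    if (is.null(stage$delta)) {
      v <- stage$lo + stage$increment *
        (0:round((stage$hi - stage$lo) / stage$increment))
    } else {
      if (is.null(centre)) stop("relative stage needs a centre")
      m <- round(stage$delta / stage$increment)
      v <- centre[[f]] + stage$increment * (-m:m)
    }
    v <- v[v >= -1e-12]
    v[v < 0] <- 0
    if (length(v) == 0L) stop("empty candidate range for ", f)
    v
  }
  free <- as.matrix(expand.grid(lapply(stats::setNames(fn, fn), valsFor),
                                KEEP.OUT.ATTRS = FALSE))
  out <- as.data.frame(.mapFree(modelId, free))
  attr(out, "free") <- free
  attr(out, "stageId") <- stage$stageId
  out
}

#' Root-mean-square error between simulated and measured adaptation
#'
#' Per-surface RMS of the per-point difference between simulated and
#' experimental adaptation fields, plus the combined RMS over the
#' concatenation of both surfaces.
#'
#' @param sim,exp lists with numeric fields `periosteal` and `endosteal`
#'   on the same P grid.
#' @return named numeric `c(P, E, C)` in um.
#' @export
rmsError <- function(sim, exp) {
  if (length(sim$periosteal) != length(exp$periosteal) ||
      length(sim$endosteal) != length(exp$endosteal))
    stop("simulated and experimental fields differ in length")
  dP <- sim$periosteal - exp$periosteal
  dE <- sim$endosteal - exp$endosteal
  c(P = sqrt(mean(dP^2)), E = sqrt(mean(dE^2)),
    C = sqrt(mean(c(dP, dE)^2)))
}

#' Calibrate mechanostat formation rates by staged grid search
#'
#' For every candidate rate combination of every stage, runs the full
#' forward simulation from the baseline, measures the simulated adaptation
#' fields against the baseline with the signed minimum-distance method,
#' and scores them against the target fields by combined RMS error. The
#' best candidate (ties broken by the lexicographically smallest rate
#' vector) seeds the next stage. Thresholds and the disuse resorption rate
#' are held fixed throughout.
#'
#' @param modelId "M1".."M4".
#' @param baseline list with the baseline `periosteal` and `endosteal`
#'   [SurfaceContour-class] pair (canonical frame).
#' @param schedule a [SimulationSchedule-class] carrying the calibration
#'   load case.
#' @param target list with measured `periosteal` and `endosteal` adaptation
#'   fields (um) on the resampled P grid.
#' @param stages list of [gridStage()] objects (default [tableStages()]).
#' @param epsHomP,epsHomE fixed thresholds; defaults are the single 1100
#'   microstrain threshold for M1/M2 and 2785/1100 for M3/M4.
#' @param kSN fixed endosteal disuse resorption rate (um/day).
#' @param n contour points per surface (defaults to the target length).
#' @return a [MechanostatFit-class].
#' @export
optimizeRates <- function(modelId, baseline, schedule, target,
                          stages = tableStages(modelId),
                          epsHomP = NULL, epsHomE = NULL, kSN = 1.398,
                          n = length(target$periosteal)) {
  if (is.null(epsHomE)) epsHomE <- 1100
  if (is.null(epsHomP)) epsHomP <- if (modelId %in% c("M1", "M2")) epsHomE else 2785
  # baselines already resampled to n points are used verbatim, so that the
  # candidate simulations share the target's measurement grid exactly
  takeRing <- function(ct) {
    if (length(positionGrid(ct)) == n) contourCoords(ct)
    else .resampleRing(contourCoords(ct), n)
  }
  basePeri <- takeRing(baseline$periosteal)
  baseEndo <- takeRing(baseline$endosteal)
  densePeri <- .densifyRing(basePeri, 4L)
  denseEndo <- .densifyRing(baseEndo, 4L)
  load <- schedule@load
  loads <- .scheduleLoads(schedule)
  scoreCandidate <- function(k) {
    params <- list(epsHomP = epsHomP, epsHomE = epsHomE,
                   kPT = k[1L], kPC = k[2L], kET = k[3L], kEC = k[4L],
                   kSN = kSN)
    res <- tryCatch(
      .simulateCore(basePeri, baseEndo, params, loads, load@loadPoint,
                    load@tibialShare, load@youngsModulus, schedule@dt, n,
                    check = "end"),
      error = function(e) NULL)
    if (is.null(res)) return(c(NA_real_, NA_real_, NA_real_))
    dP <- .minDistToSet(res$peri, densePeri) *
      (1 - 2 * .pointsInPolygon(basePeri, res$peri))
    dE <- .minDistToSet(res$endo, denseEndo) *
      (2 * .pointsInPolygon(baseEndo, res$endo) - 1)
    rmsError(list(periosteal = dP, endosteal = dE), target)
  }
  logRows <- list()
  centre <- NULL
  stageBest <- list()
  for (st in stages) {
    cand <- enumerateStage(modelId, st, centre)
    free <- attr(cand, "free")
    sc <- t(apply(as.matrix(cand), 1L, scoreCandidate))
    colnames(sc) <- c("rmsP", "rmsE", "rmsC")
    stLog <- data.frame(stage = st$stageId, cand, sc)
    logRows[[st$stageId]] <- stLog
    ok <- which(is.finite(sc[, "rmsC"]))
    if (length(ok) == 0L) stop("no candidate simulation succeeded in ",
                               st$stageId)
    ordArgs <- c(list(sc[ok, "rmsC"]),
                 lapply(seq_len(ncol(cand)), function(j) cand[ok, j]))
    best <- ok[do.call(order, ordArgs)[1L]]
    centre <- free[best, , drop = TRUE]
    names(centre) <- colnames(free)
    stageBest[[st$stageId]] <- stLog[best, ]
  }
  bestRow <- stageBest[[length(stageBest)]]
  params <- mechanostatParams(modelId, kPT = bestRow$kPT, kPC = bestRow$kPC,
                              kET = bestRow$kET, kEC = bestRow$kEC,
                              epsHomP = epsHomP, epsHomE = epsHomE,
                              kSN = kSN)
  new("MechanostatFit", params = params,
      rms = c(P = bestRow$rmsP, E = bestRow$rmsE, C = bestRow$rmsC),
      log = do.call(rbind, c(logRows, make.row.names = FALSE)),
      stageBest = do.call(rbind, c(stageBest, make.row.names = FALSE)))
}
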