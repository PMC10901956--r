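# Scoring of simulated endpoints against measured adaptation.

#' Fraction of accurately predicted points
#'
#' The fraction of points whose simulated value lies within `band` of the
#' experimental value. The default band equals the working image
#' resolution (9.56 um) for surface fields; thickness comparisons
#' conventionally use twice that (19.12 um).
#'
#' @param sim,exp numeric fields on a shared P grid (um).
#' @param band accuracy half-width in um.
#' @return fraction in [0, 1].
#' @export
predictionAccuracy <- function(sim, exp, band = 9.56) {
  if (length(sim) == 0L || length(sim) != length(exp))
    stop("fields must be non-empty and of equal length")
  if (band <= 0) stop("band must be positive")
  mean(abs(sim - exp) <= band)
}

#' Regional summary at anatomical stations
#'
#' Extracts an adaptation measure at the four standard stations of the
#' registered midshaft frame (P = 0.27 lateral, 0.46 anterior, 0.68
#' medial, 0.99 posterior), reporting the experimental mean and SD and,
#' when given, the simulated point value at the grid point nearest each
#' station.
#'
#' @param measurement an [AdaptationMeasurement-class].
#' @param sim optional simulated field on the same P grid (um).
#' @param stations normalised positions in [0, 1).
#' @return data frame with columns `station`, `P`, `mean`, `sd` and
#'   (optionally) `sim`.
#' @export
regionalSummary <- function(measurement, sim = NULL,
                            stations = c(0.27, 0.46, 0.68, 0.99)) {
  if (any(stations < 0 | stations >= 1))
    stop("stations must lie in [0, 1)")
  P <- positionGrid(measurement)
  idx <- vapply(stations, function(s) which.min(abs(P - s)), integer(1))
  out <- data.frame(station = stations, P = P[idx],
                    mean = fieldMean(measurement)[idx],
                    sd = fieldSD(measurement)[idx])
  if (!is.null(sim)) out$sim <- sim[idx]
  out
}
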