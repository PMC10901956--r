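# Reading and writing slices, contours and metadata.

#' Write a binary slice as an 8-bit PNG with a JSON sidecar
#'
#' Bone pixels are written as 255, background as 0. The sidecar
#' (`<path>.json`) records the pixel size, origin and any extra metadata,
#' so a slice round-trips exactly.
#'
#' @param slice a [BinarySlice-class].
#' @param path output PNG path.
#' @param meta named list of extra metadata (limb, mouse id, load, seed,
#'   ...).
#' @return the path, invisibly.
#' @export
writeSlice <- function(slice, path, meta = list()) {
  g <- sliceGrid(slice)
  # PNG rows run top-down; store y as rows flipped so that the image looks
  # y-up, and undo this on read
  img <- t(g[, rev(seq_len(ncol(g))), drop = FALSE]) + 0
  png::writePNG(img, path)
  sidecar <- c(list(pixel_size_um = pixelSize(slice),
                    origin_um = slice@origin,
                    dim = dim(g)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binary slice written by [writeSlice()]
#'
#' @param path PNG path with an accompanying `<path>.json` sidecar.
#' @return a [BinarySlice-class]; the sidecar metadata is attached as the
#'   attribute `"meta"`.
#' @export
readSlice <- function(path) {
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(sidecarPath))
    stop("missing sidecar JSON for slice: ", sidecarPath)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  g <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE] > 0.5
  slice <- binarySlice(g, meta$pixel_size_um, meta$origin_um)
  attr(slice, "meta") <- meta
  slice
}

#' Write contours to CSV
#'
#' One row per point with columns `surface`, `limb`, `P`, `x_um`, `y_um`.
#'
#' @param contours a [SurfaceContour-class] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeContours <- function(contours, path) {
  if (is(contours, "SurfaceContour")) contours <- list(contours)
  df <- do.call(rbind, lapply(contours, function(ct) {
    pts <- contourCoords(ct)
    data.frame(surface = surfaceLabel(ct), limb = limbLabel(ct),
               P = if (length(positionGrid(ct))) positionGrid(ct) else NA_real_,
               x_um = pts[, 1L], y_um = pts[, 2L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read contours written by [writeContours()]
#'
#' @param path CSV path.
#' @return named list of [SurfaceContour-class] objects, one per
#'   surface/limb combination present.
#' @export
readContours <- function(path) {
  df <- utils::read.csv(path)
  key <- paste(df$surface, df$limb, sep = ".")
  lapply(split(df, key), function(d) {
    if (!anyNA(d$P)) {
      new("SurfaceContour", coords = cbind(d$x_um, d$y_um),
          surface = d$surface[1L], limb = d$limb[1L], P = d$P)
    } else surfaceContour(cbind(d$x_um, d$y_um), d$surface[1L], d$limb[1L])
  })
}

#' Write an adaptation measurement to CSV
#'
#' Per-point rows with columns `measure`, `P`, `mean_um`, `sd_um`, `p`,
#' `significant`.
#'
#' @param measurement an [AdaptationMeasurement-class] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMeasurement <- function(measurement, path) {
  if (is(measurement, "AdaptationMeasurement")) measurement <- list(measurement)
  df <- do.call(rbind, lapply(measurement, function(m) {
    data.frame(measure = m@measure, P = m@P, mean_um = m@mean,
               sd_um = m@sd, p = m@p, significant = m@significant)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
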