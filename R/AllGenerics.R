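#' @rdname BinarySlice-class
#' @param object,x a MechanoCT object.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname BinarySlice-class
#' @export
setGeneric("sliceGrid", function(object) standardGeneric("sliceGrid"))

#' @rdname SurfaceContour-class
#' @export
setGeneric("contourCoords", function(object) standardGeneric("contourCoords"))

#' @rdname SurfaceContour-class
#' @export
setGeneric("surfaceLabel", function(object) standardGeneric("surfaceLabel"))

#' @rdname SurfaceContour-class
#' @export
setGeneric("limbLabel", function(object) standardGeneric("limbLabel"))

#' @rdname SurfaceContour-class
#' @export
setGeneric("positionGrid", function(object) standardGeneric("positionGrid"))

#' @rdname SectionProperties-class
#' @export
setGeneric("sectionArea", function(object) standardGeneric("sectionArea"))

#' @rdname SectionProperties-class
#' @export
setGeneric("sectionCentroid", function(object) standardGeneric("sectionCentroid"))

#' @rdname SectionProperties-class
#' @export
setGeneric("secondMoments", function(object) standardGeneric("secondMoments"))

#' @rdname MechanostatParams-class
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @rdname MechanostatParams-class
#' @export
setGeneric("formationRates", function(object) standardGeneric("formationRates"))

#' @rdname MechanostatParams-class
#' @export
setGeneric("resorptionRate", function(object) standardGeneric("resorptionRate"))

#' @rdname MechanostatParams-class
#' @export
setGeneric("strainThresholds", function(object) standardGeneric("strainThresholds"))

#' @rdname AdaptationMeasurement-class
#' @export
setGeneric("fieldMean", function(object) standardGeneric("fieldMean"))

#' @rdname AdaptationMeasurement-class
#' @export
setGeneric("fieldSD", function(object) standardGeneric("fieldSD"))

#' @rdname AdaptationMeasurement-class
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname MechanostatFit-class
#' @export
setGeneric("bestParams", function(object) standardGeneric("bestParams"))

#' @rdname MechanostatFit-class
#' @export
setGeneric("rmsErrors", function(object) standardGeneric("rmsErrors"))

#' @rdname MechanostatFit-class
#' @export
setGeneric("searchLog", function(object) standardGeneric("searchLog"))
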