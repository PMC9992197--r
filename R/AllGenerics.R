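#' @include AllClasses.R
NULL

#' Canonical region-of-interest names
#'
#' The 26 bilateral cognition-related cortical regions analysed by the
#' pipeline: 13 Desikan-Killiany areas of the default-mode, central
#' executive and salience ("triple") networks, each with a left (.L) and
#' right (.R) hemisphere label. The order returned here is the canonical
#' row order of every ROI-indexed output.
#'
#' @param areas if TRUE return the 13 area abbreviations without
#'   hemisphere suffix.
#' @return character vector of 26 ROI names (or 13 area names).
#' @examples
#' roiNames()[1:4]
#' @export
roiNames <- function(areas = FALSE) {
  ab <- c("CAC", "CMF", "IPL", "IC", "MT", "PaH", "PCC",
          "PCu", "RACC", "RMF", "SF", "ST", "SM")
  if (areas) return(ab)
  as.vector(t(outer(ab, c(".L", ".R"), paste0)))
}

#' Approximate triple-network membership of the ROI areas
#'
#' Coarse default-mode (DMN) / central-executive (CEN) / salience (SN)
#' assignment of the 13 areas, used only as reporting metadata.
#'
#' @return named character vector keyed by area abbreviation.
#' @export
roiNetworks <- function() {
  c(CAC = "SN", CMF = "CEN", IPL = "CEN", IC = "SN", MT = "DMN",
    PaH = "DMN", PCC = "DMN", PCu = "DMN", RACC = "DMN", RMF = "CEN",
    SF = "DMN", ST = "DMN", SM = "CEN")
}

#' @rdname SensorArray-class
#' @param object,x a megpower object.
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))
#' @rdname SensorArray-class
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
#' @rdname SensorArray-class
#' @export
setGeneric("sensorOrientations", function(x) standardGeneric("sensorOrientations"))
#' @rdname SensorArray-class
#' @export
setGeneric("sensorIds", function(x) standardGeneric("sensorIds"))

#' @rdname SourceSpace-class
#' @param x a megpower object.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname SourceSpace-class
#' @export
setGeneric("vertexPositions", function(x) standardGeneric("vertexPositions"))
#' @rdname SourceSpace-class
#' @export
setGeneric("vertexNormals", function(x) standardGeneric("vertexNormals"))
#' @rdname SourceSpace-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname Recording-class
#' @param x a megpower object.
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname Recording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname Recording-class
#' @export
setGeneric("sensorArray", function(x) standardGeneric("sensorArray"))
#' @rdname Recording-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname LeadField-class
#' @param x a megpower object.
#' @export
setGeneric("gainMatrix", function(x) standardGeneric("gainMatrix"))
#' @rdname NoiseCovariance-class
#' @param x a megpower object.
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))
#' @rdname InverseOperator-class
#' @param x a megpower object.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))
#' @rdname InverseOperator-class
#' @export
setGeneric("depthWeightValues", function(x) standardGeneric("depthWeightValues"))

#' @rdname BandScheme-class
#' @param x a megpower object.
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname BandScheme-class
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))

#' @rdname RelativePowerTable-class
#' @param x a megpower object.
#' @export
setGeneric("powerValues", function(x) standardGeneric("powerValues"))

#' @rdname StatReport-class
#' @param x a megpower object.
#' @export
setGeneric("statTests", function(x) standardGeneric("statTests"))
#' @rdname StatReport-class
#' @export
setGeneric("statCorrelations", function(x) standardGeneric("statCorrelations"))

setMethod("nSensors", "SensorArray", function(x) nrow(x@positions))
setMethod("sensorPositions", "SensorArray", function(x) x@positions)
setMethod("sensorOrientations", "SensorArray", function(x) x@orientations)
setMethod("sensorIds", "SensorArray", function(x) x@sensorIds)

setMethod("nVertices", "SourceSpace", function(x) nrow(x@positions))
setMethod("vertexPositions", "SourceSpace", function(x) x@positions)
setMethod("vertexNormals", "SourceSpace", function(x) x@normals)
setMethod("vertexLabels", "SourceSpace", function(x) x@labels)

setMethod("recordingData", "Recording", function(x) x@data)
setMethod("samplingRate", "Recording", function(x) x@rate)
setMethod("nSamples", "Recording", function(x) ncol(x@data))
setMethod("sensorArray", "Recording", function(x) x@array)
setMethod("annotations", "Recording", function(x) x@annotations)

setMethod("gainMatrix", "LeadField", function(x) x@gain)
setMethod("covMatrix", "NoiseCovariance", function(x) x@matrix)
setMethod("kernelMatrix", "InverseOperator", function(x) x@kernel)
setMethod("depthWeightValues", "InverseOperator", function(x) x@weights)

setMethod("bandNames", "BandScheme", function(x) x@name)
setMethod("bandEdges", "BandScheme", function(x)
  data.frame(name = x@name, f_low = x@fLow, f_high = x@fHigh))

setMethod("powerValues", "RelativePowerTable", function(x) x@values)
setMethod("statTests", "StatReport", function(x) x@tests)
setMethod("statCorrelations", "StatReport", function(x) x@correlations)

setMethod("show", "SensorArray", function(object) {
  cat("SensorArray with", nSensors(object), "sensors\n")
  r <- range(.row_norms(object@positions))
  cat(sprintf("  radial distance: %.4f - %.4f m\n", r[1], r[2]))
})

setMethod("show", "SourceSpace", function(object) {
  lab <- object@labels
  cat("SourceSpace with", nVertices(object), "vertices,",
      length(setdiff(unique(lab), "unlabeled")), "ROIs\n")
  sz <- table(lab[lab != "unlabeled"])
  cat(sprintf("  vertices per ROI: %d - %d\n", min(sz), max(sz)))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate))
  if (length(object@annotations))
    cat("  annotations:", paste(names(object@annotations), collapse = ", "), "\n")
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d sensors x %d sources (T per A*m)\n",
              nrow(object@gain), ncol(object@gain)))
})

setMethod("show", "NoiseCovariance", function(object) {
  cat(sprintf("NoiseCovariance: %d channels, shrinkage %.3g\n",
              nrow(object@matrix), object@shrinkage))
})

setMethod("show", "InverseOperator", function(object) {
  cat(sprintf(
    "InverseOperator: %d sources x %d sensors, lambda2 = %g (SNR ~ %.3g)\n",
    nrow(object@kernel), ncol(object@kernel), object@lambda2,
    1 / object@lambda2))
})

setMethod("show", "BandScheme", function(object) {
  cat("BandScheme with", length(object@name), "bands:\n")
  cat(paste0("  ", object@name, " ", object@fLow, "-", object@fHigh, " Hz",
             collapse = "\n"), "\n")
})

setMethod("show", "RelativePowerTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("RelativePowerTable: %d subjects x %d ROIs x %d bands\n",
              d[1], d[2], d[3]))
})

setMethod("show", "StatReport", function(object) {
  cat(sprintf("StatReport: %d tests, %d correlations\n",
              nrow(object@tests), nrow(object@correlations)))
  if (nrow(object@tests)) {
    rej <- subset(object@tests, object@tests$contrast != "omnibus" &
                    object@tests$reject_05)
    cat("  FDR rejections at 0.05 (pairwise):", nrow(rej), "\n")
  }
})
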