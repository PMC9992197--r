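#' @import methods
NULL

.unit_tol <- 1e-9

.row_norms <- function(m) sqrt(rowSums(m^2))

#' SensorArray: MEG magnetometer geometry
#'
#' Positions and orientations of a set of point magnetometers. Orientations
#' are unit vectors; the field reported by a sensor is the projection of the
#' magnetic field (tesla) onto its orientation.
#'
#' @slot sensorIds character vector of channel names.
#' @slot positions numeric matrix (sensors x 3), metres.
#' @slot orientations numeric matrix (sensors x 3), unit vectors.
#' @export
setClass("SensorArray",
  representation(
    sensorIds = "character",
    positions = "matrix",
    orientations = "matrix"
  )
)

setValidity("SensorArray", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (n < 8L) msg <- c(msg, "a sensor array needs at least 8 sensors")
  if (ncol(object@positions) != 3L || ncol(object@orientations) != 3L)
    msg <- c(msg, "positions and orientations must have 3 columns")
  if (nrow(object@orientations) != n)
    msg <- c(msg, "positions and orientations disagree on sensor count")
  if (length(object@sensorIds) != n)
    msg <- c(msg, "sensorIds length must match sensor count")
  if (n > 0 && max(abs(.row_norms(object@orientations) - 1)) > .unit_tol)
    msg <- c(msg, "orientations must be unit vectors")
  if (length(msg)) msg else TRUE
})

#' SourceSpace: cortical source model with ROI labels
#'
#' Discrete dipole locations with outward unit normals (the fixed dipole
#' orientation) and a region-of-interest label per vertex, drawn from the
#' 26 bilateral triple-network regions (see [roiNames()]) or "unlabeled".
#'
#' @slot positions numeric matrix (vertices x 3), metres.
#' @slot normals numeric matrix (vertices x 3), unit vectors.
#' @slot labels character vector, one ROI name (or "unlabeled") per vertex.
#' @export
setClass("SourceSpace",
  representation(
    positions = "matrix",
    normals = "matrix",
    labels = "character"
  )
)

setValidity("SourceSpace", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L || ncol(object@normals) != 3L)
    msg <- c(msg, "positions and normals must have 3 columns")
  if (nrow(object@normals) != n || length(object@labels) != n)
    msg <- c(msg, "normals/labels must match vertex count")
  if (n > 0 && max(abs(.row_norms(object@normals) - 1)) > .unit_tol)
    msg <- c(msg, "normals must be unit vectors")
  missing <- setdiff(roiNames(), unique(object@labels))
  if (length(missing))
    msg <- c(msg, paste0("ROIs with no vertex: ", paste(missing, collapse = ", ")))
  bad <- setdiff(unique(object@labels), c(roiNames(), "unlabeled"))
  if (length(bad))
    msg <- c(msg, paste0("unknown ROI labels: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' HeadSphere: spherical conductor model
#'
#' @slot center numeric(3), metres.
#' @slot radius positive scalar, metres.
#' @export
setClass("HeadSphere",
  representation(center = "numeric", radius = "numeric")
)

setValidity("HeadSphere", function(object) {
  if (length(object@center) != 3L) return("center must be a 3-vector")
  if (length(object@radius) != 1L || object@radius <= 0)
    return("radius must be a positive scalar")
  TRUE
})

#' LeadField: linear forward operator
#'
#' Gain matrix mapping fixed-orientation dipole moments (A*m) at the source
#' vertices to sensor readings (tesla): one column per source, one row per
#' sensor.
#'
#' @slot gain numeric matrix (sensors x sources), tesla per A*m.
#' @slot sphere the [HeadSphere-class] used by the forward model.
#' @export
setClass("LeadField",
  representation(gain = "matrix", sphere = "HeadSphere")
)

setValidity("LeadField", function(object) {
  if (!all(is.finite(object@gain))) return("lead field has non-finite entries")
  TRUE
})

#' Recording: multichannel MEG time series
#'
#' @slot array the [SensorArray-class] the data were recorded with.
#' @slot data numeric matrix (channels x samples), tesla.
#' @slot rate sampling rate, Hz.
#' @slot annotations named list of provenance entries (chosen segment
#'   offset, applied filters, subject id, ...).
#' @export
setClass("Recording",
  representation(
    array = "SensorArray",
    data = "matrix",
    rate = "numeric",
    annotations = "list"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@data) != nSensors(object@array))
    msg <- c(msg, "data row count must equal sensor count")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' NoiseCovariance: sensor noise model
#'
#' Sample covariance of an empty-room recording, shrunk toward its diagonal
#' so the whitener used by the inverse operator exists.
#'
#' @slot matrix symmetric positive-definite matrix (channels x channels), tesla^2.
#' @slot shrinkage scalar in [0, 1] applied toward the diagonal.
#' @export
setClass("NoiseCovariance",
  representation(matrix = "matrix", shrinkage = "numeric")
)

setValidity("NoiseCovariance", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("covariance must be square")
  if (max(abs(m - t(m))) > 1e-10 * max(abs(m), 1e-300))
    return("covariance must be symmetric")
  TRUE
})

#' InverseOperator: depth-weighted minimum-norm kernel
#'
#' Linear kernel K (sources x sensors) such that the source estimate for
#' sensor data b is s-hat = K b; see [buildInverse()] for the convention.
#'
#' @slot kernel numeric matrix (sources x sensors).
#' @slot lambda2 regularization parameter, the reciprocal of the assumed
#'   squared SNR (default 0.33, i.e. SNR about 3).
#' @slot weights per-source depth weights used in the source prior.
#' @export
setClass("InverseOperator",
  representation(kernel = "matrix", lambda2 = "numeric", weights = "numeric")
)

setValidity("InverseOperator", function(object) {
  msg <- character()
  if (!all(is.finite(object@kernel))) msg <- c(msg, "kernel has non-finite entries")
  if (object@lambda2 <= 0) msg <- c(msg, "lambda2 must be > 0")
  if (any(object@weights <= 0)) msg <- c(msg, "depth weights must be > 0")
  if (nrow(object@kernel) != length(object@weights))
    msg <- c(msg, "weights length must equal source count")
  if (length(msg)) msg else TRUE
})

#' BandScheme: ordered analysis frequency bands
#'
#' @slot name unique band names, low to high.
#' @slot fLow,fHigh band edges in Hz; both edges inclusive, except that a
#'   band whose lower edge coincides with the previous band's upper edge
#'   opens exclusively (the shared bin belongs to the lower band).
#' @export
setClass("BandScheme",
  representation(name = "character", fLow = "numeric", fHigh = "numeric")
)

setValidity("BandScheme", function(object) {
  msg <- character()
  if (anyDuplicated(object@name)) msg <- c(msg, "band names must be unique")
  if (length(object@fLow) != length(object@name) ||
      length(object@fHigh) != length(object@name))
    msg <- c(msg, "name/fLow/fHigh lengths differ")
  if (any(object@fLow >= object@fHigh))
    msg <- c(msg, "each band needs fLow < fHigh")
  if (length(object@name) > 1) {
    if (any(diff(object@fLow) <= 0)) msg <- c(msg, "bands must be ordered by frequency")
    if (any(object@fHigh[-length(object@fHigh)] > object@fLow[-1]))
      msg <- c(msg, "bands may share an edge but not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' RelativePowerTable: subject x ROI x band relative spectral power
#'
#' Every value lies in [0, 1]; for each subject and ROI the values sum to 1
#' over bands (each band's share of the total power in the analysed bands).
#'
#' @slot values numeric 3-d array (subject x roi x band) with dimnames.
#' @slot provenance named list recording the settings that produced it.
#' @export
setClass("RelativePowerTable",
  representation(values = "array", provenance = "list")
)

setValidity("RelativePowerTable", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-d array")
  if (is.null(dimnames(v)) || any(vapply(dimnames(v), is.null, logical(1))))
    return("values must carry subject/roi/band dimnames")
  # NA cells are tolerated here (incomplete tables can be stored and
  # inspected); runStats() refuses them with their locations
  if (isTRUE(any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)))
    return("values must lie in [0, 1]")
  sums <- apply(v, c(1, 2), sum)
  if (isTRUE(max(abs(sums - 1), na.rm = TRUE) > 1e-6))
    return("per subject x ROI, band shares must sum to 1")
  TRUE
})

#' StatReport: group-comparison and correlation results
#'
#' @slot tests data.frame, one row per (roi, band, contrast) test with
#'   columns roi, band, contrast, H, p_raw, p_bonf, p_fdr, reject_05,
#'   reject_005 (contrast "omnibus" rows carry the Kruskal-Wallis test).
#' @slot correlations data.frame, one row per (group, clinical variable,
#'   roi, band) correlation with columns group, variable, roi, band, R, p,
#'   p_fdr, method.
#' @slot settings named list (alpha, reporting cut, FDR family, ...).
#' @export
setClass("StatReport",
  representation(tests = "data.frame", correlations = "data.frame",
                 settings = "list")
)

setValidity("StatReport", function(object) {
  need <- c("roi", "band", "contrast", "H", "p_raw", "p_bonf", "p_fdr",
            "reject_05", "reject_005")
  if (!all(need %in% names(object@tests)))
    return(paste0("tests is missing columns: ",
                  paste(setdiff(need, names(object@tests)), collapse = ", ")))
  TRUE
})
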