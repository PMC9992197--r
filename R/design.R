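#' CohortDesign: generative conditions for a synthetic cohort
#'
#' Holds every parameter of the synthetic cohort generator; together with
#' the master seed it fully determines the generated data. See
#' [cohortDesign()] for field semantics and defaults.
#'
#' @slot params named list of generator parameters.
#' @export
setClass("CohortDesign", representation(params = "list"))

.design_required <- c(
  "nPerGroup", "nSensors", "nVertices", "headRadius", "rate", "duration",
  "backgroundExponent", "backgroundComponents", "sourceAmplitude",
  "bandAmplitudes", "sensorNoiseSd", "lineAmplitude", "lineFreq",
  "effects", "seed")

setValidity("CohortDesign", function(object) {
  p <- object@params
  miss <- setdiff(.design_required, names(p))
  if (length(miss))
    return(paste0("missing design fields: ", paste(miss, collapse = ", ")))
  msg <- character()
  if (p$nPerGroup < 1) msg <- c(msg, "nPerGroup must be >= 1")
  if (p$duration <= 0 || p$rate <= 0) msg <- c(msg, "duration and rate must be > 0")
  if (p$duration * p$rate > 5e7) msg <- c(msg, "duration x rate too large")
  if (nrow(p$effects) && any(p$effects$multiplier < 0))
    msg <- c(msg, "effect multipliers must be >= 0")
  if (any(p$bandAmplitudes < 0)) msg <- c(msg, "band amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Default group effect map
#'
#' The generator's built-in ground truth, oriented like the study
#' conditions it emulates: relative to healthy controls (HC), both patient
#' groups get raised delta-band and lowered alpha-band oscillator
#' amplitudes across all 26 triple-network ROIs; the cognitively
#' non-impaired (CNI) group additionally gets raised theta; and both
#' patient groups get a high-band (beta and above) decrease confined to
#' the insula (IC), superior/middle temporal (ST, MT) and parahippocampal
#' (PaH) areas. Multipliers scale oscillator *amplitude* (power scales
#' with their square).
#'
#' @return data.frame with columns group, roi, band, multiplier.
#' @export
defaultEffectMap <- function() {
  allRois <- roiNames()
  highRois <- as.vector(t(outer(c("IC", "ST", "MT", "PaH"),
                                c(".L", ".R"), paste0)))
  highBands <- c("beta", "gamma1", "gamma2", "ripple", "fastripple")
  rbind(
    data.frame(group = "CI", roi = allRois, band = "delta", multiplier = 1.5),
    data.frame(group = "CI", roi = allRois, band = "alpha", multiplier = 0.70),
    data.frame(group = "CI",
               roi = rep(highRois, each = length(highBands)),
               band = rep(highBands, times = length(highRois)),
               multiplier = 0.80),
    data.frame(group = "CNI", roi = allRois, band = "delta", multiplier = 1.25),
    data.frame(group = "CNI", roi = allRois, band = "theta", multiplier = 1.40),
    data.frame(group = "CNI", roi = allRois, band = "alpha", multiplier = 0.75),
    data.frame(group = "CNI",
               roi = rep(highRois, each = length(highBands)),
               band = rep(highBands, times = length(highRois)),
               multiplier = 0.75)
  )
}

#' Construct a cohort design
#'
#' Defaults are desk-scale study conditions: 24 subjects per group (CI,
#' CNI, HC), 64 sensors, 520 shell vertices, 600 Hz sampling and 60 s
#' recordings; the full acquisition scale (275 sensors, 6000 Hz, 120 s,
#' ~15k vertices) is reachable by overriding those fields. Source signals
#' are 1/f background plus band-limited Gaussian oscillators, one per
#' (ROI, band), whose amplitudes the `effects` map scales per group.
#'
#' @param nPerGroup subjects per group (default 24).
#' @param nSensors,nVertices,headRadius geometry sizes (see
#'   [makeSensorArray()], [makeSourceSpace()]).
#' @param rate sampling rate, Hz. @param duration recording length, s.
#' @param backgroundExponent 1/f^a power-law exponent of the background.
#' @param backgroundComponents number of shared spatial background
#'   components mixed into the vertices.
#' @param sourceAmplitude overall dipole moment scale, A*m (time-domain SD
#'   of a unit-multiplier oscillator).
#' @param bandAmplitudes named per-band relative oscillator amplitudes.
#' @param sensorNoiseSd white sensor noise SD, tesla.
#' @param lineAmplitude,lineFreq powerline contamination amplitude (tesla)
#'   and frequency (Hz, default 50).
#' @param effects data.frame(group, roi, band, multiplier); defaults to
#'   [defaultEffectMap()]. An empty data.frame gives a null cohort.
#' @param seed master seed; determines the whole cohort.
#' @return a [CohortDesign-class].
#' @examples
#' d <- cohortDesign(nPerGroup = 2, duration = 10)
#' @export
cohortDesign <- function(nPerGroup = 24,
                         nSensors = 64,
                         nVertices = 520,
                         headRadius = 0.09,
                         rate = 600,
                         duration = 60,
                         backgroundExponent = 1,
                         backgroundComponents = 24,
                         sourceAmplitude = 1e-8,
                         bandAmplitudes = c(delta = 1.0, theta = 0.8,
                                            alpha = 1.0, beta = 0.5,
                                            gamma1 = 0.25, gamma2 = 0.15,
                                            ripple = 0.08, fastripple = 0.05),
                         sensorNoiseSd = 1e-13,
                         lineAmplitude = 5e-13,
                         lineFreq = 50,
                         effects = defaultEffectMap(),
                         seed = 1) {
  rownames(effects) <- NULL
  new("CohortDesign", params = list(
    nPerGroup = nPerGroup, nSensors = nSensors, nVertices = nVertices,
    headRadius = headRadius, rate = rate, duration = duration,
    backgroundExponent = backgroundExponent,
    backgroundComponents = backgroundComponents,
    sourceAmplitude = sourceAmplitude, bandAmplitudes = bandAmplitudes,
    sensorNoiseSd = sensorNoiseSd, lineAmplitude = lineAmplitude,
    lineFreq = lineFreq, effects = effects, seed = seed))
}

#' @rdname CohortDesign-class
#' @param x a CohortDesign.
#' @export
designParams <- function(x) x@params

setMethod("show", "CohortDesign", function(object) {
  p <- object@params
  cat(sprintf(
    "CohortDesign: 3 x %d subjects, %d sensors, %d vertices, %g Hz, %g s\n",
    p$nPerGroup, p$nSensors, p$nVertices, p$rate, p$duration))
  cat(sprintf("  %d effect-map entries, master seed %d\n",
              nrow(p$effects), p$seed))
})

#' Serialize / restore a cohort design as YAML
#'
#' @param design a [CohortDesign-class]. @param path file path.
#' @return `readCohortDesign` returns a [CohortDesign-class].
#' @export
writeCohortDesign <- function(design, path) {
  p <- designParams(design)
  p$effects <- as.list(p$effects)
  p$bandAmplitudes <- as.list(p$bandAmplitudes)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname writeCohortDesign
#' @export
readCohortDesign <- function(path) {
  p <- yaml::read_yaml(path)
  p$effects <- as.data.frame(p$effects)
  if (nrow(p$effects) == 0)
    p$effects <- data.frame(group = character(), roi = character(),
                            band = character(), multiplier = numeric())
  p$bandAmplitudes <- unlist(p$bandAmplitudes)
  do.call(cohortDesign, p)
}

#' Hash of a design or settings list (provenance key)
#' @param x any serializable object.
#' @return character md5 digest.
#' @export
settingsHash <- function(x) {
  if (is(x, "CohortDesign")) x <- designParams(x)
  tf <- tempfile()
  on.exit(unlink(tf))
  # canonical JSON so integer/double storage differences do not matter
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                              dataframe = "columns"), tf)
  unname(tools::md5sum(tf))
}
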