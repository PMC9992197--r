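# Shared small fixtures, built once per test session.

.fx <- new.env(parent = emptyenv())

fx_geometry <- function() {
  if (is.null(.fx$geom)) {
    arr <- makeSensorArray(32, headRadius = 0.09, seed = 7)
    ss <- makeSourceSpace(104, seed = 1)
    sph <- fitSphere(ss)
    lf <- computeLeadField(ss, arr, sph)
    .fx$geom <- list(array = arr, space = ss, sphere = sph, lf = lf)
  }
  .fx$geom
}

# tiny but complete cohort world for pipeline-level tests
fx_world <- function() {
  if (is.null(.fx$world)) {
    design <- cohortDesign(nPerGroup = 2, nSensors = 32, nVertices = 104,
                           duration = 12, seed = 5,
                           effects = data.frame(group = character(),
                                                roi = character(),
                                                band = character(),
                                                multiplier = numeric()))
    p <- designParams(design)
    arr <- makeSensorArray(p$nSensors, p$headRadius, seed = p$seed)
    ss <- makeSourceSpace(p$nVertices, seed = p$seed)
    lf <- computeLeadField(ss, arr, fitSphere(ss))
    er <- simulateEmptyRoom(arr, 30, p$sensorNoiseSd, p$rate, seed = 99)
    ncov <- estimateNoiseCovariance(er)
    inv <- buildInverse(lf, ncov)
    .fx$world <- list(design = design, array = arr, space = ss, lf = lf,
                      emptyRoom = er, ncov = ncov, inv = inv,
                      scheme = bandSchemeForRate(p$rate, warn = FALSE))
  }
  .fx$world
}

# random rotation matrix from a seed
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
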