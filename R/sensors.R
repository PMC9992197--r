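#' Build a quasi-uniform magnetometer helmet
#'
#' Places `count` point magnetometers on an upper spherical cap of radius
#' `headRadius * 1.1` (a helmet standing slightly off the scalp), oriented
#' radially. Placement uses a golden-angle spiral over the cap, so sensors
#' are quasi-uniform; the seed fixes a random azimuthal rotation of the
#' whole helmet.
#'
#' @param count number of sensors (>= 8; default 275, a whole-head array).
#' @param headRadius scalp sphere radius in metres (default 0.09).
#' @param seed integer seed; the same seed always yields the same array.
#' @param capAngle polar half-angle of the helmet cap in degrees
#'   (default 100: the helmet reaches a little below the equator).
#' @return a [SensorArray-class].
#' @examples
#' arr <- makeSensorArray(64, seed = 7)
#' range(sqrt(rowSums(sensorPositions(arr)^2)))  # all ~ 0.099 m
#' @export
makeSensorArray <- function(count = 275, headRadius = 0.09, seed = 7,
                            capAngle = 100) {
  if (count < 8L)
    stop("invalid configuration: a sensor array needs at least 8 sensors, got ",
         count)
  r <- headRadius * 1.1
  set.seed(as.integer(seed))
  phi0 <- stats::runif(1, 0, 2 * pi)
  k <- seq_len(count)
  # uniform in z over the cap, golden-angle azimuth
  zmin <- cos(capAngle * pi / 180)
  z <- zmin + (1 - zmin) * (count - k + 0.5) / count
  golden <- pi * (3 - sqrt(5))
  phi <- phi0 + k * golden
  s <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  dimnames(dirs) <- NULL
  new("SensorArray",
      sensorIds = sprintf("MEG%03d", k),
      positions = dirs * r,
      orientations = dirs)
}
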