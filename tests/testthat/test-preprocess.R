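make_rec <- function(data, rate, arr = NULL) {
  if (is.null(arr)) {
    arr <- makeSensorArray(max(8, nrow(data)), seed = 1)
    # trim to the requested channel count
    arr <- new("SensorArray", sensorIds = sensorIds(arr)[1:nrow(data)],
               positions = sensorPositions(arr)[1:nrow(data), , drop = FALSE],
               orientations = sensorOrientations(arr)[1:nrow(data), ,
                                                      drop = FALSE])
  }
  new("Recording", array = arr, data = data, rate = rate,
      annotations = list())
}

band_rms <- function(x, rate, f0, halfwidth = 1) {
  ps <- welchPsd(x, rate, windowSec = 2)
  sel <- abs(ps$freq - f0) <= halfwidth
  sqrt(sum(ps$psd[1, sel]) * (ps$freq[2] - ps$freq[1]))
}

test_that("the notch removes powerline tones and spares nearby rhythms", {
  rate <- 600
  tt <- seq(0, 40, by = 1 / rate)[-1]
  d <- rbind(sin(2 * pi * 50 * tt), sin(2 * pi * 10 * tt))
  d <- rbind(d, d[1, ] + d[2, ], matrix(0, 5, length(tt)))
  rec <- make_rec(d, rate)
  out <- recordingData(notchFilter(rec))
  expect_equal(ncol(out), ncol(d))
  # >= 40 dB attenuation of the 50 Hz tone (band-limited RMS)
  att <- band_rms(out[1, ], rate, 50) / band_rms(d[1, ], rate, 50)
  expect_lt(att, 0.01)
  # < 1% change of a 10 Hz tone
  expect_lt(abs(band_rms(out[2, ], rate, 10) / band_rms(d[2, ], rate, 10) - 1),
            0.01)
  # all-zero input stays zero
  z <- notchFilter(make_rec(matrix(0, 8, 2400), rate))
  expect_true(all(recordingData(z) == 0))
  # explicit harmonic above Nyquist is refused with the offender named
  expect_error(notchFilter(rec, nHarmonics = 7), "Nyquist")
})

test_that("the notch is a linear operator", {
  rate <- 600
  set.seed(4)
  x <- matrix(rnorm(8 * 3000), 8, 3000)
  y <- matrix(rnorm(8 * 3000), 8, 3000)
  fa <- recordingData(notchFilter(make_rec(x, rate)))
  fb <- recordingData(notchFilter(make_rec(y, rate)))
  fab <- recordingData(notchFilter(make_rec(2 * x - 3 * y, rate)))
  expect_lt(max(abs(fab - (2 * fa - 3 * fb))) / max(abs(fab)), 1e-9)
})

test_that("segment selection finds the first clean window or fails loudly", {
  rate <- 100
  set.seed(8)
  n <- 120 * rate
  d <- matrix(rnorm(8 * n), 8, n)
  rec <- make_rec(d, rate)
  seg <- selectSegment(rec, duration = 30)
  expect_equal(annotations(seg)$segment_offset_s, 0)
  expect_equal(ncol(recordingData(seg)), 30 * rate)

  # artifact burst over 2-9.5 s pushes the window past it
  d2 <- d
  d2[1, 200:950] <- 40
  seg2 <- selectSegment(make_rec(d2, rate), duration = 30)
  expect_gte(annotations(seg2)$segment_offset_s, 10)

  # threshold below the noise floor: explicit error, never truncation
  expect_error(selectSegment(rec, duration = 30, threshold = rep(1e-3, 8)),
               "no artifact-free segment")
  expect_error(selectSegment(rec, duration = 200), "shorter")
})

test_that("noise covariance estimation is accurate, shrunk and SPD", {
  arr <- fx_geometry()$array
  er <- simulateEmptyRoom(arr, duration = 120, noiseSd = 1, rate = 100,
                          seed = 3)
  nc <- estimateNoiseCovariance(er, shrinkage = 0.1)
  C <- covMatrix(nc)
  expect_true(all(abs(diag(C) - 1) < 0.05))
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  # shrinkage 1 gives exactly the diagonal
  nc1 <- estimateNoiseCovariance(er, shrinkage = 1)
  expect_equal(covMatrix(nc1), diag(diag(cov(t(recordingData(er))))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(estimateNoiseCovariance(
    simulateEmptyRoom(arr, duration = 5, noiseSd = 1, rate = 100)), "10 s")
})

test_that("covariance error halves when the duration quadruples", {
  arr <- fx_geometry()$array
  err_at <- function(dur, seed) {
    er <- simulateEmptyRoom(arr, duration = dur, noiseSd = 1, rate = 100,
                            seed = seed)
    C <- cov(t(recordingData(er)))
    norm(C - diag(nrow(C)), "F") / norm(diag(nrow(C)), "F")
  }
  e1 <- mean(vapply(1:6, function(s) err_at(30, s), numeric(1)))
  e4 <- mean(vapply(1:6, function(s) err_at(120, s), numeric(1)))
  expect_lt(abs(e1 / e4 - 2), 0.5)
})
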