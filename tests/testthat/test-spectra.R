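test_that("Welch PSD recovers sinusoid power and white-noise variance", {
  rate <- 600
  tt <- seq(1 / rate, 30, by = 1 / rate)
  x <- 2 * sin(2 * pi * 10 * tt)
  w <- welchPsd(x, rate)
  df <- w$freq[2] - w$freq[1]
  expect_equal(df, 0.2)
  expect_equal(w$nSegments, 11)
  expect_lt(abs(sum(w$psd) * df - 2) / 2, 0.05)      # A^2/2 = 2
  expect_equal(w$freq[which.max(w$psd[1, ])], 10)
  # Parseval on white noise
  set.seed(5)
  n <- rnorm(length(tt), sd = 3)
  wn <- welchPsd(n, rate)
  expect_lt(abs(sum(wn$psd) * df - 9) / 9, 0.05)
  # flat spectrum: no bin more than a few times the median
  expect_lt(max(wn$psd) / median(wn$psd), 8)
  expect_error(welchPsd(x[1:100], rate), "shorter than one window")
})

test_that("ROI reduction averages vertex spectra in the canonical order", {
  ss <- makeSourceSpace(52, seed = 1)
  rate <- 200
  tt <- seq(1 / rate, 20, by = 1 / rate)
  n <- nVertices(ss)
  src <- matrix(0, n, length(tt))
  # all vertices share a 10 Hz tone; one ROI gets an extra 25 Hz tone on
  # one of its two vertices
  src <- src + matrix(sin(2 * pi * 10 * tt), n, length(tt), byrow = TRUE)
  idx <- roiVertexIndices(ss)
  roi <- "PCC.L"
  src[idx[[roi]][1], ] <- src[idx[[roi]][1], ] + 2 * sin(2 * pi * 25 * tt)
  rp <- roiPsd(src, ss, rate, windowSec = 2)
  expect_identical(rownames(rp$psd), roiNames())
  i10 <- which.min(abs(rp$freq - 10))
  i25 <- which.min(abs(rp$freq - 25))
  other <- setdiff(roiNames(), roi)[1]
  # identical vertices: ROI PSD equals the single-vertex PSD
  wv <- welchPsd(src[idx[[other]][1], ], rate, windowSec = 2)
  expect_equal(rp$psd[other, ], wv$psd[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # the mixed ROI shows both peaks, the 25 Hz one diluted by exactly
  # the ROI's vertex count (power-first averaging)
  nv <- length(idx[[roi]])
  wpeak <- welchPsd(2 * sin(2 * pi * 25 * tt), rate, windowSec = 2)
  expect_lt(abs(rp$psd[roi, i25] - wpeak$psd[1, i25] / nv) /
              (wpeak$psd[1, i25] / nv), 0.05)
  expect_gt(rp$psd[roi, i10], 0.5 * rp$psd[other, i10])
})

test_that("band integration respects edges, gaps and Nyquist", {
  freq <- seq(0, 300, by = 0.2)
  scheme <- bandSchemeForRate(600, warn = FALSE)
  flat <- matrix(1, 1, length(freq))
  bp <- bandPower(flat, freq, scheme)
  # inclusive edges add one bin width; ripple opens exclusively at the
  # shared 90 Hz edge so it integrates to exactly its nominal width
  expect_equal(unname(bp[1, ]),
               c(2.2, 2.2, 4.2, 14.2, 29.2, 30.2, 160.0), tolerance = 1e-9)
  # alpha-only spectrum excites only alpha
  alpha <- matrix(as.numeric(freq >= 8 & freq <= 12), 1, length(freq))
  bpa <- bandPower(alpha, freq, scheme)
  expect_true(all(bpa[1, setdiff(colnames(bpa), "alpha")] == 0))
  expect_gt(bpa[1, "alpha"], 0)
  # gap frequencies (e.g. 13 Hz) belong to no band
  gap <- matrix(as.numeric(abs(freq - 13) < 0.5), 1, length(freq))
  expect_true(all(bandPower(gap, freq, scheme) == 0))
  # the shared 90 Hz edge is counted once, for gamma2
  edge <- matrix(as.numeric(abs(freq - 90) < 0.01), 1, length(freq))
  bpe <- bandPower(edge, freq, scheme)
  expect_gt(bpe[1, "gamma2"], 0)
  expect_equal(unname(bpe[1, "ripple"]), 0)
  # a band beyond the spectrum is refused
  expect_error(bandPower(flat, freq, defaultBandScheme()), "Nyquist")
})

test_that("relative power is a proper share: [0,1], rows sum to 1", {
  expect_equal(unname(relativePsd(c(2, 0, 0, 0, 0, 0, 0, 0))[1, ]),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(relativePsd(rep(3, 8))[1, ]), rep(1 / 8, 8))
  set.seed(3)
  m <- matrix(rexp(26 * 7), 26, 7)
  r <- relativePsd(m)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(rowSums(r), rep(1, 26), tolerance = 1e-9, ignore_attr = TRUE)
  # invariant to global amplitude scaling
  expect_equal(relativePsd(m * 1e12), r, tolerance = 1e-9)
  expect_error(relativePsd(rbind(m, 0)), "all-zero")
  expect_error(relativePsd(-m), "non-negative")
})

test_that("the kernel-domain Welch path equals explicit source Welch", {
  w <- fx_world()
  rec <- simulateSubject(w$design, w$space, w$array, w$lf, "CNI", seed = 55)
  rec <- notchFilter(rec)
  rec <- selectSegment(rec, duration = 10)
  src <- applyInverse(w$inv, rec)
  a <- roiPsd(src, w$space, samplingRate(rec), windowSec = 2)
  b <- roiPsdKernel(w$inv, rec, w$space, windowSec = 2)
  expect_equal(a$freq, b$freq)
  expect_lt(max(abs(a$psd - b$psd)) / max(a$psd), 1e-9)
})

test_that("subject-level relative power is invariant to global scaling", {
  w <- fx_world()
  rec <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 66)
  scaled <- initialize(rec, data = recordingData(rec) * 37)
  r1 <- processSubject(rec, w$inv, w$space, w$scheme, segmentSec = 10)
  r2 <- processSubject(scaled, w$inv, w$space, w$scheme, segmentSec = 10)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(rowSums(r1), rep(1, 26), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("relative power tables round-trip through the long CSV", {
  set.seed(21)
  mk <- function() {
    m <- matrix(rexp(26 * 7), 26, 7,
                dimnames = list(roiNames(),
                                bandNames(bandSchemeForRate(600, warn = FALSE))))
    relativePsd(m)
  }
  tab <- relativePowerTable(list(`sub-01` = mk(), `sub-02` = mk()))
  path <- tempfile(fileext = ".csv")
  writeRelativePowerCSV(tab, path)
  back <- readRelativePowerCSV(path)
  expect_equal(powerValues(back), powerValues(tab), tolerance = 1e-12)
  raw <- read.csv(path)
  expect_identical(names(raw),
                   c("subject_id", "roi", "hemisphere", "band", "value"))
  expect_setequal(unique(raw$hemisphere), c("L", "R"))
})
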