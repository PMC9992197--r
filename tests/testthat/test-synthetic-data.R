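test_that("sensor arrays sit on the helmet cap, radially oriented, reproducibly", {
  for (count in c(8, 64, 275)) {
    arr <- makeSensorArray(count, headRadius = 0.09, seed = 7)
    expect_equal(nSensors(arr), count)
    expect_equal(sqrt(rowSums(sensorPositions(arr)^2)),
                 rep(0.099, count), tolerance = 1e-12)
    expect_equal(sqrt(rowSums(sensorOrientations(arr)^2)),
                 rep(1, count), tolerance = 1e-12)
    # radial orientation: parallel to position
    cosang <- rowSums(sensorOrientations(arr) *
                        sensorPositions(arr)) / 0.099
    expect_equal(cosang, rep(1, count), tolerance = 1e-12)
  }
  expect_identical(makeSensorArray(64, seed = 3), makeSensorArray(64, seed = 3))
  expect_false(isTRUE(all.equal(sensorPositions(makeSensorArray(64, seed = 3)),
                                sensorPositions(makeSensorArray(64, seed = 4)))))
  expect_error(makeSensorArray(7), "at least 8")
})

test_that("source spaces cover all 26 ROIs and mirror across the midline", {
  for (nv in c(52, 520)) {
    ss <- makeSourceSpace(nv, seed = 1)
    expect_setequal(unique(vertexLabels(ss)), roiNames())
    expect_equal(sqrt(rowSums(vertexNormals(ss)^2)),
                 rep(1, nVertices(ss)), tolerance = 1e-12)
    expect_true(all(table(vertexLabels(ss)) >= 1))
    # strictly inside the head sphere
    expect_true(all(sqrt(rowSums(vertexPositions(ss)^2)) < 0.09))
  }
  ss <- makeSourceSpace(520, seed = 1)
  # bilateral pairs are exact mirror images: centroids reflect in x
  pos <- vertexPositions(ss); lab <- vertexLabels(ss)
  for (area in roiNames(areas = TRUE)[c(1, 5, 9, 13)]) {
    cl <- colMeans(pos[lab == paste0(area, ".L"), , drop = FALSE])
    cr <- colMeans(pos[lab == paste0(area, ".R"), , drop = FALSE])
    expect_equal(cl * c(-1, 1, 1), cr, tolerance = 1e-12)
  }
  # dipoles must not be radial (radial dipoles are MEG-silent)
  rad <- abs(rowSums(vertexNormals(ss) * pos / sqrt(rowSums(pos^2))))
  expect_true(all(rad < 0.999))
  expect_error(makeSourceSpace(51), "at least 52")
})

test_that("clinical draws reproduce the published group summaries", {
  set.seed(10)
  ci <- do.call(rbind, lapply(1:1000, function(i) sampleClinical("CI")))
  expect_lt(abs(mean(ci$FSIQ) - 84.63) / 84.63, 0.05)
  expect_lt(abs(sd(ci$FSIQ) - 4.79) / 4.79, 0.05)
  expect_true(all(ci$FSIQ < 90))
  expect_lt(abs(mean(ci$seizure_count) - 3.17) / 3.17, 0.05)
  expect_lt(abs(mean(ci$onset_age) - 7.98) / 7.98, 0.05)
  set.seed(11)
  cni <- do.call(rbind, lapply(1:400, function(i) sampleClinical("CNI")))
  expect_true(all(cni$FSIQ > 90))
  expect_lt(abs(mean(cni$FSIQ) - 107.79) / 107.79, 0.05)
  set.seed(12)
  hc <- do.call(rbind, lapply(1:200, function(i) sampleClinical("HC")))
  expect_true(all(hc$FSIQ >= 90 & hc$FSIQ <= 110))
  expect_true(all(is.na(hc$onset_age)))
  expect_true(all(ci$WMI > 0 & ci$PSI > 0))
  expect_error(sampleClinical("patient"), "unknown group")
})

test_that("subject simulation is seed-deterministic and shape-checked", {
  w <- fx_world()
  r1 <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 21)
  r2 <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 21)
  expect_identical(recordingData(r1), recordingData(r2))
  r3 <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 22)
  expect_false(identical(recordingData(r1), recordingData(r3)))
  expect_equal(nrow(recordingData(r1)), 32)
  badlf <- new("LeadField", gain = gainMatrix(w$lf)[, 1:10],
               sphere = fitSphere(w$space))
  expect_error(simulateSubject(w$design, w$space, w$array, badlf, "HC"),
               "dimensions")
})

test_that("line contamination shows as a 50 Hz PSD peak before the notch", {
  w <- fx_world()
  rec <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 31)
  ps <- welchPsd(recordingData(rec)[1:4, ], samplingRate(rec))
  m <- colMeans(ps$psd)
  at50 <- which.min(abs(ps$freq - 50))
  near <- ps$freq > 40 & ps$freq < 60
  expect_equal(which.max(m * near), at50)
  expect_gt(m[at50], 10 * max(m[ps$freq > 40 & ps$freq < 48]))
})

test_that("empty-room recordings are white noise at the requested level", {
  arr <- fx_geometry()$array
  er <- simulateEmptyRoom(arr, duration = 120, noiseSd = 1, rate = 200,
                          seed = 2)
  sds <- apply(recordingData(er), 1, sd)
  expect_true(all(abs(sds - 1) < 0.05))
  C <- cov(t(recordingData(er)))
  offdiag <- C[upper.tri(C)]
  expect_lt(max(abs(offdiag)), 0.05)
  z <- simulateEmptyRoom(arr, duration = 1, noiseSd = 0, rate = 200)
  expect_true(all(recordingData(z) == 0))
  expect_error(simulateEmptyRoom(arr, duration = 0), "duration")
})

test_that("raising a single (ROI, band) multiplier raises sensor power", {
  w <- fx_world()
  p <- designParams(w$design)
  meanVar <- function(mult) {
    p2 <- p
    p2$effects <- data.frame(group = "CI", roi = c("PCC.L", "PCC.R"),
                             band = "alpha", multiplier = mult)
    p2$sensorNoiseSd <- 0
    p2$lineAmplitude <- 0
    d2 <- do.call(cohortDesign, p2)
    mean(vapply(1:12, function(i) {
      rec <- simulateSubject(d2, w$space, w$array, w$lf, "CI",
                             seed = 100 + i)
      mean(recordingData(rec)^2)
    }, numeric(1)))
  }
  v <- vapply(c(1, 2, 4), meanVar, numeric(1))
  expect_true(all(diff(v) > 0))
})
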