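# ---- frequency-domain synthesis helpers ------------------------------

# Inverse-FFT synthesis of real Gaussian series from one-sided complex
# spectra, two real series per complex transform (spectra are Hermitian,
# so ifft(C1 + i C2) carries series 1 in its real and series 2 in its
# imaginary part). `cpos`: (n/2) x m complex matrix of positive-frequency
# coefficients (row n/2 = Nyquist, must be real or zero).
.synth_real <- function(cpos, n) {
  m <- ncol(cpos)
  npair <- ceiling(m / 2)
  out <- matrix(0, n, m)
  nh <- n / 2
  for (j in seq_len(npair)) {
    i1 <- 2 * j - 1
    i2 <- if (2 * j <= m) 2 * j else NA_integer_
    full1 <- complex(length.out = n)
    full1[2:(nh + 1)] <- cpos[, i1]
    full1[n:(nh + 2)] <- Conj(cpos[-nh, i1])
    if (!is.na(i2)) {
      full2 <- complex(length.out = n)
      full2[2:(nh + 1)] <- cpos[, i2]
      full2[n:(nh + 2)] <- Conj(cpos[-nh, i2])
      g <- stats::fft(full1 + 1i * full2, inverse = TRUE) / n
      out[, i1] <- Re(g)
      out[, i2] <- Im(g)
    } else {
      g <- stats::fft(full1, inverse = TRUE) / n
      out[, i1] <- Re(g)
    }
  }
  out
}

.onesided_freqs <- function(n, rate) (1:(n / 2)) * rate / n

# band-limited Gaussian-bump envelope, zero outside [lo, hi]
.band_envelope <- function(f, lo, hi) {
  mid <- (lo + hi) / 2
  sdf <- (hi - lo) / 4
  e <- exp(-0.5 * ((f - mid) / sdf)^2)
  e[f < lo | f > hi] <- 0
  e
}

# 1/f^a background envelope (amplitude = power^(1/2)); Nyquist bin zeroed
.background_envelope <- function(f, exponent, fmin = 0.5) {
  e <- ifelse(f >= fmin, f^(-exponent / 2), 0)
  e[length(e)] <- 0
  e
}

# complex standard-normal draws (unit E|z|^2)
.crnorm <- function(k) {
  complex(real = stats::rnorm(k), imaginary = stats::rnorm(k)) / sqrt(2)
}

#' Bands the generator can represent at a sampling rate
#'
#' A band is generated/analysed only if the rate exceeds twice its upper
#' edge; at desk-scale rates (e.g. 600 Hz) the fast-ripple band is dropped
#' with a warning and the relative-power denominator re-spans the rest.
#'
#' @param rate sampling rate, Hz.
#' @param scheme a [BandScheme-class] (default [defaultBandScheme()]).
#' @param warn warn about dropped bands.
#' @return a [BandScheme-class] restricted to representable bands.
#' @export
bandSchemeForRate <- function(rate, scheme = defaultBandScheme(), warn = TRUE) {
  keep <- scheme@fHigh <= rate / 2
  if (all(keep)) return(scheme)
  if (warn)
    warning("dropping bands above Nyquist (", rate / 2, " Hz): ",
            paste(scheme@name[!keep], collapse = ", "), call. = FALSE)
  new("BandScheme", name = scheme@name[keep],
      fLow = scheme@fLow[keep], fHigh = scheme@fHigh[keep])
}

# per-band synthesis bins and envelopes on the length-nh positive grid,
# honouring the shared-edge rule of bandPower() so band spectra are
# disjoint and ROI variance is the exact sum of band variances
.band_bins <- function(f, scheme) {
  lapply(seq_along(scheme@name), function(b) {
    lowOpen <- b > 1 && scheme@fLow[b] == scheme@fHigh[b - 1]
    sel <- if (lowOpen) which(f > scheme@fLow[b] & f <= scheme@fHigh[b])
           else which(f >= scheme@fLow[b] & f <= scheme@fHigh[b])
    env <- .band_envelope(f[sel], scheme@fLow[b], scheme@fHigh[b])
    list(sel = sel, env = env, scale0 = 1 / sqrt(2 * sum(env^2)))
  })
}

#' Simulate one subject's sensor-level MEG recording
#'
#' Source activity at each vertex is 1/f background (a low-rank spatial
#' mixture of shared background components) plus, for every analysis
#' band, a band-limited Gaussian oscillator shared coherently by the
#' vertices of the vertex's ROI, with time-domain amplitude (SD)
#' `sourceAmplitude * bandAmplitude * multiplier(group, roi, band)` —
#' amplitude scaling is exact in expectation, so a multiplier m scales
#' expected band power by exactly m^2. Sensor data are the lead-field
#' projection of the sources plus white sensor noise and a powerline
#' sinusoid.
#'
#' @param design a [CohortDesign-class].
#' @param space the [SourceSpace-class] the cohort shares.
#' @param array the [SensorArray-class].
#' @param leadField the [LeadField-class] for `space` x `array`.
#' @param group one of "CI", "CNI", "HC" (selects the effect-map rows).
#' @param seed integer seed making the draw reproducible.
#' @param subjectId stored in the recording annotations.
#' @return a sensor-space [Recording-class].
#' @export
simulateSubject <- function(design, space, array, leadField, group,
                            seed = 1, subjectId = NULL) {
  p <- designParams(design)
  G <- gainMatrix(leadField)
  if (ncol(G) != nVertices(space) || nrow(G) != nSensors(array))
    stop("lead field dimensions do not match source space / sensor array")
  n <- round(p$duration * p$rate)
  if (n %% 2 == 1) n <- n - 1
  set.seed(as.integer(seed))

  scheme <- bandSchemeForRate(p$rate, warn = FALSE)
  bnames <- bandNames(scheme)
  nh <- n / 2
  f <- .onesided_freqs(n, p$rate)
  rois <- roiNames()
  idx <- roiVertexIndices(space, rois)
  nv <- nVertices(space)

  # --- effect multipliers: rois x bands, default 1 ---------------------
  eff <- p$effects[p$effects$group == group, , drop = FALSE]
  mult <- matrix(1, length(rois), length(bnames),
                 dimnames = list(rois, bnames))
  if (nrow(eff)) {
    eff <- eff[eff$band %in% bnames & eff$roi %in% rois, , drop = FALSE]
    mult[cbind(eff$roi, eff$band)] <- eff$multiplier
  }

  # --- per-ROI spectra: sum of its band oscillators --------------------
  bins <- .band_bins(f, scheme)
  cpos <- matrix(0+0i, nh, length(rois))
  for (r in seq_along(rois)) {
    for (b in seq_along(bnames)) {
      amp <- p$sourceAmplitude * p$bandAmplitudes[[bnames[b]]] *
        mult[r, b]
      if (amp <= 0 || !length(bins[[b]]$sel)) next
      cpos[bins[[b]]$sel, r] <- cpos[bins[[b]]$sel, r] +
        bins[[b]]$env * .crnorm(length(bins[[b]]$sel)) *
          (amp * n * bins[[b]]$scale0)
    }
  }
  roiSig <- .synth_real(cpos, n)                       # n x R

  # --- background components ------------------------------------------
  K <- p$backgroundComponents
  envBg <- .background_envelope(f, p$backgroundExponent)
  sBg <- p$sourceAmplitude * n / sqrt(2 * sum(envBg^2))
  cbg <- envBg * matrix(.crnorm(nh * K), nh, K) * sBg
  cbg[nh, ] <- 0
  BG <- .synth_real(cbg, n)                            # n x K
  Mbg <- matrix(stats::rnorm(nv * K, sd = 1 / sqrt(K)), nv, K)

  # --- project to sensors ---------------------------------------------
  A <- vapply(idx, function(iv) rowSums(G[, iv, drop = FALSE]),
              numeric(nrow(G)))                        # C x R
  sens <- (G %*% Mbg) %*% t(BG) + A %*% t(roiSig)

  # --- sensor noise and powerline component ----------------------------
  sens <- sens + stats::rnorm(length(sens), sd = p$sensorNoiseSd)
  if (p$lineAmplitude > 0) {
    tt <- (seq_len(n) - 1) / p$rate
    phase <- stats::runif(1, 0, 2 * pi)
    gains <- stats::runif(nrow(sens), 0.5, 1.5)
    sens <- sens + gains %o% (p$lineAmplitude *
                                sin(2 * pi * p$lineFreq * tt + phase))
  }
  new("Recording", array = array, data = sens, rate = p$rate,
      annotations = list(subject_id = subjectId, group = group,
                         seed = as.integer(seed)))
}

#' Simulate an empty-room (sensor noise only) recording
#'
#' @param array a [SensorArray-class].
#' @param duration seconds (> 0).
#' @param noiseSd white noise SD, tesla.
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @return a [Recording-class] of zero-mean white noise.
#' @export
simulateEmptyRoom <- function(array, duration = 120, noiseSd = 1e-13,
                              rate = 600, seed = 1) {
  if (duration <= 0) stop("duration must be > 0")
  set.seed(as.integer(seed))
  n <- round(duration * rate)
  d <- matrix(stats::rnorm(nSensors(array) * n, sd = noiseSd),
              nSensors(array), n)
  new("Recording", array = array, data = d, rate = rate,
      annotations = list(kind = "empty-room"))
}

#' Simulate a full cohort
#'
#' Generates the shared geometry (sensor array, source space, lead field),
#' an empty-room recording, a clinical manifest and one recording per
#' subject. Everything is a deterministic function of the design and its
#' master seed.
#'
#' @param design a [CohortDesign-class].
#' @param groups group labels to simulate.
#' @return list with elements `space`, `array`, `leadField`, `sphere`,
#'   `emptyRoom`, `manifest` (data.frame) and `recordings` (named list of
#'   [Recording-class], one per manifest row).
#' @export
simulateCohort <- function(design, groups = c("CI", "CNI", "HC")) {
  p <- designParams(design)
  array <- makeSensorArray(p$nSensors, p$headRadius, seed = p$seed)
  space <- makeSourceSpace(p$nVertices, seed = p$seed,
                           shellRadius = p$headRadius * 7 / 9)
  sphere <- fitSphere(space)
  lf <- computeLeadField(space, array, sphere)
  emptyRoom <- simulateEmptyRoom(array, duration = min(120, max(30, p$duration)),
                                 noiseSd = p$sensorNoiseSd, rate = p$rate,
                                 seed = .subject_seed(p$seed, 0L, 2L))
  manifest <- sampleCohortManifest(design, groups)
  recs <- vector("list", nrow(manifest))
  names(recs) <- manifest$subject_id
  for (i in seq_len(nrow(manifest))) {
    recs[[i]] <- simulateSubject(
      design, space, array, lf, manifest$group[i],
      seed = .subject_seed(p$seed, i, 3L), subjectId = manifest$subject_id[i])
  }
  list(space = space, array = array, leadField = lf, sphere = sphere,
       emptyRoom = emptyRoom, manifest = manifest, recordings = recs)
}
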