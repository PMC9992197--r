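#' Zero-phase notch filtering of powerline contamination
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth
#' band-stop at the powerline frequency and each requested harmonic.
#' Signal length is preserved and the operation is linear.
#'
#' @param recording a [Recording-class].
#' @param baseFreq powerline frequency, Hz (default 50).
#' @param nHarmonics number of harmonics to remove (k = 1..nHarmonics at
#'   k * baseFreq); default: every harmonic below Nyquist.
#' @param bandwidth stop-band width around each harmonic, Hz (default 2).
#' @return the filtered [Recording-class]; the applied notches are
#'   appended to its annotations.
#' @export
notchFilter <- function(recording, baseFreq = 50, nHarmonics = NULL,
                        bandwidth = 2) {
  rate <- samplingRate(recording)
  nyq <- rate / 2
  if (is.null(nHarmonics)) {
    nHarmonics <- floor((nyq - bandwidth) / baseFreq - 1e-9)
  } else {
    bad <- baseFreq * seq_len(nHarmonics)
    bad <- bad[bad + bandwidth / 2 >= nyq]
    if (length(bad))
      stop("notch harmonic(s) at or above Nyquist (", nyq, " Hz): ",
           paste(bad, collapse = ", "))
  }
  if (nHarmonics < 1) stop("no notch harmonic below Nyquist")
  d <- recordingData(recording)
  pad <- min(ncol(d) - 1L, round(rate))  # 1 s of odd-reflection padding
  flts <- lapply(seq_len(nHarmonics), function(k) {
    f0 <- baseFreq * k
    signal::butter(2, c(f0 - bandwidth / 2, f0 + bandwidth / 2) / nyq,
                   type = "stop")
  })
  bmat <- do.call(rbind, lapply(flts, `[[`, "b"))
  amat <- do.call(rbind, lapply(flts, `[[`, "a"))
  d <- .cpp_filtfilt_cascade_rows(bmat, amat, d, pad)
  ann <- annotations(recording)
  ann$notch <- list(base_freq = baseFreq, n_harmonics = nHarmonics,
                    bandwidth = bandwidth)
  initialize(recording, data = d, annotations = ann)
}

#' Select the first artifact-free analysis segment
#'
#' Scans the recording in steps of `step` seconds and returns the first
#' contiguous window of `duration` seconds whose peak absolute amplitude
#' stays below a per-channel threshold on every channel — an explicit,
#' reproducible stand-in for visual segment vetting. The default
#' threshold is `thresholdK` robust SDs (median absolute deviation,
#' Gaussian-consistent) around the channel median.
#'
#' @param recording a [Recording-class].
#' @param duration segment length, s (default 30).
#' @param thresholdK threshold in per-channel robust SDs (default 5).
#' @param threshold explicit per-channel absolute threshold vector
#'   (overrides `thresholdK`).
#' @param step scan step, s.
#' @return the selected [Recording-class] window; its annotations record
#'   the chosen offset (`segment_offset_s`).
#' @export
selectSegment <- function(recording, duration = 30, thresholdK = 5,
                          threshold = NULL, step = 1) {
  d <- recordingData(recording)
  rate <- samplingRate(recording)
  nwin <- round(duration * rate)
  if (nwin > ncol(d))
    stop("recording (", ncol(d) / rate, " s) shorter than requested segment (",
         duration, " s)")
  if (is.null(threshold)) {
    med <- apply(d, 1, stats::median)
    threshold <- thresholdK * apply(abs(d - med), 1, stats::median) * 1.4826
    d0 <- d - med
  } else {
    d0 <- d
  }
  offsets <- seq(0L, ncol(d) - nwin, by = max(1L, round(step * rate)))
  for (off in offsets) {
    block <- d0[, (off + 1):(off + nwin), drop = FALSE]
    # `threshold` (one entry per channel) recycles down the columns
    if (!any(abs(block) > threshold)) {
      ann <- annotations(recording)
      ann$segment_offset_s <- off / rate
      ann$segment_duration_s <- duration
      return(initialize(recording,
                        data = d[, (off + 1):(off + nwin), drop = FALSE],
                        annotations = ann))
    }
  }
  stop("no artifact-free segment of ", duration,
       " s found below the amplitude threshold")
}

#' Estimate sensor noise covariance from an empty-room recording
#'
#' Sample covariance of the demeaned channels, shrunk toward its diagonal:
#' `C = (1 - s) * S + s * diag(S)`. Any positive shrinkage makes the
#' result positive definite (given non-degenerate channels), which the
#' whitening step of [buildInverse()] requires.
#'
#' @param emptyRoom a [Recording-class] of at least 10 s.
#' @param shrinkage shrinkage factor in (0, 1] (default 0.1);
#'   `shrinkage = 1` gives the diagonal matrix.
#' @return a [NoiseCovariance-class].
#' @export
estimateNoiseCovariance <- function(emptyRoom, shrinkage = 0.1) {
  d <- recordingData(emptyRoom)
  if (ncol(d) / samplingRate(emptyRoom) < 10)
    stop("empty-room recording must be at least 10 s long")
  S <- stats::cov(t(d))
  C <- (1 - shrinkage) * S + shrinkage * diag(diag(S))
  C <- (C + t(C)) / 2
  new("NoiseCovariance", matrix = C, shrinkage = shrinkage)
}
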