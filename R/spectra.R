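#' The default eight-band analysis scheme
#'
#' delta 2-4, theta 5-7, alpha 8-12, beta 15-29, gamma1 30-59, gamma2
#' 60-90, ripple 90-250 and fast ripple 250-500 Hz. Note the deliberate
#' gaps (4-5, 7-8, 12-15, 29-30 Hz): frequencies there belong to no band
#' and never enter the relative-power denominator. The 90 Hz edge shared
#' by gamma2 and ripple is counted once, for gamma2.
#'
#' @return a [BandScheme-class].
#' @examples
#' defaultBandScheme()
#' @export
defaultBandScheme <- function() {
  new("BandScheme",
      name = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2",
               "ripple", "fastripple"),
      fLow = c(2, 5, 8, 15, 30, 60, 90, 250),
      fHigh = c(4, 7, 12, 29, 59, 90, 250, 500))
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered, per-segment-demeaned periodograms over
#' overlapping segments, with density scaling: the PSD integrates (sum
#' over bins times bin width) to the signal variance. Bin spacing is
#' `1 / windowSec`.
#'
#' @param x numeric vector, or matrix with one series per row.
#' @param rate sampling rate, Hz.
#' @param windowSec segment length in seconds (default 5).
#' @param overlap fractional overlap of consecutive segments (default 0.5).
#' @return list with `freq` (Hz, one-sided including 0 and Nyquist),
#'   `psd` (series x bins matrix, power per Hz), `nSegments`, and the
#'   settings used.
#' @examples
#' x <- 2 * sin(2 * pi * 10 * seq(0, 30, by = 1 / 600))
#' w <- welchPsd(x, 600)
#' sum(w$psd) * (w$freq[2] - w$freq[1])  # ~ amplitude^2 / 2 = 2
#' @export
welchPsd <- function(x, rate, windowSec = 5, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nw <- round(windowSec * rate)
  if (n < nw)
    stop("series (", n, " samples) shorter than one window (", nw, ")")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)   # periodic Hann
  wnorm <- sum(win^2)
  nbin <- nw %/% 2 + 1L
  acc <- matrix(0, nrow(x), nbin)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + nw - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- stats::mvfft(t(seg * rep(win, each = nrow(seg))))
    p <- (Mod(ft[seq_len(nbin), , drop = FALSE])^2) / (rate * wnorm)
    acc <- acc + t(p)
  }
  psd <- acc / length(starts)
  # one-sided: double everything but DC and Nyquist
  dbl <- rep(2, nbin); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nbin] <- 1
  psd <- psd * rep(dbl, each = nrow(psd))
  list(freq = (seq_len(nbin) - 1) * rate / nw, psd = psd,
       nSegments = length(starts),
       settings = list(window_s = windowSec, overlap = overlap, rate = rate))
}

#' Per-ROI source-space PSD
#'
#' Computes the Welch PSD of every vertex of each ROI and reduces over
#' vertices. The default reduction is "power-first": average the
#' per-vertex PSDs, which is insensitive to phase cancellation between
#' vertices. "mean-first" (PSD of the ROI-mean time series) is available
#' for comparison.
#'
#' @param sourceTs sources x samples matrix (output of [applyInverse()]).
#' @param space the [SourceSpace-class] providing vertex labels.
#' @param rate sampling rate, Hz.
#' @param windowSec,overlap Welch settings, see [welchPsd()].
#' @param reduce "power-first" (default) or "mean-first".
#' @param rois ROI order (default the canonical 26, see [roiNames()]).
#' @return list with `freq`, `psd` (ROI x bins, rows in `rois` order),
#'   `settings`.
#' @export
roiPsd <- function(sourceTs, space, rate, windowSec = 5, overlap = 0.5,
                   reduce = c("power-first", "mean-first"),
                   rois = roiNames()) {
  reduce <- match.arg(reduce)
  idx <- roiVertexIndices(space, rois)
  if (reduce == "mean-first") {
    m <- t(vapply(idx, function(iv)
      colMeans(sourceTs[iv, , drop = FALSE]), numeric(ncol(sourceTs))))
    w <- welchPsd(m, rate, windowSec, overlap)
    psd <- w$psd
  } else {
    w <- welchPsd(sourceTs, rate, windowSec, overlap)
    psd <- t(vapply(idx, function(iv)
      colMeans(w$psd[iv, , drop = FALSE]), numeric(length(w$freq))))
  }
  rownames(psd) <- rois
  list(freq = w$freq, psd = psd,
       settings = c(w$settings, list(reduce = reduce)))
}

#' Per-ROI PSD by applying the inverse kernel in the frequency domain
#'
#' Mathematically identical to [applyInverse()] followed by [roiPsd()]
#' with power-first reduction (both are linear maps commuting with the
#' windowed Fourier transform), but much cheaper: the sensor-level
#' segment spectra are computed once and the source kernel is applied per
#' frequency bin.
#'
#' @param inverseOp an [InverseOperator-class].
#' @param recording a sensor-space [Recording-class] (the analysis
#'   segment).
#' @param space the [SourceSpace-class].
#' @param windowSec,overlap Welch settings.
#' @param rois ROI order.
#' @return list with `freq`, `psd` (ROI x bins), `settings` — the same
#'   contract as [roiPsd()].
#' @export
roiPsdKernel <- function(inverseOp, recording, space, windowSec = 5,
                         overlap = 0.5, rois = roiNames()) {
  K <- kernelMatrix(inverseOp)
  d <- recordingData(recording)
  rate <- samplingRate(recording)
  if (nrow(d) != ncol(K))
    stop("recording has ", nrow(d), " channels but kernel expects ", ncol(K))
  n <- ncol(d)
  nw <- round(windowSec * rate)
  if (n < nw)
    stop("series (", n, " samples) shorter than one window (", nw, ")")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)
  wnorm <- sum(win^2)
  nbin <- nw %/% 2 + 1L
  acc <- matrix(0, nrow(K), nbin)
  for (s0 in starts) {
    seg <- d[, s0:(s0 + nw - 1L), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(win, each = nrow(seg))
    ft <- stats::mvfft(t(seg))[seq_len(nbin), , drop = FALSE]  # nbin x C
    zr <- K %*% t(Re(ft))
    zi <- K %*% t(Im(ft))
    acc <- acc + (zr * zr + zi * zi)
  }
  psd <- acc / (length(starts) * rate * wnorm)
  dbl <- rep(2, nbin); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nbin] <- 1
  psd <- psd * rep(dbl, each = nrow(psd))
  idx <- roiVertexIndices(space, rois)
  out <- t(vapply(idx, function(iv)
    colMeans(psd[iv, , drop = FALSE]), numeric(nbin)))
  rownames(out) <- rois
  list(freq = (seq_len(nbin) - 1) * rate / nw, psd = out,
       settings = list(window_s = windowSec, overlap = overlap,
                       rate = rate, reduce = "power-first"))
}

#' Absolute band power from a PSD
#'
#' Sums PSD bins falling in each band (times the bin width). Both band
#' edges are inclusive, except that a band whose lower edge equals the
#' previous band's upper edge opens exclusively, so no bin is counted
#' twice. Frequencies in the inter-band gaps contribute to no band.
#'
#' @param psd series x bins matrix (or vector) of PSD values.
#' @param freq bin frequencies, Hz.
#' @param scheme a [BandScheme-class]; bands must lie within `max(freq)`.
#' @return series x bands matrix of absolute band powers.
#' @export
bandPower <- function(psd, freq, scheme = defaultBandScheme()) {
  if (is.vector(psd)) psd <- matrix(psd, nrow = 1)
  if (ncol(psd) != length(freq)) stop("psd/freq length mismatch")
  over <- scheme@fHigh > max(freq) + 1e-9
  if (any(over))
    stop("band(s) exceed the spectrum's frequency range (Nyquist): ",
         paste(scheme@name[over], collapse = ", "))
  df <- freq[2] - freq[1]
  nb <- length(scheme@name)
  out <- matrix(0, nrow(psd), nb,
                dimnames = list(rownames(psd), scheme@name))
  for (b in seq_len(nb)) {
    lowOpen <- b > 1 && scheme@fLow[b] == scheme@fHigh[b - 1]
    sel <- if (lowOpen)
      freq > scheme@fLow[b] + 1e-12 & freq <= scheme@fHigh[b] + 1e-12
    else
      freq >= scheme@fLow[b] - 1e-12 & freq <= scheme@fHigh[b] + 1e-12
    out[, b] <- rowSums(psd[, sel, drop = FALSE]) * df
  }
  out
}

#' Relative band power (relative PSD)
#'
#' Each band's power divided by the summed power of all analysed bands,
#' per series: values lie in [0, 1] and sum to 1 across bands. This is
#' the normalization that makes spectral power comparable across regions
#' and subjects.
#'
#' @param bandPowers series x bands matrix (or vector) of non-negative
#'   absolute band powers.
#' @return matrix of the same shape with rows summing to 1.
#' @examples
#' relativePsd(c(2, 0, 0, 0, 0, 0, 0, 0))  # (1, 0, ..., 0)
#' @export
relativePsd <- function(bandPowers) {
  v <- if (is.vector(bandPowers)) matrix(bandPowers, nrow = 1,
                                         dimnames = list(NULL, names(bandPowers)))
       else bandPowers
  if (any(v < 0)) stop("band powers must be non-negative")
  tot <- rowSums(v)
  if (any(tot == 0))
    stop("all-zero band powers for series ",
         paste(which(tot == 0), collapse = ", "),
         ": relative power undefined")
  v / tot
}

#' Assemble a RelativePowerTable from per-subject ROI x band matrices
#'
#' @param perSubject named list of ROI x band matrices (identical dimnames).
#' @param provenance named list stored with the table.
#' @return a [RelativePowerTable-class].
#' @export
relativePowerTable <- function(perSubject, provenance = list()) {
  stopifnot(length(perSubject) > 0)
  d1 <- dim(perSubject[[1]])
  arr <- array(NA_real_, c(length(perSubject), d1),
               dimnames = c(list(names(perSubject)),
                            dimnames(perSubject[[1]])))
  for (i in seq_along(perSubject)) arr[i, , ] <- perSubject[[i]]
  new("RelativePowerTable", values = arr, provenance = provenance)
}

#' Export / import a RelativePowerTable as long-format CSV
#'
#' Columns: subject_id, roi, hemisphere, band, value — the canonical
#' input of [runStats()].
#'
#' @param table a [RelativePowerTable-class]. @param path CSV path.
#' @return `readRelativePowerCSV` returns a [RelativePowerTable-class].
#' @export
writeRelativePowerCSV <- function(table, path) {
  v <- powerValues(table)
  dn <- dimnames(v)
  long <- expand.grid(subject_id = dn[[1]], roi = dn[[2]], band = dn[[3]],
                      stringsAsFactors = FALSE)
  long$value <- as.vector(v)
  long$hemisphere <- sub("^.*\\.", "", long$roi)
  long$roi_full <- long$roi
  long$roi <- sub("\\.[LR]$", "", long$roi_full)
  utils::write.csv(long[, c("subject_id", "roi", "hemisphere", "band",
                            "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRelativePowerCSV
#' @export
readRelativePowerCSV <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long$roi_full <- paste0(long$roi, ".", long$hemisphere)
  subs <- unique(long$subject_id)
  rois <- intersect(roiNames(), unique(long$roi_full))
  bands <- unique(long$band)
  arr <- array(NA_real_, c(length(subs), length(rois), length(bands)),
               dimnames = list(subs, rois, bands))
  arr[cbind(match(long$subject_id, subs), match(long$roi_full, rois),
            match(long$band, bands))] <- long$value
  new("RelativePowerTable", values = arr, provenance = list(source = path))
}
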