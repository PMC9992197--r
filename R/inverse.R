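#' Depth weights for a minimum-norm source prior
#'
#' The minimum-norm estimate is biased toward superficial sources because
#' their lead-field columns have larger norms. Depth weighting counters
#' this with per-source prior weights `w_s = (g_s' g_s)^(-exponent)`,
#' where `g_s` is source s's lead-field column. Weights are then clipped
#' from below to `max(w) / limit^2`, bounding the dynamic range so very
#' deep (weak-gain) sources cannot dominate the prior.
#'
#' @param leadField a [LeadField-class] or gain matrix.
#' @param exponent depth exponent in [0, 1]; 0 disables weighting,
#'   0.5 is the conventional default of distributed minimum-norm practice.
#' @param limit weight-ratio limit (>= 1, default 10): max(w)/min(w) is at
#'   most limit^2 after clipping.
#' @return numeric vector of per-source weights (> 0).
#' @examples
#' G <- cbind(c(1, 0), c(0, 2))
#' depthWeights(G, exponent = 0.5, limit = 1000)  # 1 and 1/2
#' @export
depthWeights <- function(leadField, exponent = 0.5, limit = 10) {
  if (exponent < 0 || exponent > 1) stop("exponent must lie in [0, 1]")
  if (limit < 1) stop("limit must be >= 1")
  G <- if (is(leadField, "LeadField")) gainMatrix(leadField) else leadField
  nrm2 <- colSums(G^2)
  if (any(nrm2 == 0))
    stop("zero-norm lead-field column for source(s): ",
         paste(which(nrm2 == 0), collapse = ", "))
  w <- nrm2^(-exponent)
  pmax(w, max(w) / limit^2)
}

#' Build a depth-weighted minimum-norm inverse operator
#'
#' With whitened lead field `L = C^(-1/2) G` and diagonal source prior
#' `R = diag(w * nu)` scaled so `trace(L R L') / n_sensors = 1`, the
#' kernel is `K = R L' (L R L' + lambda2 I)^(-1) C^(-1/2)`. The estimate
#' `s = K b` minimizes `|C^(-1/2)(b - G s)|^2 + lambda2 |R^(-1/2) s|^2`.
#' Under the trace normalization, `lambda2` is the reciprocal of the
#' assumed sensor-level SNR; the default 0.33 corresponds to SNR ~ 3.
#'
#' @param leadField a [LeadField-class] or gain matrix (sensors x sources).
#' @param noiseCov a [NoiseCovariance-class] or positive-definite matrix.
#' @param lambda2 regularization parameter (> 0, default 0.33).
#' @param weights per-source prior weights; default [depthWeights()] with
#'   exponent 0.5 and limit 10.
#' @return an [InverseOperator-class].
#' @export
buildInverse <- function(leadField, noiseCov, lambda2 = 0.33,
                         weights = NULL) {
  if (lambda2 <= 0) stop("lambda2 must be > 0")
  G <- if (is(leadField, "LeadField")) gainMatrix(leadField) else leadField
  C <- if (is(noiseCov, "NoiseCovariance")) covMatrix(noiseCov) else noiseCov
  if (nrow(C) != nrow(G)) stop("noise covariance does not match sensor count")
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) <= 0)
    stop("noise covariance is not positive definite; ",
         "apply diagonal shrinkage (see estimateNoiseCovariance)")
  whitener <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  L <- whitener %*% G
  if (is.null(weights)) weights <- depthWeights(G)
  if (length(weights) != ncol(G))
    stop("weights length must equal source count")
  nu <- nrow(G) / sum(weights * colSums(L^2))
  Rw <- weights * nu
  LR <- L * rep(Rw, each = nrow(L))        # L %*% diag(Rw)
  M <- LR %*% t(L)
  diag(M) <- diag(M) + lambda2
  K <- t(LR) %*% solve(M, whitener)
  new("InverseOperator", kernel = K, lambda2 = lambda2, weights = weights)
}

#' Apply an inverse operator to sensor data
#'
#' Streams the matrix product in time blocks with bounded memory; the
#' block size does not change the result.
#'
#' @param inverseOp an [InverseOperator-class].
#' @param recording a [Recording-class] or channels x samples matrix.
#' @param blockSize samples per block (default 20000).
#' @return sources x samples matrix of estimated dipole amplitudes.
#' @export
applyInverse <- function(inverseOp, recording, blockSize = 20000) {
  K <- kernelMatrix(inverseOp)
  d <- if (is(recording, "Recording")) recordingData(recording) else recording
  if (nrow(d) != ncol(K))
    stop("recording has ", nrow(d), " channels but kernel expects ", ncol(K))
  n <- ncol(d)
  out <- matrix(0, nrow(K), n)
  start <- 1L
  while (start <= n) {
    end <- min(start + blockSize - 1L, n)
    out[, start:end] <- K %*% d[, start:end, drop = FALSE]
    start <- end + 1L
  }
  out
}
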