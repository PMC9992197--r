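#' Fit a conductor sphere to a source space
#'
#' Algebraic least-squares sphere through the vertex cloud (Coope's linear
#' formulation), with the radius then inflated so every vertex lies
#' strictly inside the conductor.
#'
#' @param space a [SourceSpace-class] (or a vertices x 3 matrix).
#' @param inflate radius inflation factor (default 1.1). With `inflate =
#'   1` the pure least-squares sphere is returned, which recovers an exact
#'   sphere through the points to numerical precision.
#' @return a [HeadSphere-class].
#' @examples
#' ss <- makeSourceSpace(260, seed = 2)
#' fitSphere(ss)
#' @export
fitSphere <- function(space, inflate = 1.1) {
  v <- if (is(space, "SourceSpace")) vertexPositions(space) else space
  if (nrow(v) < 4) stop("degenerate geometry: need at least 4 vertices")
  A <- cbind(2 * v, 1)
  b <- rowSums(v^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate geometry: vertices are coplanar or collinear")
  x <- qr.coef(qrA, b)
  center <- x[1:3]
  r2 <- x[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate geometry: non-positive fitted radius")
  r <- sqrt(r2)
  dmax <- sqrt(max(rowSums((v - matrix(center, nrow(v), 3, byrow = TRUE))^2)))
  new("HeadSphere", center = unname(center),
      radius = max(r, dmax) * inflate)
}

# Sarvas closed-form field of a current dipole in a homogeneous
# conducting sphere centred at the origin, evaluated at sensor points
# outside the sphere. rs: sensors x 3; r0: length-3 source position;
# q: length-3 dipole moment (A*m). Returns sensors x 3 field (tesla).
.sarvas_field <- function(rs, r0, q) {
  mu0_4pi <- 1e-7
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (all(qxr0 == 0)) return(matrix(0, nrow(rs), 3))
  a_vec <- rs - matrix(r0, nrow(rs), 3, byrow = TRUE)
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(rs^2))
  ar <- rowSums(a_vec * rs)
  Fv <- a * (r * a + r^2 - drop(rs %*% r0))
  # grad F
  c1 <- a^2 / r + ar / a + 2 * a + 2 * r
  c2 <- a + 2 * r + ar / a
  gradF <- rs * c1 - matrix(r0, nrow(rs), 3, byrow = TRUE) * c2
  qr0_dot_rs <- drop(rs %*% qxr0)
  B <- (matrix(qxr0, nrow(rs), 3, byrow = TRUE) * Fv - gradF * qr0_dot_rs) *
    (mu0_4pi / Fv^2)
  B
}

#' Field of arbitrary current dipoles at the array's sensors
#'
#' Sarvas closed-form conducting-sphere field of one or more current
#' dipoles, projected on each sensor's orientation. This is the
#' elementary operation behind [computeLeadField()], exposed for probing
#' the model with explicit dipoles (radial-silence checks, localization
#' fixtures).
#'
#' @param array a [SensorArray-class].
#' @param positions dipoles x 3 matrix of locations (m), inside the sphere.
#' @param moments dipoles x 3 matrix of dipole moments (A*m).
#' @param sphere a [HeadSphere-class].
#' @return sensors x dipoles matrix (tesla).
#' @export
dipoleField <- function(array, positions, moments, sphere) {
  positions <- rbind(positions)
  moments <- rbind(moments)
  if (nrow(positions) != nrow(moments))
    stop("positions/moments must have the same number of rows")
  pos <- sensorPositions(array)
  ori <- sensorOrientations(array)
  ctr <- sphere@center
  out <- matrix(0, nrow(pos), nrow(positions))
  for (d in seq_len(nrow(positions))) {
    B <- .sarvas_field(sweep(pos, 2, ctr), positions[d, ] - ctr,
                       moments[d, ])
    out[, d] <- rowSums(B * ori)
  }
  out
}

#' Compute the spherical-head MEG lead field
#'
#' Magnetic field of a unit current dipole (1 A*m) at each source vertex,
#' oriented along the vertex normal (fixed-orientation model), in a
#' homogeneous conducting sphere — the Sarvas closed form — projected on
#' each sensor's orientation. A dipole moment aligned with the radial
#' direction produces no external field in this model; the closed form
#' yields that limit exactly.
#'
#' @param space a [SourceSpace-class]; vertices must be inside the sphere.
#' @param array a [SensorArray-class]; sensors must be outside the sphere.
#' @param sphere a [HeadSphere-class]; default [fitSphere()] of `space`.
#'   Per-sensor sphere lists (overlapping-spheres models) can be passed as
#'   a list of HeadSphere of length `nSensors(array)`.
#' @return a [LeadField-class] (sensors x sources, tesla per A*m).
#' @export
computeLeadField <- function(space, array, sphere = fitSphere(space)) {
  spheres <- if (is.list(sphere)) sphere else NULL
  sph1 <- if (is.list(sphere)) sphere[[1]] else sphere
  pos <- sensorPositions(array)
  ori <- sensorOrientations(array)
  src <- vertexPositions(space)
  nrm <- vertexNormals(space)
  G <- matrix(0, nrow(pos), nrow(src))
  for (s in seq_len(nrow(src))) {
    if (is.null(spheres)) {
      ctr <- sph1@center
      B <- .sarvas_field(sweep(pos, 2, ctr), src[s, ] - ctr, nrm[s, ])
      G[, s] <- rowSums(B * ori)
    } else {
      for (k in seq_len(nrow(pos))) {
        ctr <- spheres[[k]]@center
        B <- .sarvas_field(matrix(pos[k, ] - ctr, 1), src[s, ] - ctr, nrm[s, ])
        G[k, s] <- sum(B * ori[k, ])
      }
    }
  }
  if (!all(is.finite(G))) stop("non-finite lead field entries")
  lf <- new("LeadField", gain = G, sphere = sph1)
  lf
}
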