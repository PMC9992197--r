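#' Build a bilateral spherical-shell source space with 26 ROI patches
#'
#' Vertices are placed quasi-uniformly over a thick spherical shell inside
#' the head (a desk-scale stand-in for a reconstructed cortical surface):
#' directions follow a golden-angle spiral, radii vary deterministically
#' across `radialSpread` of the shell radius so sources differ in depth,
#' as cortical sources do. Dipole orientations ("normals") are tilted
#' `tiltDeg` away from the radial direction with a deterministically
#' varying azimuth: purely radial dipoles are externally silent in a
#' spherical conductor, so radial normals would make the whole model
#' invisible to MEG, while tilted ones emulate the orientation
#' variability of folded cortex.
#'
#' The right hemisphere (x > 0) is tiled with 13 contiguous area patches
#' found by spherical k-means; the left hemisphere is its exact mirror
#' image across the x = 0 plane (positions and orientations), so
#' left/right ROI pairs are geometrically symmetric.
#'
#' @param nVertices requested vertex count (>= 52, i.e. >= 2 per ROI);
#'   rounded up to an even number so the hemispheres match.
#' @param seed integer seed fixing the patch layout.
#' @param shellRadius outer shell radius in metres (default 0.07, a
#'   cortical shell inside a 0.09 m head sphere).
#' @param radialSpread fractional depth range: radii span
#'   `shellRadius * (1 - radialSpread)` to `shellRadius` (default 0.25).
#' @param tiltDeg dipole tilt from radial, degrees (default 45).
#' @return a [SourceSpace-class] whose labels cover all 26 [roiNames()].
#' @examples
#' ss <- makeSourceSpace(520, seed = 1)
#' table(vertexLabels(ss))[1:4]
#' @export
makeSourceSpace <- function(nVertices = 520, seed = 1, shellRadius = 0.07,
                            radialSpread = 0.25, tiltDeg = 45) {
  if (nVertices < 52L)
    stop("invalid configuration: need at least 52 vertices (2 per ROI), got ",
         nVertices)
  nh <- as.integer(ceiling(nVertices / 2))
  # golden-angle spiral over the x > 0 hemisphere
  k <- seq_len(nh)
  x <- (k - 0.5) / nh
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  s <- sqrt(pmax(0, 1 - x^2))
  dirs <- cbind(x, s * cos(phi), s * sin(phi))
  dimnames(dirs) <- NULL

  # deterministic low-discrepancy depth per vertex
  frac <- (k * (sqrt(2) - 1)) %% 1
  radii <- shellRadius * (1 - radialSpread * frac)
  right <- dirs * radii

  # tilted dipole orientations: radial rotated toward the local tangent
  t1 <- cbind(-s, x * cos(phi), x * sin(phi))        # d(dir)/d(polar)
  t2 <- cbind(0, -sin(phi), cos(phi))                # azimuthal tangent
  psi <- k * golden * 2
  tang <- t1 * cos(psi) + t2 * sin(psi)
  tilt <- tiltDeg * pi / 180
  nrm <- dirs * cos(tilt) + tang * sin(tilt)
  nrm <- nrm / sqrt(rowSums(nrm^2))

  set.seed(as.integer(seed))
  km <- stats::kmeans(dirs, centers = 13L, nstart = 10, iter.max = 50)
  cl <- km$cluster
  # stable area assignment: order clusters front-to-back, top-to-bottom
  ord <- order(-km$centers[, 3], km$centers[, 2])
  areaOf <- integer(13L)
  areaOf[ord] <- seq_len(13L)
  areas <- roiNames(areas = TRUE)[areaOf[cl]]

  mirror <- matrix(c(-1, 1, 1), nh, 3, byrow = TRUE)
  new("SourceSpace",
      positions = rbind(right, right * mirror),
      normals = rbind(nrm, nrm * mirror),
      labels = c(paste0(areas, ".R"), paste0(areas, ".L")))
}

#' Indices of each ROI's vertices
#'
#' @param space a [SourceSpace-class].
#' @param rois ROI names (default the canonical 26).
#' @return named list of integer vectors.
#' @export
roiVertexIndices <- function(space, rois = roiNames()) {
  lab <- vertexLabels(space)
  out <- lapply(rois, function(r) which(lab == r))
  names(out) <- rois
  empty <- rois[vapply(out, length, integer(1)) == 0L]
  if (length(empty))
    stop("ROIs with no vertex: ", paste(empty, collapse = ", "))
  out
}
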