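# Independent numerical oracles used by the test suite. They never call
# the implementation paths they check.

# ---- conducting-sphere field by numerical Biot-Savart ----------------
# B(rs) = mu0/4pi [ Q x (rs - r0)/|rs - r0|^3      (primary current)
#                 + Int_volume J_v x k dV ],  J_v = -sigma grad V,
# k(r') = (rs - r')/|rs - r'|^3, V = V_inf + W with W harmonic and
# dV/dr = 0 on the sphere (insulating exterior). The singular part
# -sigma grad V_inf integrated over the sphere equals
# +sigma Int_exterior grad V_inf x k dV (its all-space Biot-Savart
# vanishes), where the integrand is smooth; the smooth W part is
# integrated over the sphere directly. sigma cancels against the 1/sigma
# in V. Fixture restricted to a dipole on the z-axis with moment along
# x, for which V has a pure cos(phi) azimuthal dependence and W reduces
# to a single associated-Legendre series.

oracle_grad_vinf <- function(pts, r0, Q) {
  dvec <- sweep(pts, 2, r0)
  d <- sqrt(rowSums(dvec^2))
  qd <- drop(dvec %*% Q)
  (matrix(Q, nrow(pts), 3, byrow = TRUE) / d^3 - 3 * qd * dvec / d^5) /
    (4 * pi)
}

oracle_cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# associated Legendre P_l^1 for l = 1..L, vectorized over u
oracle_plm1 <- function(u, L) {
  s <- sqrt(pmax(0, 1 - u^2))
  out <- matrix(0, length(u), L)
  out[, 1] <- -s
  if (L >= 2) out[, 2] <- -3 * u * s
  if (L >= 3) for (l in 2:(L - 1))
    out[, l + 1] <- ((2 * l + 1) * u * out[, l] - (l + 1) * out[, l - 1]) / l
  out
}

oracle_wcoef <- function(r0z, Q, R, L = 45, nq = 240) {
  gl <- pracma::gaussLegendre(nq, -1, 1)
  u <- gl$x
  s <- sqrt(1 - u^2)
  bpts <- cbind(R * s, 0, R * u)
  h <- -rowSums(oracle_grad_vinf(bpts, c(0, 0, r0z), Q) * (bpts / R))
  P <- oracle_plm1(u, L)
  l <- 1:L
  proj <- drop(t(P) %*% (h * gl$w))
  (R / l) * (2 * l + 1) / (2 * l * (l + 1)) * proj
}

oracle_w_eval <- function(pts, a, R) {
  r <- sqrt(rowSums(pts^2))
  u <- pts[, 3] / r
  phi <- atan2(pts[, 2], pts[, 1])
  P <- oracle_plm1(u, length(a))
  rl <- outer(r / R, seq_along(a), `^`)
  cos(phi) * drop((P * rl) %*% a)
}

oracle_grad_w <- function(pts, a, R, h = 1e-7) {
  g <- matrix(0, nrow(pts), 3)
  for (j in 1:3) {
    e <- matrix(0, nrow(pts), 3); e[, j] <- h
    g[, j] <- (oracle_w_eval(pts + e, a, R) -
                 oracle_w_eval(pts - e, a, R)) / (2 * h)
  }
  g
}

oracle_sphere_grid <- function(R, nr = 40, nu = 48, nphi = 64) {
  gr <- pracma::gaussLegendre(nr, 0, R)
  gu <- pracma::gaussLegendre(nu, -1, 1)
  phi <- (0:(nphi - 1)) * 2 * pi / nphi
  g <- expand.grid(ir = 1:nr, iu = 1:nu, ip = 1:nphi)
  r <- gr$x[g$ir]; u <- gu$x[g$iu]; p <- phi[g$ip]
  s <- sqrt(1 - u^2)
  list(pts = cbind(r * s * cos(p), r * s * sin(p), r * u),
       w = gr$w[g$ir] * gu$w[g$iu] * (2 * pi / nphi) * r^2)
}

# Int_exterior grad V_inf x k dV by sensor-centred ray quadrature: along
# each direction omega the kernel cancels to -(grad V x omega) dt dOmega
# and the chord inside the conductor is excluded.
oracle_ext_integral <- function(rs, r0, Q, R, nth = 40, nph = 80, nt = 28,
                                Tmax = 20 * R, ntail = 10) {
  gu <- pracma::gaussLegendre(nth, -1, 1)
  phi <- (0:(nph - 1)) * 2 * pi / nph
  wphi <- 2 * pi / nph
  gv0 <- pracma::gaussLegendre(ntail, 0, 1)
  allpts <- list(); allw <- list(); allom <- list()
  k <- 0L
  for (iu in 1:nth) for (ip in 1:nph) {
    u <- gu$x[iu]; s <- sqrt(1 - u^2); p <- phi[ip]
    om <- c(s * cos(p), s * sin(p), u)
    wom <- gu$w[iu] * wphi
    b <- sum(rs * om); cc <- sum(rs^2) - R^2
    disc <- b^2 - cc
    segs <- if (b < 0 && disc > 0)
      list(c(0, -b - sqrt(disc)), c(-b + sqrt(disc), Tmax))
    else list(c(0, Tmax))
    for (sg in segs) {
      gt <- pracma::gaussLegendre(nt, sg[1], sg[2])
      k <- k + 1L
      allpts[[k]] <- sweep(outer(gt$x, om), 2, rs, `+`)
      allw[[k]] <- gt$w * wom
      allom[[k]] <- matrix(om, nt, 3, byrow = TRUE)
    }
    k <- k + 1L
    allpts[[k]] <- sweep(outer(Tmax / gv0$x, om), 2, rs, `+`)
    allw[[k]] <- gv0$w * (Tmax / gv0$x^2) * wom
    allom[[k]] <- matrix(om, ntail, 3, byrow = TRUE)
  }
  pts <- do.call(rbind, allpts)
  gvf <- oracle_grad_vinf(pts, r0, Q)
  -colSums(oracle_cross_rows(gvf, do.call(rbind, allom)) * unlist(allw))
}

# total field at sensor rs: primary + volume-current quadrature
oracle_sphere_dipole_field <- function(rs, r0z, Q, R, L = 45) {
  r0 <- c(0, 0, r0z)
  a <- oracle_wcoef(r0z, Q, R, L = L)
  dv <- rs - r0
  Bp <- 1e-7 * c(Q[2] * dv[3] - Q[3] * dv[2],
                 Q[3] * dv[1] - Q[1] * dv[3],
                 Q[1] * dv[2] - Q[2] * dv[1]) / sum(dv^2)^1.5
  IE <- oracle_ext_integral(rs, r0, Q, R)
  sg <- oracle_sphere_grid(R)
  gw <- oracle_grad_w(sg$pts, a, R)
  kvec <- sweep(-sg$pts, 2, rs, `+`)
  kn <- rowSums(kvec^2)^1.5
  IW <- colSums(oracle_cross_rows(gw, kvec / kn) * sg$w)
  Bp + 1e-7 * (IE - IW)
}

# ---- dense penalized-least-squares solve (inverse-operator oracle) ---
# minimizes |C^(-1/2)(b - G s)|^2 + lambda2 |R^(-1/2) s|^2 by the normal
# equations, with the same trace-normalized prior convention.
oracle_mne_solve <- function(G, C, lambda2, weights, b) {
  Ci <- solve(C)
  eig <- eigen(C, symmetric = TRUE)
  W <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  L <- W %*% G
  nu <- nrow(G) / sum(weights * colSums(L^2))
  Rw <- weights * nu
  solve(t(G) %*% Ci %*% G + lambda2 * diag(1 / Rw), t(G) %*% Ci %*% b)
}

# ---- Spearman rank-formula oracle (no ties) --------------------------
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
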