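# Small 3D helpers shared by the builder, matcher and field code.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any unit vector perpendicular to v (deterministic choice)
perp_vector <- function(v) {
  v <- unitv(v)
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unitv(cross3(v, ref))
}

# Rodrigues rotation of point rows about an axis through `origin`
rotate_about_axis <- function(pts, origin, axis, angle) {
  k <- unitv(axis)
  p <- sweep(pts, 2, origin)
  ca <- cos(angle); sa <- sin(angle)
  kx <- p %*% rbind(c(0, k[3], -k[2]), c(-k[3], 0, k[1]), c(k[2], -k[1], 0))
  rot <- p * ca + kx * sa + outer(drop(p %*% k) * (1 - ca), k)
  sweep(rot, 2, origin, "+")
}

# NeRF internal-coordinate placement: new atom bonded to A with length r,
# angle `ang` to B (radians) and torsion `tor` about the B-A axis w.r.t. C
zmat_place <- function(pA, pB, pC, r, ang, tor) {
  bc <- unitv(pA - pB)
  ab <- pB - pC
  n <- cross3(ab, bc)
  if (vnorm(n) < 1e-8) n <- cross3(perp_vector(bc), bc)
  n <- unitv(n)
  m <- cross3(n, bc)
  d <- r * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  pA + d[1] * bc + d[2] * m + d[3] * n
}

# least-squares rigid superposition (Kabsch); returns rotation R and
# translation t such that  x %*% R + t  maps `mobile` onto `target`
kabsch_fit <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(target, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = ct - drop(cm %*% R))
}

apply_rigid <- function(coords, R, t) sweep(coords %*% R, 2, t, "+")

# deterministic random rigid transform (test fixtures, torsion sampling)
random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- unitv(runif(3, -1, 1))
  ang <- runif(1, 0, 2 * pi)
  ca <- cos(ang); sa <- sin(ang)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sa * K + (1 - ca) * (K %*% K)
  list(R = t(R), t = runif(3, -8, 8))
}
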