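# Small rigid-body geometry kernel shared by trajectory alignment, model
# alignment and screening placement. Coordinates are plain n x 3 matrices in
# Angstroms throughout.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum ||R x_i + t - y_i||^2` over paired coordinates, via SVD of the
#' cross-covariance with a determinant correction so that `det(R) = +1`
#' (no reflections).
#'
#' @param x,y n x 3 coordinate matrices (moving and reference), paired by row.
#' @param weights optional per-pair weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   of the superposed pairs.
#' @export
kabsch <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 1)
  w <- if (is.null(weights)) rep(1, nrow(x)) else weights
  w <- w / sum(w)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  h <- t(xc * w) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cy - as.vector(rot %*% cx)
  fitted <- t(rot %*% t(x)) + rep(trans, each = nrow(x))
  list(
    rotation = rot,
    translation = trans,
    rmsd = sqrt(sum(w * rowSums((fitted - y)^2)))
  )
}

apply_rigid <- function(xyz, rotation, translation) {
  t(rotation %*% t(as.matrix(xyz))) + rep(translation, each = nrow(xyz))
}

# rank of the centered point cloud; < 2 means collinear/degenerate for a
# rigid fit
points_rank <- function(xyz, tol = 1e-8) {
  xc <- sweep(as.matrix(xyz), 2, colMeans(xyz))
  sv <- svd(xc, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv, 1))
}

# Newell's method: robust polygon normal from ordered vertices (unit length).
ring_normal <- function(xyz) {
  xyz <- as.matrix(xyz)
  nxt <- rbind(xyz[-1, , drop = FALSE], xyz[1, , drop = FALSE])
  n <- c(
    sum(xyz[, 2] * nxt[, 3] - xyz[, 3] * nxt[, 2]),
    sum(xyz[, 3] * nxt[, 1] - xyz[, 1] * nxt[, 3]),
    sum(xyz[, 1] * nxt[, 2] - xyz[, 2] * nxt[, 1])
  )
  n / sqrt(sum(n^2))
}

# RMS distance of ring atoms from their best-fit plane
ring_planarity_rms <- function(xyz) {
  xyz <- as.matrix(xyz)
  xc <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xc, nu = 0, nv = 0)$d
  sv[3] / sqrt(nrow(xyz))
}

# fold the angle between two (un-oriented) plane normals into [0, 90] degrees
interplanar_angle <- function(n1, n2) {
  c <- abs(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2)))
  acos(pmin(1, c)) * 180 / pi
}

vec_angle <- function(a, b) {
  c <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, c))) * 180 / pi
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * ux + (1 - c1) * (u %o% u)
}
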